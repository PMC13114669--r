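# Perturbation-based superpixel attributions: kernel SHAP and LIME over a
# grid-seeded intensity superpixel partition. Occluded segments are replaced
# by a Gaussian-blurred patch (black patches are out of distribution for
# min-max-normalized ultrasound).

#' Grid-seeded intensity superpixels
#'
#' SLIC-style segmentation: seeds on a regular grid, iterative assignment of
#' each pixel to the nearest seed in (row, col, lambda * intensity) space
#' with center updates. Labels are compacted to 1..K.
#'
#' @param image H x W matrix.
#' @param n_segments requested segment count (>= 2).
#' @param lambda intensity weight relative to spatial distance.
#' @param iters assignment iterations.
#' @return integer matrix of segment labels.
#' @export
superpixel_segments <- function(image, n_segments = 50L, lambda = 10,
                                iters = 5L) {
  if (n_segments < 2L) stop("n_segments must be >= 2")
  H <- nrow(image); W <- ncol(image)
  g <- ceiling(sqrt(n_segments))
  cy <- (seq_len(g) - 0.5) * H / g
  cx <- (seq_len(g) - 0.5) * W / g
  centers <- expand.grid(y = cy, x = cx)
  centers <- centers[seq_len(min(nrow(centers), n_segments)), ]
  ci <- vapply(seq_len(nrow(centers)), function(i)
    image[round(centers$y[i]), round(centers$x[i])], numeric(1))
  yy <- rep(seq_len(H), W)
  xx <- rep(seq_len(W), each = H)
  iv <- as.numeric(image)
  lab <- integer(H * W)
  for (it in seq_len(iters)) {
    d <- matrix(Inf, H * W, nrow(centers))
    for (i in seq_len(nrow(centers))) {
      d[, i] <- (yy - centers$y[i])^2 + (xx - centers$x[i])^2 +
        (lambda * (iv - ci[i]))^2
    }
    lab <- max.col(-d, ties.method = "first")
    for (i in seq_len(nrow(centers))) {
      sel <- lab == i
      if (any(sel)) {
        centers$y[i] <- mean(yy[sel])
        centers$x[i] <- mean(xx[sel])
        ci[i] <- mean(iv[sel])
      }
    }
  }
  lab <- match(lab, sort(unique(lab)))
  matrix(lab, H, W)
}

shapley_kernel_weight <- function(M, k) {
  (M - 1) / (choose(M, k) * k * (M - k))
}

#' Superpixel occlusion attribution (kernel SHAP or LIME)
#'
#' The image is partitioned into superpixels; binary coalitions are scored
#' by the segmentation target scalar under occlusion of the absent segments
#' (Gaussian-blurred patches); per-segment coefficients come from a
#' Shapley-kernel-weighted constrained least squares ("shap") or a
#' proximity-kernel ridge regression ("lime") and are painted back to
#' pixels. When \code{n_samples} covers all nontrivial coalitions the
#' enumeration is exhaustive and kernel SHAP equals exact Shapley values for
#' additive targets.
#'
#' @param model trained model (or any function image -> scalar via
#'   \code{target_fn}, used mainly for testing).
#' @param image H x W matrix.
#' @param mode "shap" or "lime".
#' @param n_segments requested superpixel count.
#' @param n_samples coalition budget (must be >= n_segments + 2).
#' @param seed RNG seed for coalition sampling.
#' @param blur_sigma occlusion blur width in pixels.
#' @param target_fn optional function(image_matrix) -> scalar overriding the
#'   model target (the predicted-foreground logit sum).
#' @param chunk forward batch size.
#' @return "attribution_map" (signed); segment labels in
#'   \code{attr(map, "segments")}, coefficients in \code{attr(map, "phi")}.
#' @export
superpixel_attribution <- function(model, image, mode = c("shap", "lime"),
                                   n_segments = 50L, n_samples = 1000L,
                                   seed = 1L, blur_sigma = 4,
                                   target_fn = NULL, chunk = 16L) {
  mode <- match.arg(mode)
  seg <- superpixel_segments(image, n_segments)
  M <- max(seg)
  if (n_samples < M + 2L) {
    stop("n_samples must be at least n_segments + 2 (underdetermined system)")
  }
  set.seed(seed)
  blurred <- gaussian_blur(image, blur_sigma)
  if (is.null(target_fn)) {
    pred <- (predict_prob(model, image)[, , 1] >= 0.5) + 0
    target_fn_batch <- function(imgs) {
      lg <- ag_val(model_forward(model, images_to_batch(imgs))$logits)
      vapply(seq_along(imgs), function(i)
        seg_target_scalar(lg[, , 1, i], pred), numeric(1))
    }
  } else {
    target_fn_batch <- function(imgs) vapply(imgs, target_fn, numeric(1))
  }
  # coalitions as 0/1 rows
  exhaustive <- (2^M - 2) <= n_samples
  Z <- if (exhaustive) {
    zz <- as.matrix(expand.grid(rep(list(0:1), M)))
    zz[rowSums(zz) > 0 & rowSums(zz) < M, , drop = FALSE]
  } else {
    ks <- 1:(M - 1)
    pk <- (M - 1) / (ks * (M - ks))
    pk <- pk / sum(pk)
    t(vapply(seq_len(n_samples), function(i) {
      k <- sample(ks, 1L, prob = pk)
      z <- integer(M)
      z[sample.int(M, k)] <- 1L
      z
    }, integer(M)))
  }
  occlude <- function(z) {
    out <- image
    drop <- which(z == 0)
    sel <- seg %in% drop
    out[sel] <- blurred[sel]
    out
  }
  vals <- numeric(nrow(Z))
  idx <- seq_len(nrow(Z))
  for (grp in split(idx, ceiling(idx / chunk))) {
    imgs <- lapply(grp, function(i) occlude(Z[i, ]))
    vals[grp] <- target_fn_batch(imgs)
  }
  v0 <- target_fn_batch(list(occlude(integer(M))))[1]
  v1 <- target_fn_batch(list(image))[1]
  if (mode == "shap") {
    k <- rowSums(Z)
    w <- shapley_kernel_weight(M, k)
    # eliminate phi_M through the efficiency constraint sum(phi) = v1 - v0
    y <- vals - v0 - Z[, M] * (v1 - v0)
    X <- Z[, -M, drop = FALSE] - Z[, M]
    XtW <- t(X * w)
    phi_part <- solve(XtW %*% X + diag(1e-10, M - 1L), XtW %*% y)
    phi <- c(phi_part, (v1 - v0) - sum(phi_part))
  } else {
    # LIME: exponential proximity kernel on coalition similarity, ridge
    simil <- rowSums(Z) / M
    w <- exp(-((1 - simil)^2) / 0.25)
    X <- cbind(1, Z)
    XtW <- t(X * w)
    lam <- 0.01 * nrow(Z)
    beta <- solve(XtW %*% X + diag(lam, M + 1L), XtW %*% (vals - v0))
    phi <- beta[-1]
  }
  vals_map <- matrix(phi[as.vector(seg)], nrow(image), ncol(image))
  out <- attribution_map(vals_map, paste0("superpixel_", mode),
                         normalized = FALSE)
  attr(out, "segments") <- seg
  attr(out, "phi") <- as.numeric(phi)
  out
}
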