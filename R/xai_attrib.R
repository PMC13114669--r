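# Attribution, attention and uncertainty methods adapted to binary
# segmentation. All methods scalarize the dense output as the sum of logits
# over the predicted foreground (all pixels when the prediction is empty),
# so classification-style attribution applies unchanged.


# Grad-CAM++ channel weighting. A, G: (h, w, C) activation and gradient
# arrays (C may be dropped for a single channel). Returns the ReLU'd
# weighted activation sum before upsampling/normalization. With a single
# channel and everywhere-positive gradients the alpha coefficients sum to 1,
# so the result reduces to ReLU(A) times a positive constant.
gradcam_pp_core <- function(A, G) {
  if (length(dim(A)) == 2L) {
    dim(A) <- c(dim(A), 1L)
    dim(G) <- dim(A)
  }
  C <- dim(A)[3]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(C)) {
    g <- G[, , c]
    a <- A[, , c]
    g2 <- g * g
    g3 <- g2 * g
    denom <- 2 * g2 + sum(a * g3)
    alpha <- ifelse(abs(denom) > 1e-12, g2 / denom, 0)
    wc <- sum(alpha * pmax(g, 0))
    cam <- cam + wc * a
  }
  pmax(cam, 0)
}

# First-singular-vector projection of a (pixels x channels) activation
# matrix; sign-aligned to nonnegative mean, absolute value. NULL for
# numerically rank-0 input.
eigen_project <- function(M) {
  sv <- svd(M, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12) return(NULL)
  proj <- as.numeric(M %*% sv$v[, 1])
  if (mean(proj) < 0) proj <- -proj
  abs(proj)
}

# Attention-rollout accumulation: per level, add identity and renormalize
# rows, expand the coarse token grid to the finest one (each coarse token
# maps to an s x s block of fine tokens, weights split evenly), and multiply.
# attn_mats: list of square matrices over column-major token grids of side
# sizes[l]; returns the accumulated matrix on the sizes[1] grid.
rollout_product <- function(attn_mats, sizes) {
  R <- NULL
  for (l in seq_along(attn_mats)) {
    A <- attn_mats[[l]]
    A <- A + diag(nrow(A))
    A <- A / rowSums(A)
    if (sizes[l] < sizes[1]) {
      s <- sizes[1] %/% sizes[l]
      hh <- rep(seq_len(sizes[1]), sizes[1])
      ww <- rep(seq_len(sizes[1]), each = sizes[1])
      cp <- ((ww - 1L) %/% s) * sizes[l] + ((hh - 1L) %/% s) + 1L
      A <- A[cp, cp, drop = FALSE] / (s * s)
    }
    R <- if (is.null(R)) A else A %*% R
  }
  R
}

attribution_map <- function(values, method, level = NA, branch = NA,
                            normalized = TRUE, flag = NULL) {
  structure(list(values = values, method = method, level = level,
                 branch = branch, normalized = normalized, flag = flag),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %s (level %s, %s) %dx%d range [%.3g, %.3g]%s\n",
              x$method, as.character(x$level), as.character(x$branch),
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

max_normalize <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Scalarization target for dense attribution
#'
#' Sum of logits over the predicted foreground; falls back to the sum over
#' all pixels when the prediction is empty. Linear in the logits, hence
#' differentiable.
#'
#' @param logits numeric logit map.
#' @param pred_mask binary predicted mask (same shape).
#' @export
seg_target_scalar <- function(logits, pred_mask) {
  if (!any(pred_mask > 0)) return(sum(logits))
  sum(logits[pred_mask > 0])
}

target_weight_array <- function(pred_mask) {
  w <- (pred_mask > 0) + 0
  if (!any(w > 0)) w[] <- 1
  w
}

# forward under tape, returning fw result; image is an H x W matrix
forward_taped <- function(model, image, input_grad = FALSE,
                          collect_attn = FALSE) {
  x <- images_to_batch(image)
  xt <- ag_tensor(x, requires_grad = input_grad)
  fw <- NULL
  with_tape({
    fw <- model_forward_tensor(model, xt, training = FALSE,
                               collect_attn = collect_attn)
    w <- target_weight_array(array((fw$prob[, , 1] >= 0.5) + 0, dim(x)))
    scalar <- ag_dot(fw$logits, w)
    ag_backward(scalar, retain = TRUE)
  })
  fw$input <- xt
  fw$target <- sum(ag_val(fw$logits) * w)
  fw
}

# the layer tensor for (level, branch) or a decoder node
pick_layer <- function(fw, level, branch) {
  if (branch %in% c("cnn", "mamba", "trans", "fused")) {
    lv <- fw$cache$levels[[level]]
    if (is.null(lv[[branch]])) {
      stop("branch '", branch, "' not present in this model variant")
    }
    return(lv[[branch]])
  }
  node <- fw$cache$decoder_nodes[[branch]]
  if (is.null(node)) stop("unknown target layer: ", branch)
  node
}

#' Grad-CAM++ attribution
#'
#' Channel weights from first/second/third powers of the target-scalar
#' gradient at the chosen layer; ReLU of the weighted activation sum,
#' bilinearly upsampled to image size and max-normalized.
#'
#' @param model trained model.
#' @param image H x W matrix in [0, 1].
#' @param level encoder level 1-4 (ignored when \code{branch} names a
#'   decoder node such as "X0_3").
#' @param branch "fused", "cnn", "mamba", "trans", or a decoder node name.
#' @return an "attribution_map" (nonnegative, max 1 unless all-zero, in
#'   which case \code{flag = "zero-gradient"}).
#' @export
grad_cam_pp <- function(model, image, level = 4L, branch = "fused") {
  fw <- forward_taped(model, image)
  layer <- pick_layer(fw, level, branch)
  A <- ag_val(layer)[, , , 1, drop = FALSE]
  G <- layer$g
  if (is.null(G) || all(G == 0)) {
    return(attribution_map(matrix(0, nrow(image), ncol(image)), "grad_cam_pp",
                           level, branch, flag = "zero-gradient"))
  }
  G <- G[, , , 1, drop = FALSE]
  cam <- gradcam_pp_core(A[, , , 1, drop = TRUE], G[, , , 1, drop = TRUE])
  cam <- resize_bilinear(cam, nrow(image), ncol(image))
  cam <- pmax(cam, 0)
  flag <- if (max(cam) == 0) "zero-map" else NULL
  attribution_map(max_normalize(cam), "grad_cam_pp", level, branch, flag = flag)
}

#' Score-CAM attribution (gradient-free)
#'
#' Each channel's normalized activation masks the input; the channel weight
#' is the increase of the target scalar over the all-masked baseline. No
#' gradients are evaluated.
#'
#' @inheritParams grad_cam_pp
#' @param chunk forward-pass batch size for channel scoring.
#' @export
score_cam <- function(model, image, level = 4L, branch = "fused",
                      chunk = 16L) {
  fw0 <- model_forward(model, image)
  pred <- (fw0$prob[, , 1] >= 0.5) + 0
  layer_val <- ag_val(pick_layer_value(fw0, level, branch))[, , , 1, drop = FALSE]
  C <- dim(layer_val)[3]
  S <- nrow(image)
  masks <- vector("list", C)
  keep <- logical(C)
  for (c in seq_len(C)) {
    a <- layer_val[, , c, 1]
    rng <- range(a)
    if (rng[2] > rng[1]) {
      masks[[c]] <- resize_bilinear((a - rng[1]) / (rng[2] - rng[1]), S, S)
      keep[c] <- TRUE
    }
  }
  base <- seg_target_scalar(
    ag_val(model_forward(model, image * 0)$logits)[, , 1, 1], pred)
  wts <- numeric(C)
  todo <- which(keep)
  for (grp in split(todo, ceiling(seq_along(todo) / chunk))) {
    xb <- array(0, c(S, S, 1L, length(grp)))
    for (i in seq_along(grp)) xb[, , 1, i] <- image * masks[[grp[i]]]
    lg <- ag_val(model_forward(model, xb)$logits)
    for (i in seq_along(grp)) {
      wts[grp[i]] <- seg_target_scalar(lg[, , 1, i], pred) - base
    }
  }
  cam <- matrix(0, dim(layer_val)[1], dim(layer_val)[2])
  for (c in seq_len(C)) if (wts[c] > 0) cam <- cam + wts[c] * layer_val[, , c, 1]
  cam <- pmax(resize_bilinear(pmax(cam, 0), S, S), 0)
  attribution_map(max_normalize(cam), "score_cam", level, branch,
                  flag = if (max(cam) == 0) "zero-map" else NULL)
}

pick_layer_value <- function(fw, level, branch) pick_layer(fw, level, branch)

#' Eigen-CAM attribution
#'
#' Projection of the (pixels x channels) activation matrix onto its first
#' right singular vector, taken in absolute value, upsampled and normalized.
#' Invariant to channel permutation and positive rescaling.
#'
#' @inheritParams grad_cam_pp
#' @export
eigen_cam <- function(model, image, level = 4L, branch = "fused") {
  fw <- model_forward(model, image)
  A <- ag_val(pick_layer(fw, level, branch))[, , , 1, drop = FALSE]
  h <- dim(A)[1]; w <- dim(A)[2]; C <- dim(A)[3]
  M <- A
  dim(M) <- c(h * w, C)
  proj <- eigen_project(M)
  if (is.null(proj)) {
    return(attribution_map(matrix(0, nrow(image), ncol(image)), "eigen_cam",
                           level, branch, flag = "degenerate-rank0"))
  }
  cam <- matrix(proj, h, w)
  cam <- pmax(resize_bilinear(cam, nrow(image), ncol(image)), 0)
  attribution_map(max_normalize(cam), "eigen_cam", level, branch)
}

#' Integrated gradients
#'
#' Midpoint-rule path integral of the target-scalar input gradient from a
#' baseline to the image, multiplied elementwise by (image - baseline).
#' Signed map; satisfies the completeness axiom up to quadrature error.
#'
#' The default baseline is a strongly Gaussian-blurred copy of the image
#' (structure removed, intensity statistics kept). An all-zero baseline is
#' accepted but discouraged: a constant image collapses the variance inside
#' the normalization layers, so the integrand develops a sharp boundary
#' layer near the baseline end of the path and the quadrature converges
#' very slowly.
#'
#' @param model trained model.
#' @param image H x W matrix.
#' @param baseline same shape (default: image blurred with sigma = 8 px).
#' @param steps quadrature points (a warning is recorded below 8).
#' @param chunk forward batch size.
#' @export
integrated_gradients <- function(model, image, baseline = NULL, steps = 64L,
                                 chunk = 16L) {
  if (is.null(baseline)) baseline <- gaussian_blur(image, 8)
  flag <- NULL
  if (steps < 8L) {
    warning("integrated_gradients with steps < 8 is a coarse quadrature")
    flag <- "few-steps"
  }
  pred <- (predict_prob(model, image)[, , 1] >= 0.5) + 0
  wmask <- target_weight_array(pred)
  S <- nrow(image)
  diff <- image - baseline
  total_grad <- matrix(0, S, S)
  alphas <- (seq_len(steps) - 0.5) / steps
  for (grp in split(alphas, ceiling(seq_along(alphas) / chunk))) {
    xb <- array(0, c(S, S, 1L, length(grp)))
    for (i in seq_along(grp)) xb[, , 1, i] <- baseline + grp[i] * diff
    xt <- ag_tensor(xb, requires_grad = TRUE)
    with_tape({
      fwb <- model_forward_tensor(model, xt, training = FALSE)
      wb <- array(0, dim(xb))
      for (i in seq_along(grp)) wb[, , 1, i] <- wmask
      ag_backward(ag_dot(fwb$logits, wb))
    })
    g <- xt$g
    for (i in seq_along(grp)) total_grad <- total_grad + g[, , 1, i]
  }
  attr_map <- (total_grad / steps) * diff
  attribution_map(attr_map, "integrated_gradients", normalized = FALSE,
                  flag = flag)
}

#' Attention rollout
#'
#' Head-averaged attention plus identity, row-renormalized, accumulated
#' across the four encoder levels after expanding coarser token grids to the
#' finest grid; the rows of the product belonging to predicted-foreground
#' tokens are averaged into a pixel map.
#'
#' @param model trained model (must contain the transformer branch).
#' @param image H x W matrix.
#' @export
attention_rollout <- function(model, image) {
  if (!"transformer" %in% model$config$branches) {
    stop("attention rollout requires the transformer branch")
  }
  fw <- model_forward(model, image, collect_attn = TRUE)
  sizes <- level_sizes(model$config)
  T0 <- sizes[1]^2
  R <- rollout_product(lapply(1:4, function(l) fw$cache$attn[[l]][[1]]),
                       sizes)
  pred <- (fw$prob[, , 1] >= 0.5)
  pred_tok <- resize_nearest(pred + 0, sizes[1], sizes[1]) > 0
  rows <- if (any(pred_tok)) which(as.vector(pred_tok)) else seq_len(T0)
  v <- colMeans(R[rows, , drop = FALSE])
  cam <- matrix(v, sizes[1], sizes[1])
  cam <- pmax(resize_bilinear(cam, nrow(image), ncol(image)), 0)
  attribution_map(max_normalize(cam), "attention_rollout")
}

#' Monte-Carlo-dropout uncertainty map
#'
#' Runs T stochastic forward passes with dropout active and returns the
#' per-pixel mean and standard deviation (population SD, so values are
#' bounded by 0.5) of the sigmoid probabilities.
#'
#' @param model trained model with a nonzero dropout rate.
#' @param image H x W matrix.
#' @param T number of stochastic passes.
#' @param seed RNG seed.
#' @param rate optional dropout-rate override for the stochastic passes
#'   (e.g. 0 to verify that the spread vanishes).
#' @return list with \code{mean} (matrix), \code{uncertainty}
#'   ("uncertainty_map": values, passes).
#' @export
mc_dropout_uncertainty <- function(model, image, T = 30L, seed = 1L,
                                   rate = NULL) {
  if (model$config$dropout <= 0) {
    stop("mc_dropout_uncertainty requires a model with dropout > 0")
  }
  if (!is.null(rate)) model$config$dropout <- rate
  set.seed(seed)
  S <- nrow(image)
  acc <- matrix(0, S, S)
  acc2 <- matrix(0, S, S)
  for (t in seq_len(T)) {
    p <- model_forward(model, image, training = TRUE)$prob[, , 1]
    acc <- acc + p
    acc2 <- acc2 + p * p
  }
  mu <- acc / T
  v <- acc2 / T - mu * mu
  v[v < 1e-14] <- 0  # clamp accumulation roundoff so identical passes give 0
  list(mean = mu,
       uncertainty = structure(list(values = sqrt(v), passes = T),
                               class = "uncertainty_map"))
}

#' Per-branch contribution by fusion-weight deactivation
#'
#' For each auxiliary branch, its fusion weight is pinned to zero at every
#' level (remaining weights renormalized per sample) and the mean DSC over
#' the samples is re-evaluated; the contribution is baseline minus
#' deactivated.
#'
#' @param model trained triple-branch model with affm fusion.
#' @param samples list of "image_sample" objects.
#' @return data.frame (branch, dsc_baseline, dsc_deactivated, delta_dsc).
#' @export
branch_contribution <- function(model, samples) {
  cfg <- model$config
  if (cfg$fusion != "affm" || length(cfg$branches) < 2L) {
    stop("branch_contribution requires affm fusion with >= 2 branches")
  }
  eval_dsc <- function(branch_mask) {
    d <- vapply(samples, function(s) {
      p <- model_forward(model, s$image, branch_mask = branch_mask)$prob[, , 1]
      overlap_metrics(p >= 0.5, s$mask)$dsc
    }, numeric(1))
    mean(d)
  }
  base <- eval_dsc(NULL)
  aux <- setdiff(cfg$branches, "cnn")
  rows <- lapply(aux, function(b) {
    if (b == "cnn") stop("the cnn anchor branch cannot be deactivated")
    mask <- as.numeric(cfg$branches != b)
    d <- eval_dsc(mask)
    data.frame(branch = b, dsc_baseline = base, dsc_deactivated = d,
               delta_dsc = base - d)
  })
  do.call(rbind, rows)
}

#' Profile the learned fusion weights on data
#'
#' Collects the per-sample per-level fusion-weight vectors in evaluation
#' mode and summarizes them (mean, quartiles) per level and branch.
#'
#' @param model affm-fusion model.
#' @param samples list of "image_sample" objects.
#' @return list with \code{weights} (list of per-level N x k matrices) and
#'   \code{summary} (data.frame: level, branch, mean, q25, median, q75).
#' @export
affm_weight_profile <- function(model, samples) {
  if (model$config$fusion != "affm" || length(model$config$branches) < 2L) {
    stop("affm_weight_profile requires affm fusion")
  }
  x <- images_to_batch(lapply(samples, `[[`, "image"))
  fw <- model_forward(model, x)
  branches <- model$config$branches
  summ <- list()
  for (l in 1:4) {
    w <- fw$weights[[l]]
    for (b in seq_along(branches)) {
      q <- quantile(w[, b], c(0.25, 0.5, 0.75), type = 7)
      summ[[length(summ) + 1L]] <- data.frame(
        level = l, branch = branches[b], mean = mean(w[, b]),
        q25 = q[1], median = q[2], q75 = q[3])
    }
  }
  list(weights = fw$weights, summary = do.call(rbind, summ))
}

#' Decoder node activation maps
#'
#' Channel-mean absolute activation of the requested dense-decoder nodes,
#' upsampled to image size and normalized to [0, 1].
#'
#' @param model trained model.
#' @param image H x W matrix.
#' @param nodes node names such as "X0_3" (default: all refinement nodes).
#' @export
decoder_feature_maps <- function(model, image, nodes = NULL) {
  fw <- model_forward(model, image)
  avail <- names(fw$cache$decoder_nodes)
  refine <- grep("_0$", avail, value = TRUE, invert = TRUE)
  if (is.null(nodes)) nodes <- refine
  missing <- setdiff(nodes, avail)
  if (length(missing)) {
    stop("decoder node(s) ", paste(missing, collapse = ", "),
         " absent in the '", model$config$decoder, "' decoder")
  }
  out <- lapply(nodes, function(nm) {
    A <- ag_val(fw$cache$decoder_nodes[[nm]])[, , , 1, drop = FALSE]
    m <- apply(abs(A[, , , 1, drop = FALSE]), c(1, 2), mean)
    max_normalize(pmax(resize_bilinear(m, nrow(image), ncol(image)), 0))
  })
  names(out) <- nodes
  out
}
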