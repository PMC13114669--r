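# Quantitative validation of attribution and uncertainty maps: localization
# statistics (normalized energy attribution ratio, top-k hit rates),
# cross-method consistency (Spearman, SSIM), uncertainty-error analysis,
# quartile case selection and uncertainty-based failure flagging.

attr_values <- function(attr) {
  if (inherits(attr, "attribution_map")) attr$values else as.matrix(attr)
}

#' Normalized energy attribution ratio (nEAR)
#'
#' Fraction of total attribution energy (sum of absolute values) inside the
#' ground-truth mask, divided by the mask's area fraction. 1 = chance level;
#' larger = attribution concentrates on the lesion.
#'
#' @param attr attribution map (or matrix).
#' @param mask binary ground-truth mask.
#' @return ratio, or NA (with a warning) for an empty mask or zero-energy
#'   map.
#' @export
near <- function(attr, mask) {
  a <- abs(attr_values(attr))
  m <- as.matrix(mask) > 0
  if (!any(m) || sum(a) == 0) {
    warning("nEAR undefined for an empty mask or zero-energy map")
    return(NA_real_)
  }
  (sum(a[m]) / sum(a)) / (sum(m) / length(m))
}

#' Top-k% lesion hit rate
#'
#' Fraction of the k% highest-|attribution| pixels (ties broken in fixed
#' row-major order) falling inside the mask, normalized by the mask area
#' fraction.
#'
#' @param attr attribution map.
#' @param mask binary mask.
#' @param k_percent percentage in (0, 100].
#' @export
topk_hit_rate <- function(attr, mask, k_percent) {
  if (k_percent <= 0 || k_percent > 100) stop("k_percent must be in (0, 100]")
  a <- abs(attr_values(attr))
  m <- as.matrix(mask) > 0
  if (!any(m) || sum(a) == 0) {
    warning("hit rate undefined for an empty mask or zero-energy map")
    return(NA_real_)
  }
  n <- length(a)
  k <- ceiling(k_percent / 100 * n)
  # row-major tie-break: order by value desc, then row-major position
  rowmaj <- as.vector(t(matrix(seq_len(n), nrow(a), ncol(a))))
  pos <- order(match(seq_len(n), rowmaj))
  sel <- order(-as.vector(a), pos)[seq_len(k)]
  (sum(m[sel]) / k) / (sum(m) / n)
}

box_mean <- function(m, k) {
  cnt <- box_count(matrix(1, nrow(m), ncol(m)), k)
  box_count(m, k) / cnt
}

#' Structural similarity between two maps
#'
#' Standard two-constant SSIM with a k x k uniform window, computed after
#' normalizing both maps to [0, 1] (dynamic range 1).
#'
#' @param a,b numeric matrices of equal shape.
#' @param window odd window size (default 7).
#' @export
ssim_map <- function(a, b, window = 7L) {
  norm01 <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  }
  a <- norm01(attr_values(a)); b <- norm01(attr_values(b))
  C1 <- 0.01^2; C2 <- 0.03^2
  mua <- box_mean(a, window); mub <- box_mean(b, window)
  va <- box_mean(a * a, window) - mua^2
  vb <- box_mean(b * b, window) - mub^2
  cab <- box_mean(a * b, window) - mua * mub
  s <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Cross-method consistency of attribution maps
#'
#' Pairwise Spearman rank correlation (average ranks on ties) and SSIM over
#' a list of maps; optional family labels yield within/between-family mean
#' agreement. A constant map makes its Spearman entries NA.
#'
#' @param maps named list of attribution maps (equal shapes).
#' @param families optional character vector of family labels per map.
#' @param window SSIM window.
#' @return list (class "consistency_matrix") with \code{spearman},
#'   \code{ssim} matrices, \code{mean_spearman}, \code{mean_ssim}
#'   (off-diagonal means) and optional \code{family_means}.
#' @export
cross_method_consistency <- function(maps, families = NULL, window = 7L) {
  k <- length(maps)
  stopifnot(k >= 2L)
  nm <- names(maps)
  if (is.null(nm)) nm <- paste0("map", seq_len(k))
  vs <- lapply(maps, function(m) as.vector(attr_values(m)))
  sp <- matrix(1, k, k, dimnames = list(nm, nm))
  ss <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sp[i, j] <- sp[j, i] <-
        if (sd(vs[[i]]) == 0 || sd(vs[[j]]) == 0) NA_real_
        else cor(vs[[i]], vs[[j]], method = "spearman")
      ss[i, j] <- ss[j, i] <- ssim_map(maps[[i]], maps[[j]], window)
    }
  }
  off <- upper.tri(sp)
  out <- list(spearman = sp, ssim = ss,
              mean_spearman = mean(sp[off], na.rm = TRUE),
              mean_ssim = mean(ss[off]))
  if (!is.null(families)) {
    stopifnot(length(families) == k)
    same <- outer(families, families, "==") & off
    diff <- (!outer(families, families, "==")) & off
    out$family_means <- list(
      within_spearman = mean(sp[same], na.rm = TRUE),
      between_spearman = mean(sp[diff], na.rm = TRUE),
      within_ssim = mean(ss[same]),
      between_ssim = mean(ss[diff]))
  }
  structure(out, class = "consistency_matrix")
}

#' Uncertainty-versus-error analysis
#'
#' Error map = prediction XOR ground truth. Reports the pooled per-pixel
#' Pearson correlation between uncertainty and error across all images, the
#' per-image correlation (mean uncertainty vs error rate), the error/correct
#' mean-uncertainty ratio, Cohen's d between the two pixel populations, and
#' the boundary/interior mean-uncertainty ratio on the ground-truth band.
#'
#' @param unc_maps list of uncertainty matrices (or "uncertainty_map"s).
#' @param pred_masks,gt_masks aligned lists of binary masks.
#' @param band_kernel kernel of the ground-truth boundary band.
#' @return list of class "uncertainty_error_report".
#' @export
uncertainty_error_report <- function(unc_maps, pred_masks, gt_masks,
                                     band_kernel = 7L) {
  n <- length(unc_maps)
  stopifnot(length(pred_masks) == n, length(gt_masks) == n)
  getu <- function(u) if (inherits(u, "uncertainty_map")) u$values else as.matrix(u)
  uu <- c(); ee <- c(); bb <- c()
  img_mu <- numeric(n); img_er <- numeric(n)
  for (i in seq_len(n)) {
    u <- getu(unc_maps[[i]])
    p <- as.matrix(pred_masks[[i]]) > 0
    g <- as.matrix(gt_masks[[i]]) > 0
    err <- xor(p, g)
    band <- boundary_band(g, band_kernel)
    uu <- c(uu, as.vector(u)); ee <- c(ee, as.numeric(err))
    bb <- c(bb, as.vector(band))
    img_mu[i] <- mean(u); img_er[i] <- mean(err)
  }
  pooled_r <- if (sd(uu) == 0 || sd(ee) == 0) NA_real_ else cor(uu, ee)
  pooled_p <- if (is.na(pooled_r)) NA_real_ else
    cor.test(uu, ee)$p.value
  per_image_r <- if (n >= 3 && sd(img_mu) > 0 && sd(img_er) > 0)
    cor(img_mu, img_er) else NA_real_
  el <- ee > 0
  mu_err <- mean(uu[el]); mu_ok <- mean(uu[!el])
  ratio <- if (mu_ok > 0) mu_err / mu_ok else if (mu_err == mu_ok) 1 else Inf
  if (sd(uu) == 0) ratio <- 1
  sp <- sqrt(((sum(el) - 1) * var(uu[el]) + (sum(!el) - 1) * var(uu[!el])) /
               (length(uu) - 2))
  d <- if (is.finite(sp) && sp > 0) (mu_err - mu_ok) / sp else NA_real_
  mu_band <- mean(uu[bb]); mu_int <- mean(uu[!bb])
  bratio <- if (mu_int > 0) mu_band / mu_int else if (mu_band == mu_int) 1 else Inf
  if (sd(uu) == 0) bratio <- 1
  structure(list(pooled_r = pooled_r, pooled_p = pooled_p,
                 per_image_r = per_image_r,
                 error_correct_ratio = ratio, cohen_d = d,
                 boundary_interior_ratio = bratio,
                 n_images = n, n_pixels = length(uu)),
            class = "uncertainty_error_report")
}

#' @export
print.uncertainty_error_report <- function(x, ...) {
  cat(sprintf(
    paste0("<uncertainty/error> pooled r=%.3f per-image r=%.3f ",
           "err/correct=%.2fx d=%.2f boundary/interior=%.2fx (n=%d images)\n"),
    x$pooled_r, x$per_image_r, x$error_correct_ratio, x$cohen_d,
    x$boundary_interior_ratio, x$n_images))
  invisible(x)
}

#' Quartile-based case selection
#'
#' Sorts items ascending by DSC (ties by id) and returns the ids at the
#' lowest rank, the 25th-percentile rank, the median rank and the highest
#' rank.
#'
#' @param dsc_by_id named numeric vector (names = ids) with >= 4 items.
#' @return character vector of 4 ids (worst, q25, median, best).
#' @export
quartile_case_selection <- function(dsc_by_id) {
  n <- length(dsc_by_id)
  if (n < 4L) stop("need at least 4 items")
  ord <- order(dsc_by_id, names(dsc_by_id))
  ids <- names(dsc_by_id)[ord]
  c(worst = ids[1],
    q25 = ids[ceiling(0.25 * n)],
    median = ids[ceiling(0.5 * n)],
    best = ids[n])
}

#' Uncertainty-based failure flag
#'
#' Flags a case as unreliable when its mean uncertainty exceeds the
#' threshold.
#'
#' @param unc_map uncertainty matrix or "uncertainty_map".
#' @param threshold mean-uncertainty threshold in (0, 0.5).
#' @return list(mean_uncertainty, flagged).
#' @export
failure_flag <- function(unc_map, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 0.5) stop("threshold must be in (0, 0.5)")
  u <- if (inherits(unc_map, "uncertainty_map")) unc_map$values else as.matrix(unc_map)
  mu <- mean(u)
  list(mean_uncertainty = mu, flagged = mu > threshold)
}
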