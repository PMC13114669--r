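# Fold aggregation and the paired statistical comparison battery: paired t,
# exact Wilcoxon signed rank (zeros dropped), Cohen's d, Shapiro-Wilk on the
# differences, Bonferroni adjustment, Friedman rank test, and the
# size/difficulty stratified comparison.

#' Aggregate per-image metric records across cross-validation folds
#'
#' Per-image values are averaged within each fold; the cross-fold mean, SD
#' and a t-distribution 95% confidence interval (df = folds - 1) are reported
#' per metric.
#'
#' @param records data.frame with an \code{id} column and numeric metric
#'   columns (as emitted by \code{\link{metrics_record}}).
#' @param manifest data.frame with \code{id} and \code{fold} columns.
#' @param conf confidence level (default 0.95).
#' @return list (class "busseg_fold_summary") with \code{fold_means} (fold x
#'   metric data.frame) and \code{summary} (per-metric mean, sd, ci_lo,
#'   ci_hi, n_folds).
#' @export
fold_aggregate <- function(records, manifest, conf = 0.95) {
  if (!all(records$id %in% manifest$id)) {
    missing <- setdiff(records$id, manifest$id)
    stop("records without fold assignment: ", paste(missing, collapse = ", "))
  }
  fold <- manifest$fold[match(records$id, manifest$id)]
  metric_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  folds <- sort(unique(fold))
  fm <- do.call(rbind, lapply(folds, function(f) {
    colMeans(records[fold == f, metric_cols, drop = FALSE])
  }))
  fm <- data.frame(fold = folds, fm, check.names = FALSE)
  n <- length(folds)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  summ <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- fm[[mc]]
    m <- mean(v); s <- sd(v)
    hw <- if (n > 1) tq * s / sqrt(n) else 0
    data.frame(metric = mc, mean = m, sd = ifelse(is.na(s), 0, s),
               ci_lo = m - ifelse(is.na(hw), 0, hw),
               ci_hi = m + ifelse(is.na(hw), 0, hw), n_folds = n)
  }))
  structure(list(fold_means = fm, summary = summ),
            class = "busseg_fold_summary")
}

#' @export
print.busseg_fold_summary <- function(x, ...) {
  cat("<fold summary> (", nrow(x$fold_means), "folds )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# Exact Wilcoxon signed-rank two-sided p. Zeros dropped (Wilcoxon's rule).
# For n <= 25 the exact sign-randomization null is computed by a
# generating-function convolution over the (possibly tied, average) ranks;
# beyond that a tie-corrected normal approximation is used.
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # counts[k + 1] = number of sign assignments with doubled rank sum k
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (k in r2) {
      shifted <- c(numeric(k), counts[seq_len(total + 1 - k)])
      counts <- counts + shifted
    }
    W2 <- as.integer(round(2 * W))
    p_ge <- sum(counts[(W2 + 1):(total + 1)]) / 2^n
    p_le <- sum(counts[1:(W2 + 1)]) / 2^n
    p <- min(1, 2 * min(p_ge, p_le))
    return(list(statistic = W, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu) / sqrt(sig2)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(z))), n = n, exact = FALSE)
}

effect_size_label <- function(d) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad < 0.2) "negligible" else if (ad < 0.5) "small"
  else if (ad < 0.8) "medium" else "large"
}

#' Paired comparison of two models' per-item metric values
#'
#' Differences are \code{b - a}. Reports the paired t test, the Wilcoxon
#' signed-rank test (exact null for small untied samples, zeros dropped),
#' paired Cohen's d = mean(diff)/sd(diff) with the conventional magnitude
#' label, Shapiro-Wilk normality of the differences, and a
#' Bonferroni-adjusted Wilcoxon p for a caller-supplied number of
#' comparisons. Zero-variance differences yield an NA (undefined) d and
#' degenerate tests are flagged.
#'
#' @param a,b equal-length numeric vectors (n >= 3), matched by item.
#' @param bonferroni_m number of comparisons in the family (default 1).
#' @return list of class "busseg_comparison".
#' @export
paired_compare <- function(a, b, bonferroni_m = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- b - a
  sdd <- sd(d)
  degenerate <- sdd == 0
  tt <- if (degenerate) list(statistic = NA_real_, p.value = NA_real_)
        else t.test(b, a, paired = TRUE)
  wx <- wilcoxon_signed_rank(d)
  cohen_d <- if (degenerate) NA_real_ else mean(d) / sdd
  sh <- if (degenerate || length(unique(d)) < 3) NULL
        else shapiro.test(d)
  structure(list(
    mean_diff = mean(d),
    t_statistic = as.numeric(tt$statistic), t_p = tt$p.value,
    wilcoxon_statistic = wx$statistic, wilcoxon_p = wx$p,
    wilcoxon_exact = wx$exact,
    wilcoxon_p_bonferroni = min(1, wx$p * bonferroni_m),
    cohen_d = cohen_d,
    effect_label = effect_size_label(cohen_d),
    shapiro_p = if (is.null(sh)) NA_real_ else sh$p.value,
    n = length(d), degenerate = degenerate),
    class = "busseg_comparison")
}

#' @export
print.busseg_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired comparison> n=%d  mean diff=%.4g  t p=%.3g  Wilcoxon p=%.3g  d=%.3g (%s)\n",
    x$n, x$mean_diff, x$t_p, x$wilcoxon_p, x$cohen_d, x$effect_label))
  invisible(x)
}

#' Friedman rank test across models
#'
#' Ranks the k models within each item (average ranks on ties) and computes
#' \code{chi2 = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)} with a chi-square
#' p on k - 1 degrees of freedom.
#'
#' @param m items x models numeric matrix.
#' @param higher_better rank direction; TRUE ranks larger values higher.
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{mean_ranks}.
#' @export
friedman_rank <- function(m, higher_better = TRUE) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L)
  r <- t(apply(if (higher_better) m else -m, 1L, rank))
  Rj <- colSums(r)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  list(chi2 = chi2, df = k - 1L, p = pchisq(chi2, k - 1L, lower.tail = FALSE),
       mean_ranks = Rj / n)
}

#' Stratified comparison by lesion size and case difficulty
#'
#' Stratifies images by ground-truth lesion-area terciles
#' (small/medium/large) and by a hard/easy split at the 25th percentile of
#' model A's per-image DSC, and reports the mean DSC difference (B - A)
#' within each stratum.
#'
#' @param dsc_a,dsc_b per-image DSC vectors of the two models (same order).
#' @param gt_masks list of ground-truth masks aligned with the vectors.
#' @return data.frame with stratum, n and mean_diff.
#' @export
difficulty_strata <- function(dsc_a, dsc_b, gt_masks) {
  stopifnot(length(dsc_a) == length(dsc_b), length(dsc_a) == length(gt_masks))
  area <- vapply(gt_masks, function(m) mean(as_binary(m)), numeric(1))
  qs <- quantile(area, c(1 / 3, 2 / 3), type = 7)
  size_stratum <- cut(area, c(-Inf, qs, Inf),
                      labels = c("small", "medium", "large"))
  hard_cut <- quantile(dsc_a, 0.25, type = 7)
  hard <- dsc_a <= hard_cut
  d <- dsc_b - dsc_a
  strata <- list(small = size_stratum == "small",
                 medium = size_stratum == "medium",
                 large = size_stratum == "large",
                 hard = hard, easy = !hard)
  do.call(rbind, lapply(names(strata), function(s) {
    idx <- strata[[s]]
    data.frame(stratum = s, n = sum(idx),
               mean_diff = if (any(idx)) mean(d[idx]) else NA_real_)
  }))
}
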