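# Per-image segmentation metrics: overlap measures from the confusion
# counts, the 95th-percentile Hausdorff distance between mask boundaries,
# and boundary IoU restricted to the ground-truth morphological band.

as_binary <- function(m) (as.matrix(m) > 0)

#' Overlap metrics from a predicted and a ground-truth mask
#'
#' Computes Dice, IoU, recall, precision and specificity from TP/FP/FN/TN.
#' Conventions for degenerate masks: both empty gives all five metrics 1;
#' ratios with a zero denominator (e.g. precision of an empty prediction
#' against a nonempty truth) are 0.
#'
#' @param pred,gt binary matrices of equal shape.
#' @return named list (dsc, iou, recall, precision, specificity).
#' @export
overlap_metrics <- function(pred, gt) {
  pred <- as_binary(pred); gt <- as_binary(gt)
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  tp <- sum(pred & gt); fp <- sum(pred & !gt)
  fn <- sum(!pred & gt); tn <- sum(!pred & !gt)
  if (tp + fp + fn == 0) {
    return(list(dsc = 1, iou = 1, recall = 1, precision = 1, specificity = 1))
  }
  ratio <- function(num, den) if (den == 0) 0 else num / den
  list(dsc = ratio(2 * tp, 2 * tp + fp + fn),
       iou = ratio(tp, tp + fp + fn),
       recall = ratio(tp, tp + fn),
       precision = ratio(tp, tp + fp),
       specificity = ratio(tn, tn + fp))
}

# Boundary pixels: mask pixels with a 4-neighbor background pixel or lying on
# the image border. Returns an n x 2 matrix of (row, col) coordinates.
mask_boundary_coords <- function(m) {
  m <- as_binary(m)
  H <- nrow(m); W <- ncol(m)
  if (!any(m)) return(matrix(numeric(0), 0, 2))
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(m & !inner, arr.ind = TRUE)
}

directed_p95 <- function(a, b) {
  # 95th percentile (linear interpolation) of nearest-neighbor distances a->b
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1L, min))
  as.numeric(quantile(dmin, 0.95, type = 7))
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Boundaries use 4-connectivity (border pixels count as boundary); the
#' statistic is the maximum of the two directed 95th-percentile
#' nearest-neighbor distances in pixels. Degenerate cases: both masks empty
#' gives 0; exactly one empty gives the image diagonal as a bounded sentinel.
#'
#' @param pred,gt binary matrices of equal shape.
#' @export
hd95 <- function(pred, gt) {
  pred <- as_binary(pred); gt <- as_binary(gt)
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  pe <- !any(pred); ge <- !any(gt)
  if (pe && ge) return(0)
  if (pe || ge) return(sqrt(sum(dim(gt)^2)))
  a <- mask_boundary_coords(pred)
  b <- mask_boundary_coords(gt)
  max(directed_p95(a, b), directed_p95(b, a))
}

#' Boundary IoU
#'
#' IoU restricted to the morphological band of the ground truth:
#' \code{|pred & gt & band| / |(pred | gt) & band|}. If the band is empty
#' (empty ground truth) the value is 1 when the masks agree and 0 otherwise.
#'
#' @param pred,gt binary matrices of equal shape.
#' @param kernel odd kernel of the band (default 7).
#' @export
boundary_iou <- function(pred, gt, kernel = 7L) {
  pred <- as_binary(pred); gt <- as_binary(gt)
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  band <- boundary_band(gt, kernel)
  den <- sum((pred | gt) & band)
  if (den == 0) return(if (identical(pred, gt)) 1 else 0)
  sum(pred & gt & band) / den
}

#' All per-image metrics for one prediction
#'
#' @param prob probability map (binarized at 0.5) or an already-binary mask.
#' @param gt binary ground truth.
#' @param id sample identifier carried into the record.
#' @param band_kernel kernel for boundary IoU.
#' @return one-row data.frame (id, dsc, iou, b_iou, recall, precision,
#'   specificity, hd95).
#' @export
metrics_record <- function(prob, gt, id = NA_character_, band_kernel = 7L) {
  pred <- as.matrix(prob) >= 0.5
  om <- overlap_metrics(pred, gt)
  data.frame(id = id, dsc = om$dsc, iou = om$iou,
             b_iou = boundary_iou(pred, gt, band_kernel),
             recall = om$recall, precision = om$precision,
             specificity = om$specificity, hd95 = hd95(pred, gt),
             stringsAsFactors = FALSE)
}
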