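# Boundary-aware composite (DBR) loss: spatially weighted BCE + soft Dice +
# a BCE term restricted to a morphological boundary band (dilation minus
# erosion of the ground-truth mask with a square kernel, zero padding on both
# operations).

#' Loss configuration
#'
#' @param lambda_bce,lambda_dice,lambda_boundary nonnegative component
#'   weights (all 1 by default).
#' @param w_boundary,w_interior pixel weights for the spatially weighted BCE
#'   (3 on the boundary band, 1 elsewhere).
#' @param band_kernel odd kernel size of the morphological band (7).
#' @param dice_smooth smoothing constant of the soft Dice term.
#' @export
loss_config <- function(lambda_bce = 1, lambda_dice = 1, lambda_boundary = 1,
                        w_boundary = 3, w_interior = 1, band_kernel = 7L,
                        dice_smooth = 1) {
  if (band_kernel %% 2L == 0L || band_kernel < 3L) {
    stop("band_kernel must be odd and >= 3")
  }
  if (any(c(lambda_bce, lambda_dice, lambda_boundary) < 0)) {
    stop("loss weights must be nonnegative")
  }
  structure(list(lambda_bce = lambda_bce, lambda_dice = lambda_dice,
                 lambda_boundary = lambda_boundary, w_boundary = w_boundary,
                 w_interior = w_interior, band_kernel = as.integer(band_kernel),
                 dice_smooth = dice_smooth),
            class = "busseg_loss_config")
}

# Count of ones in a k x k window around every pixel, zero padding (integral
# image).
box_count <- function(m, k) {
  r <- (k - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 2L * r, W + 2L * r)
  P[r + seq_len(H), r + seq_len(W)] <- m
  I <- matrix(0, H + 2L * r + 1L, W + 2L * r + 1L)
  I[-1L, -1L] <- apply(apply(P, 2L, cumsum), 1L, cumsum) |> t()
  hi <- seq_len(H) + 2L * r
  wi <- seq_len(W) + 2L * r
  I[hi + 1L, wi + 1L, drop = FALSE] - I[hi + 1L - k, wi + 1L, drop = FALSE] -
    I[hi + 1L, wi + 1L - k, drop = FALSE] + I[hi + 1L - k, wi + 1L - k, drop = FALSE]
}

#' Morphological boundary band of a binary mask
#'
#' Band = dilation(mask) AND NOT erosion(mask) with a square structuring
#' element; the image is zero-padded for both operations, so an all-ones mask
#' has a band along the image border.
#'
#' @param mask binary matrix (0/1 or logical).
#' @param kernel odd kernel size (default 7).
#' @return logical matrix.
#' @export
boundary_band <- function(mask, kernel = 7L) {
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  m <- (as.matrix(mask) > 0) + 0
  cnt <- box_count(m, kernel)
  dil <- cnt > 0
  ero <- cnt == kernel * kernel
  dil & !ero
}

clamp_probs <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

bce_elem <- function(probs, target) {
  q <- clamp_probs(probs)
  -(target * log(q) + (1 - target) * log(1 - q))
}

#' Spatially weighted binary cross-entropy
#'
#' Mean BCE with per-pixel weights \code{w_boundary} on the band and
#' \code{w_interior} elsewhere, normalized by the total weight (so with equal
#' weights it reduces to plain mean BCE exactly).
#'
#' @param probs predicted probabilities (clamped to [1e-7, 1 - 1e-7]).
#' @param target binary target, same shape.
#' @param band logical boundary band, same shape.
#' @param w_boundary,w_interior pixel weights.
#' @export
weighted_bce <- function(probs, target, band, w_boundary = 3, w_interior = 1) {
  if (!identical(dim(as.matrix(probs)), dim(as.matrix(target)))) {
    stop("probs and target shapes differ")
  }
  w <- ifelse(band, w_boundary, w_interior)
  sum(w * bce_elem(probs, target)) / sum(w)
}

#' Soft Dice loss
#'
#' \code{1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)} over the whole image.
#' @param probs predicted probabilities.
#' @param target binary target.
#' @param smooth smoothing constant.
#' @export
dice_loss <- function(probs, target, smooth = 1) {
  if (length(probs) != length(target)) stop("probs and target shapes differ")
  1 - (2 * sum(probs * target) + smooth) / (sum(probs) + sum(target) + smooth)
}

#' Boundary BCE term
#'
#' Mean unweighted BCE over the band pixels; 0 for an empty band.
#' @param probs predicted probabilities.
#' @param target binary target.
#' @param band logical boundary band.
#' @export
boundary_loss <- function(probs, target, band) {
  if (!any(band)) return(0)
  mean(bce_elem(probs[band], target[band]))
}

#' Boundary-aware composite loss
#'
#' Computes the three components and their weighted total
#' \code{l_total = lambda_bce * l_bce_weighted + lambda_dice * l_dice +
#' lambda_boundary * l_boundary}; the band is derived from the target.
#'
#' @param probs predicted probabilities.
#' @param target binary target mask.
#' @param config a \code{\link{loss_config}}.
#' @return list (class "busseg_loss_breakdown") with \code{l_bce_weighted},
#'   \code{l_dice}, \code{l_boundary}, \code{l_total}.
#' @export
dbr_loss <- function(probs, target, config = loss_config()) {
  band <- boundary_band(target, config$band_kernel)
  l_bce <- weighted_bce(probs, target, band, config$w_boundary, config$w_interior)
  l_dice <- dice_loss(probs, target, config$dice_smooth)
  l_bnd <- boundary_loss(probs, target, band)
  structure(list(l_bce_weighted = l_bce, l_dice = l_dice, l_boundary = l_bnd,
                 l_total = config$lambda_bce * l_bce +
                   config$lambda_dice * l_dice +
                   config$lambda_boundary * l_bnd),
            class = "busseg_loss_breakdown")
}

# Differentiable batch loss on logits (numerically stable BCE-with-logits;
# Dice on sigmoid probabilities). logits: tensor (H,W,1,N); targets: array of
# the same shape. Returns list(total = scalar tensor, breakdown).
dbr_loss_ag <- function(logits, targets, config = loss_config()) {
  d <- dim(targets)
  N <- d[4]
  band <- array(FALSE, d)
  for (n in seq_len(N)) band[, , 1L, n] <- boundary_band(targets[, , 1L, n],
                                                         config$band_kernel)
  w <- ifelse(band, config$w_boundary, config$w_interior)
  l_bce <- ag_wbce_logits(logits, targets, w)
  probs <- ag_sigmoid(logits)
  num <- ag_add(ag_scale(ag_dot(probs, targets), 2), config$dice_smooth)
  den <- ag_add(ag_sum(probs), sum(targets) + config$dice_smooth)
  l_dice <- ag_sub(1, ag_div(num, den))
  l_bnd <- if (any(band)) ag_wbce_logits(logits, targets, band + 0) else ag_tensor(0)
  total <- ag_add(ag_add(ag_scale(l_bce, config$lambda_bce),
                         ag_scale(l_dice, config$lambda_dice)),
                  ag_scale(l_bnd, config$lambda_boundary))
  list(total = total,
       breakdown = list(l_bce_weighted = ag_val(l_bce), l_dice = ag_val(l_dice),
                        l_boundary = ag_val(l_bnd), l_total = ag_val(total)))
}
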