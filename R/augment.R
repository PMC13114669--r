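# Training-time augmentation: horizontal flip (p = 0.5), rotation within
# +/-15 degrees, and a mild affine jitter (translation <= 5% of the side,
# isotropic scale 0.9-1.1). The identical geometric transform is applied to
# the image (bilinear, zero fill outside the canvas) and the mask (nearest,
# re-binarized).

# inverse-map affine warp; A maps output pixel coords (centered) to source
warp_affine <- function(m, A, shift, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- rep(seq_len(H), W) - cy
  xx <- rep(seq_len(W), each = H) - cx
  sy <- A[1, 1] * yy + A[1, 2] * xx + cy + shift[1]
  sx <- A[2, 1] * yy + A[2, 2] * xx + cx + shift[2]
  if (bilinear) {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    val <- function(yi, xi) {
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
      v <- numeric(length(yi))
      v[ok] <- m[cbind(yi[ok], xi[ok])]
      v
    }
    out <- (1 - fy) * (1 - fx) * val(y0, x0) +
      (1 - fy) * fx * val(y0, x0 + 1) +
      fy * (1 - fx) * val(y0 + 1, x0) +
      fy * fx * val(y0 + 1, x0 + 1)
  } else {
    yi <- round(sy); xi <- round(sx)
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    out <- numeric(H * W)
    out[ok] <- m[cbind(yi[ok], xi[ok])]
  }
  matrix(out, H, W)
}

#' Randomly augment an image/mask sample
#'
#' Draws flip/rotation/affine parameters from the current RNG stream and
#' applies the same geometric transform to image and mask. The image stays in
#' [0, 1] and the mask stays binary.
#'
#' @param sample an "image_sample" (image, mask, id, fold).
#' @param flip_p horizontal-flip probability.
#' @param max_rotate rotation limit in degrees.
#' @param max_translate translation limit as a fraction of the image side.
#' @param scale_range isotropic scale range.
#' @return augmented sample.
#' @export
augment_sample <- function(sample, flip_p = 0.5, max_rotate = 15,
                           max_translate = 0.05, scale_range = c(0.9, 1.1)) {
  img <- sample$image
  msk <- sample$mask
  if (runif(1) < flip_p) {
    img <- img[, rev(seq_len(ncol(img)))]
    msk <- msk[, rev(seq_len(ncol(msk)))]
  }
  ang <- runif(1, -max_rotate, max_rotate) * pi / 180
  sc <- runif(1, scale_range[1], scale_range[2])
  tr <- runif(2, -max_translate, max_translate) * nrow(img)
  # inverse map: rotate by -ang, scale by 1/sc, then shift by -tr
  A <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2) / sc
  if (abs(ang) > 1e-12 || abs(sc - 1) > 1e-12 || any(abs(tr) > 1e-12)) {
    img <- pmin(pmax(warp_affine(img, A, -tr, bilinear = TRUE), 0), 1)
    msk <- (warp_affine(msk, A, -tr, bilinear = FALSE) >= 0.5) + 0
  }
  sample$image <- img
  sample$mask <- msk
  sample
}
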