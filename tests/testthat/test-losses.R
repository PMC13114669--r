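# Boundary-aware composite loss: morphology fixtures, hand-computed BCE
# oracles, component identities, and the gradient of the trainable form.

test_that("boundary_band matches hand morphology with zero padding", {
  expect_false(any(boundary_band(matrix(0, 9, 9), 7)))
  # single center pixel in 13x13: dilation is the 7x7 square, erosion empty
  m <- matrix(0, 13, 13); m[7, 7] <- 1
  b <- boundary_band(m, 7)
  expect_equal(sum(b), 49)
  expect_true(all(which(b, arr.ind = TRUE)[, 1] %in% 4:10))
  # all-ones 10x10 with zero padding: erosion leaves the inner 4x4
  b2 <- boundary_band(matrix(1, 10, 10), 7)
  expect_equal(sum(b2), 100 - 16)
  expect_error(boundary_band(m, 6), "odd")
})

test_that("boundary_band contains the topological boundary for kernel >= 3", {
  set.seed(20)
  for (i in 1:20) {
    m <- boundary_band(matrix(rbinom(15 * 15, 1, 0.4), 15, 15), 1)  # any mask
    msk <- matrix(rbinom(15 * 15, 1, 0.35), 15, 15)
    band <- boundary_band(msk, 3)
    edge <- getFromNamespace("mask_boundary_coords", "busseg")(msk)
    if (nrow(edge)) expect_true(all(band[edge]))
  }
})

test_that("weighted_bce reproduces constants and a 3x3 hand oracle", {
  tgt <- matrix(c(0, 1, 0, 1), 2, 2)
  band <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  # perfect prediction (clamped): essentially zero
  expect_lt(weighted_bce(tgt, tgt, band), 2e-6)
  # constant 0.5 probabilities: ln 2 regardless of weights
  expect_equal(weighted_bce(matrix(0.5, 2, 2), tgt, band, 3, 1), log(2),
               tolerance = 1e-12)
  # 3x3 toy with a fixed probability fixture against per-pixel arithmetic
  t3 <- matrix(0, 3, 3); t3[2, 2] <- 1
  band3 <- boundary_band(t3, 3)
  p3 <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.9, 0.6, 0.2, 0.1, 0.3), 3, 3)
  w <- ifelse(band3, 3, 1)
  bce <- -(t3 * log(p3) + (1 - t3) * log(1 - p3))
  expect_equal(weighted_bce(p3, t3, band3), sum(w * bce) / sum(w),
               tolerance = 1e-12)
  # equal weights reduce exactly to the plain mean
  expect_equal(weighted_bce(p3, t3, band3, 1, 1), mean(bce), tolerance = 1e-15)
})

test_that("dice_loss matches closed-form arithmetic", {
  tgt <- matrix(0, 20, 20); tgt[3:12, 3:12] <- 1  # sum = 100
  expect_equal(dice_loss(tgt, tgt, smooth = 1), 0)
  expect_equal(dice_loss(tgt * 0, tgt, smooth = 1), 1 - 1 / 101,
               tolerance = 1e-12)
  expect_equal(dice_loss(0.5 * tgt, tgt, smooth = 1), 1 - 101 / 151,
               tolerance = 1e-12)
})

test_that("boundary_loss matches the 13x13 hand fixture and empty fallback", {
  expect_equal(boundary_loss(matrix(0.4, 5, 5), matrix(0, 5, 5),
                             boundary_band(matrix(0, 5, 5), 7)), 0)
  t13 <- matrix(0, 13, 13); t13[7, 7] <- 1
  band <- boundary_band(t13, 7)
  probs <- matrix(0.25, 13, 13)
  want <- (log(4) + 48 * log(4 / 3)) / 49
  expect_equal(boundary_loss(probs, t13, band), want, tolerance = 1e-10)
  expect_equal(boundary_loss(probs, t13, band), 0.3100, tolerance = 1e-3)
  # constant 0.5 on the band gives ln 2
  expect_equal(boundary_loss(matrix(0.5, 13, 13), t13, band), log(2),
               tolerance = 1e-12)
})

test_that("dbr_loss satisfies the component-sum identity and vanishes at the target", {
  set.seed(21)
  for (i in 1:100) {
    tgt <- matrix(rbinom(64, 1, 0.3), 8, 8)
    probs <- matrix(runif(64, 0.01, 0.99), 8, 8)
    cfg <- loss_config(lambda_bce = runif(1, 0, 2), lambda_dice = runif(1, 0, 2),
                       lambda_boundary = runif(1, 0, 2), band_kernel = 3L)
    br <- dbr_loss(probs, tgt, cfg)
    expect_equal(br$l_total,
                 cfg$lambda_bce * br$l_bce_weighted +
                   cfg$lambda_dice * br$l_dice +
                   cfg$lambda_boundary * br$l_boundary,
                 tolerance = 1e-6)
    expect_true(all(unlist(br) >= 0))
  }
  tgt <- matrix(0, 10, 10); tgt[4:6, 4:6] <- 1
  expect_lt(dbr_loss(tgt, tgt)$l_total, 1e-5)
})

test_that("the no-boundary configuration equals plain BCE + Dice", {
  tgt <- matrix(0, 13, 13); tgt[5:8, 5:8] <- 1
  probs <- matrix(runif(169, 0.05, 0.95), 13, 13)
  cfg <- loss_config(lambda_boundary = 0, w_boundary = 1, w_interior = 1)
  br <- dbr_loss(probs, tgt, cfg)
  bce <- mean(-(tgt * log(probs) + (1 - tgt) * log(1 - probs)))
  expect_equal(br$l_total, bce + dice_loss(probs, tgt), tolerance = 1e-10)
})

test_that("gradient of the trainable loss matches finite differences on an 8x8 instance", {
  set.seed(22)
  tgt <- array(0, c(8, 8, 1, 1)); tgt[3:5, 3:6, 1, 1] <- 1
  z <- array(rnorm(64), c(8, 8, 1, 1))
  agt <- getFromNamespace("ag_tensor", "busseg")
  lt <- agt(z, requires_grad = TRUE)
  getFromNamespace("with_tape", "busseg")({
    l <- getFromNamespace("dbr_loss_ag", "busseg")(lt, tgt)
    getFromNamespace("ag_backward", "busseg")(l$total)
  })
  f <- function(x) {
    lv <- getFromNamespace("dbr_loss_ag", "busseg")(agt(x), tgt)
    getFromNamespace("ag_val", "busseg")(lv$total)
  }
  gn <- fd_grad(f, z)
  expect_lt(max(abs(lt$g - gn)) / max(abs(gn)), 1e-3)
})
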