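# Attribution methods: closed-form cores, axiomatic checks on the miniature
# model, rollout arithmetic, SHAP exactness, and MC-dropout contracts.

ns <- function(f) getFromNamespace(f, "busseg")

test_that("the scalarization target is linear and falls back on empty predictions", {
  z <- matrix(rnorm(25), 5, 5)
  m <- matrix(0, 5, 5); m[2:3, 2:3] <- 1
  expect_equal(seg_target_scalar(z, m), sum(z[m > 0]))
  expect_equal(seg_target_scalar(z + 2 * m, m), seg_target_scalar(z, m) + 2 * 4)
  expect_equal(seg_target_scalar(z, m * 0), sum(z))
})

test_that("grad-cam++ core: single channel with positive gradients gives ReLU activation", {
  set.seed(60)
  A <- matrix(runif(36, -0.5, 1), 6, 6)
  G <- matrix(runif(36, 0.2, 1), 6, 6)
  cam <- ns("gradcam_pp_core")(A, G)
  # alpha sums to 1 over the map when all gradients are positive, so the
  # channel weight is positive and the map is proportional to ReLU(A)
  expect_equal(cam / max(cam), pmax(A, 0) / max(pmax(A, 0)), tolerance = 1e-9)
})

test_that("eigen projection recovers |u| for rank-1 activations and its invariances", {
  set.seed(61)
  u <- rnorm(30); v <- rnorm(7)
  M <- u %o% v
  p <- ns("eigen_project")(M)
  expect_equal(p / max(p), abs(u) / max(abs(u)), tolerance = 1e-9)
  # channel permutation and positive scaling do not change the map
  expect_equal(ns("eigen_project")(M[, sample(7)]), p, tolerance = 1e-9)
  expect_equal(ns("eigen_project")(3.7 * M) / 3.7, p, tolerance = 1e-9)
  expect_null(ns("eigen_project")(matrix(0, 5, 3)))
})

test_that("CAM maps on the model are nonnegative, normalized, deterministic", {
  tt <- get_tiny_trained()
  img <- tt$gs$samples[[1]]$image
  for (f in list(grad_cam_pp, eigen_cam)) {
    m1 <- f(tt$model, img)
    expect_true(all(m1$values >= 0))
    expect_lte(max(m1$values), 1)
    m2 <- f(tt$model, img)
    expect_identical(m1$values, m2$values)
  }
  sc <- score_cam(tt$model, img, level = 3L)
  expect_true(all(sc$values >= 0))
  expect_lte(max(sc$values), 1)
})

test_that("integrated gradients: completeness within 1% and zero at the baseline", {
  tt <- get_tiny_trained()
  img <- tt$gs$samples[[2]]$image
  base <- ns("gaussian_blur")(img, 8)
  ig <- integrated_gradients(tt$model, img, baseline = base, steps = 256L)
  pred <- (predict_prob(tt$model, img)[, , 1] >= 0.5) + 0
  f <- function(x) seg_target_scalar(
    ns("ag_val")(model_forward(tt$model, x)$logits)[, , 1, 1], pred)
  total <- f(img) - f(base)
  expect_lt(abs(sum(ig$values) - total) / abs(total), 0.01)
  ig0 <- integrated_gradients(tt$model, img, baseline = img, steps = 16L)
  expect_true(all(ig0$values == 0))
  expect_warning(integrated_gradients(tt$model, img, steps = 4L), "quadrature")
})

test_that("attention rollout arithmetic matches a hand matrix product", {
  # two levels on 2x2 and 1x1 grids with hand-specified attention
  A1 <- matrix(c(0.4, 0.2, 0.2, 0.2,
                 0.1, 0.6, 0.2, 0.1,
                 0.25, 0.25, 0.25, 0.25,
                 0.3, 0.3, 0.2, 0.2), 4, 4, byrow = TRUE)
  A2 <- matrix(1, 1, 1)
  R <- ns("rollout_product")(list(A1, A2), c(2L, 1L))
  B1 <- (A1 + diag(4)); B1 <- B1 / rowSums(B1)
  # second level: (A2 + I)/rowsum = 1 on the 1x1 grid; expansion to the 2x2
  # grid spreads each unit row over s^2 = 4 fine tokens
  B2f <- matrix(1 / 4, 4, 4)
  expect_equal(R, B2f %*% B1, tolerance = 1e-12)
  expect_equal(rowSums(R), rep(1, 4), tolerance = 1e-12)
  # uniform single-level attention stays uniform
  U <- matrix(1 / 4, 4, 4)
  Ru <- ns("rollout_product")(list(U), c(2L))
  expect_true(all(abs(Ru - Ru[1, 1]) < 1e-12 | abs(Ru - Ru[1, 2]) < 1e-12))
  # identity attention at every level gives identity weighting
  Ri <- ns("rollout_product")(list(diag(4), diag(4)), c(2L, 2L))
  expect_equal(Ri, diag(4))
  tt <- get_tiny_trained()
  expect_error(attention_rollout(
    build_variant("cnn_mamba", tiny_cfg(), 1L)$model,
    tt$gs$samples[[1]]$image), "transformer")
})

test_that("kernel SHAP equals exact Shapley values on an additive 6-segment target", {
  set.seed(62)
  img <- matrix(runif(32 * 32), 32, 32)
  seg <- superpixel_segments(img, 6L)
  M <- max(seg)
  coef <- rnorm(M)
  target <- function(im) {
    s <- 0
    for (k in seq_len(M)) s <- s + coef[k] * mean(im[seg == k])
    s
  }
  shap <- superpixel_attribution(NULL, img, "shap", n_segments = 6L,
                                 n_samples = 2L^M, seed = 1L,
                                 target_fn = target)
  phi <- attr(shap, "phi")
  # exact Shapley value of an additive game: the per-segment contribution
  blur <- ns("gaussian_blur")(img, 4)
  exact <- vapply(seq_len(max(attr(shap, "segments"))), function(k) {
    sel <- attr(shap, "segments") == k
    coef_k <- coef[k]
    coef_k * (mean(img[sel]) - mean(blur[sel]))
  }, numeric(1))
  expect_equal(phi, exact, tolerance = 1e-8)
  # a constant target yields near-zero coefficients
  shap0 <- superpixel_attribution(NULL, img, "shap", n_segments = 6L,
                                  n_samples = 2L^M, seed = 1L,
                                  target_fn = function(im) 3.5)
  expect_lt(max(abs(attr(shap0, "phi"))), 1e-8)
  # determinism under a fixed seed (sampled regime)
  s1 <- superpixel_attribution(NULL, img, "lime", n_segments = 6L,
                               n_samples = 40L, seed = 9L, target_fn = target)
  s2 <- superpixel_attribution(NULL, img, "lime", n_segments = 6L,
                               n_samples = 40L, seed = 9L, target_fn = target)
  expect_identical(s1$values, s2$values)
  expect_error(superpixel_attribution(NULL, img, "shap", n_segments = 6L,
                                      n_samples = 5L, target_fn = target),
               "underdetermined")
})

test_that("MC dropout: bounded spread, zero at rate 0, seed-reproducible", {
  tt <- get_tiny_trained()
  img <- tt$gs$samples[[3]]$image
  u <- mc_dropout_uncertainty(tt$model, img, T = 8L, seed = 2L)
  expect_true(all(u$uncertainty$values <= 0.5))
  expect_true(all(u$uncertainty$values >= 0))
  expect_gt(max(u$uncertainty$values), 0)  # dropout 0.1 is active
  u2 <- mc_dropout_uncertainty(tt$model, img, T = 8L, seed = 2L)
  expect_identical(u$uncertainty$values, u2$uncertainty$values)
  u0 <- mc_dropout_uncertainty(tt$model, img, T = 5L, seed = 2L, rate = 0)
  expect_true(all(u0$uncertainty$values == 0))
  nodrop <- build_model(tiny_cfg(dropout = 0), seed = 1L)
  expect_error(mc_dropout_uncertainty(nodrop, img), "dropout")
})

test_that("branch deactivation renormalizes weights and reports finite deltas", {
  tt <- get_tiny_trained()
  samples <- tt$gs$samples[1:4]
  bc <- branch_contribution(tt$model, samples)
  expect_setequal(bc$branch, c("mamba", "transformer"))
  expect_true(all(is.finite(bc$delta_dsc)))
  # masked weights sum to one
  fw <- model_forward(tt$model, samples[[1]]$image, branch_mask = c(1, 0, 1))
  for (l in 1:4) {
    expect_equal(rowSums(fw$weights[[l]]), 1, tolerance = 1e-9)
    expect_equal(fw$weights[[l]][, 2], 0)
  }
})

test_that("fusion-weight profiling sums to one per level and per mean", {
  tt <- get_tiny_trained()
  pr <- affm_weight_profile(tt$model, tt$gs$samples[1:6])
  for (l in 1:4) {
    expect_equal(rowSums(pr$weights[[l]]), rep(1, 6), tolerance = 1e-6)
    mlev <- pr$summary$mean[pr$summary$level == l]
    expect_equal(sum(mlev), 1, tolerance = 1e-6)
  }
})

test_that("decoder feature maps cover the nested topology and stay in [0, 1]", {
  tt <- get_tiny_trained()
  img <- tt$gs$samples[[1]]$image
  maps <- decoder_feature_maps(tt$model, img)
  expect_setequal(names(maps),
                  c("X0_1", "X1_1", "X2_1", "X0_2", "X1_2", "X0_3"))
  for (m in maps) {
    expect_true(all(m >= 0 & m <= 1))
    expect_identical(dim(m), dim(img))
  }
  plain <- build_variant("no_dense_decoder", tiny_cfg(), 1L)$model
  expect_error(decoder_feature_maps(plain, img, nodes = "X0_3"), "plain")
})
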