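# Quantitative attribution statistics: closed-form localization ratios,
# consistency matrices, uncertainty-error recovery, and case selection.

test_that("nEAR closed forms: uniform, concentrated, checkerboard", {
  mask <- matrix(0, 8, 8); mask[1:4, 1:8] <- 1       # 50% of pixels
  expect_equal(near(matrix(1, 8, 8), mask), 1)
  mask25 <- matrix(0, 8, 8); mask25[1:4, 1:4] <- 1   # 25%
  attr_in <- matrix(0, 8, 8); attr_in[1:4, 1:4] <- runif(16, 0.1, 1)
  expect_equal(near(attr_in, mask25), 4)
  # checkerboard aligned with a 50% mask
  cb <- mask
  expect_equal(near(cb, mask), 2)
  # signed maps use absolute energy
  expect_equal(near(-attr_in, mask25), 4)
  expect_warning(expect_true(is.na(near(matrix(1, 4, 4), matrix(0, 4, 4)))),
                 "undefined")
  # upper bound: all energy inside the mask
  expect_lte(near(attr_in, mask25), length(mask25) / sum(mask25))
})

test_that("top-k hit rates: indicator, uniform, and full-selection cases", {
  n <- 100
  mask <- matrix(0, 10, 10); mask[1, 1:10] <- 1      # 10% of pixels
  expect_equal(topk_hit_rate(mask, mask, 10), 10)
  expect_equal(topk_hit_rate(matrix(1, 10, 10), mask, 100), 1)
  expect_equal(topk_hit_rate(matrix(runif(100), 10, 10), mask, 100), 1)
  # uniform attribution with an evenly spread mask is ~1 at any k
  spread <- matrix(0, 10, 10)
  spread[cbind(1:10, 1:10)] <- 1  # diagonal: one mask pixel per row
  u <- topk_hit_rate(matrix(1, 10, 10), spread, 25)
  expect_lt(abs(u - 1), 0.35)
  expect_error(topk_hit_rate(mask, mask, 0), "k_percent")
  expect_lte(topk_hit_rate(mask, mask, 5), 1 / (sum(mask) / n))
})

test_that("consistency matrices are symmetric with unit diagonal and rank-invariant", {
  set.seed(70)
  a <- matrix(runif(400), 20, 20)
  maps <- list(a = a, b = exp(2 * a) + 1, c = -a, d = matrix(runif(400), 20, 20))
  cm <- cross_method_consistency(maps, families = c("x", "x", "y", "y"))
  expect_equal(diag(cm$spearman), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$spearman, t(cm$spearman))
  expect_equal(cm$ssim, t(cm$ssim))
  expect_equal(cm$spearman["a", "b"], 1)    # monotone transform
  expect_equal(cm$spearman["a", "c"], -1)   # negation
  expect_equal(cm$ssim["a", "a"], 1)
  expect_true(all(abs(cm$ssim) <= 1 + 1e-9))
  # constant map: undefined correlation flagged as NA
  cm2 <- cross_method_consistency(list(a = a, k = matrix(1, 20, 20)))
  expect_true(is.na(cm2$spearman["a", "k"]))
})

test_that("ssim equals 1 for identical maps and decreases under noise", {
  set.seed(71)
  a <- matrix(runif(400), 20, 20)
  expect_equal(ssim_map(a, a), 1, tolerance = 1e-12)
  b <- a + matrix(rnorm(400, sd = 0.5), 20, 20)
  expect_lt(ssim_map(a, b), 1)
})

test_that("uncertainty-error report recovers a planted pooled correlation", {
  set.seed(72)
  n_img <- 20
  uncs <- list(); preds <- list(); gts <- list()
  uu <- c(); ee <- c()
  for (i in 1:n_img) {
    gt <- matrix(0, 16, 16); gt[4:10, 4:10] <- 1
    err <- matrix(rbinom(256, 1, 0.15), 16, 16)
    pred <- xor(gt > 0, err > 0) + 0  # pred differs from gt exactly on err
    u <- 0.4 * err + 0.1 * matrix(abs(rnorm(256)), 16, 16)
    uncs[[i]] <- u; preds[[i]] <- pred; gts[[i]] <- gt
    uu <- c(uu, as.vector(u)); ee <- c(ee, as.vector(err))
  }
  rep <- uncertainty_error_report(uncs, preds, gts)
  oracle_r <- cor(uu, ee)  # direct oracle on the constructed vectors
  expect_equal(rep$pooled_r, oracle_r, tolerance = 1e-12)
  expect_gt(rep$pooled_r, 0.5)
  expect_gt(rep$error_correct_ratio, 1)
  expect_gt(rep$cohen_d, 0)
  # perfect association
  rep1 <- uncertainty_error_report(list(matrix(c(0, 1, 0, 1), 2, 2)),
                                   list(matrix(c(0, 1, 0, 1), 2, 2)),
                                   list(matrix(0, 2, 2)))
  expect_equal(rep1$pooled_r, 1)
  # constant uncertainty: NA correlation, unit ratios
  repc <- uncertainty_error_report(list(matrix(0.2, 4, 4)),
                                   list(matrix(rbinom(16, 1, 0.4), 4, 4)),
                                   list(matrix(0, 4, 4)))
  expect_true(is.na(repc$pooled_r))
  expect_equal(repc$error_correct_ratio, 1)
})

test_that("quartile case selection follows rank arithmetic and tie rules", {
  d <- c(a = .1, b = .2, c = .3, d = .4, e = .5, f = .6, g = .7, h = .8)
  sel <- quartile_case_selection(d)
  expect_identical(unname(sel), c("a", "b", "d", "h"))
  # invariant to input ordering
  sel2 <- quartile_case_selection(d[sample(8)])
  expect_identical(sel, sel2)
  # all-equal values: distinct ids by tie-break order
  dd <- setNames(rep(0.5, 5), letters[1:5])
  sel3 <- quartile_case_selection(dd)
  expect_identical(unname(sel3), c("a", "b", "c", "e"))
  expect_error(quartile_case_selection(dd[1:3]), "4")
})

test_that("failure flagging is monotone in the threshold", {
  expect_false(failure_flag(matrix(0, 4, 4), 0.1)$flagged)
  r <- failure_flag(matrix(0.4, 4, 4), 0.3)
  expect_true(r$flagged)
  expect_equal(r$mean_uncertainty, 0.4)
  u <- matrix(runif(64, 0, 0.5), 8, 8)
  ths <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  flags <- vapply(ths, function(t) failure_flag(u, t)$flagged, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
  expect_error(failure_flag(u, 0.7), "threshold")
})
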