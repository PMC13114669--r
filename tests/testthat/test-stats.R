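# Fold aggregation and the paired statistics battery.

test_that("fold_aggregate reproduces t-interval arithmetic", {
  manifest <- data.frame(id = paste0("s", 1:10),
                         fold = rep(1:5, each = 2))
  # identical values: zero spread
  rec <- data.frame(id = manifest$id, dsc = rep(0.9, 10))
  fs <- fold_aggregate(rec, manifest)
  expect_equal(fs$summary$mean, 0.9)
  expect_equal(fs$summary$sd, 0)
  expect_equal(fs$summary$ci_lo, 0.9)
  # constructed fold means [0.89, 0.90, 0.91, 0.90, 0.905]
  vals <- rep(c(0.89, 0.90, 0.91, 0.90, 0.905), each = 2)
  rec2 <- data.frame(id = manifest$id, dsc = vals)
  fs2 <- fold_aggregate(rec2, manifest)
  fm <- c(0.89, 0.90, 0.91, 0.90, 0.905)
  expect_equal(fs2$summary$mean, mean(fm), tolerance = 1e-12)
  expect_equal(fs2$summary$sd, sd(fm), tolerance = 1e-12)
  hw <- qt(0.975, 4) * sd(fm) / sqrt(5)
  expect_equal(fs2$summary$ci_hi - fs2$summary$mean, hw, tolerance = 1e-12)
  expect_equal(qt(0.975, 4), 2.776, tolerance = 1e-3)
  # permutation invariance
  perm <- sample(1:10)
  fs3 <- fold_aggregate(rec2[perm, ], manifest)
  expect_equal(fs3$summary, fs2$summary)
  expect_error(fold_aggregate(data.frame(id = "zz", dsc = 1), manifest),
               "fold assignment")
})

test_that("paired_compare handles degenerate, all-positive and arithmetic cases", {
  a <- c(0.8, 0.85, 0.9, 0.82, 0.88)
  r0 <- paired_compare(a, a)
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$wilcoxon_p, 1)
  expect_true(is.na(r0$cohen_d))
  expect_true(r0$degenerate)
  # n = 5 all-positive differences: exact two-sided p = 2/32
  b <- a + c(0.01, 0.02, 0.03, 0.02, 0.02)
  r1 <- paired_compare(a, b)
  expect_equal(r1$wilcoxon_p, 0.0625, tolerance = 1e-12)
  expect_true(r1$wilcoxon_exact)
  expect_equal(r1$mean_diff, 0.02, tolerance = 1e-12)
  expect_equal(r1$cohen_d, 0.02 / sd(c(0.01, 0.02, 0.03, 0.02, 0.02)),
               tolerance = 1e-12)
  expect_equal(r1$cohen_d, 2.828, tolerance = 1e-3)
  expect_identical(r1$effect_label, "large")
  # Bonferroni multiplier
  r2 <- paired_compare(a, b, bonferroni_m = 4L)
  expect_equal(r2$wilcoxon_p_bonferroni, 0.25, tolerance = 1e-12)
})

test_that("effect-size labels follow the conventional |d| thresholds", {
  lab <- getFromNamespace("effect_size_label", "busseg")
  expect_identical(lab(0.1), "negligible")
  expect_identical(lab(-0.3), "small")
  expect_identical(lab(0.65), "medium")
  expect_identical(lab(-1.2), "large")
})

test_that("exact Wilcoxon p matches full sign enumeration for n <= 10", {
  wsr <- getFromNamespace("wilcoxon_signed_rank", "busseg")
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    # all 2^n sign assignments of the same |d| ranks
    Ws <- vapply(0:(2^n - 1), function(mask) {
      signs <- as.integer(intToBits(mask))[1:n]
      sum(r[signs == 1])
    }, numeric(1))
    p_ge <- mean(Ws >= W)
    p_le <- mean(Ws <= W)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(40)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 1)  # coarse rounding produces frequent ties
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(wsr(d)$p, enum_p(d), tolerance = 1e-12)
  }
})

test_that("friedman_rank matches rank-sum arithmetic and is monotone-invariant", {
  m0 <- matrix(rep(c(1, 2, 3), 6), 6, 3, byrow = TRUE) * 0 + 5
  expect_equal(friedman_rank(m0)$chi2, 0)
  # perfectly consistent ordering over 10 items, 3 models: chi2 = 20
  m1 <- matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE)
  fr <- friedman_rank(m1)
  expect_equal(fr$chi2, 20, tolerance = 1e-12)
  expect_equal(fr$p, pchisq(20, 2, lower.tail = FALSE), tolerance = 1e-12)
  # invariance to monotone per-item transforms
  m2 <- m1
  for (i in 1:10) m2[i, ] <- exp(m1[i, ] * runif(1, 0.5, 2)) + i
  expect_equal(friedman_rank(m2)$chi2, fr$chi2)
  # cross-check against the standard implementation on untied data
  set.seed(41)
  m3 <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(friedman_rank(m3)$chi2,
               unname(friedman.test(m3)$statistic), tolerance = 1e-9)
})

test_that("difficulty_strata recovers a planted small-lesion advantage", {
  set.seed(42)
  n <- 30
  masks <- lapply(1:n, function(i) {
    m <- matrix(0, 20, 20)
    side <- if (i <= 10) 2 else if (i <= 20) 5 else 9
    m[1:side, 1:side] <- 1
    m
  })
  a <- seq(0.7, 0.99, length.out = n)
  b <- a
  b[1:10] <- a[1:10] + 0.01  # boost small-lesion images only
  st <- difficulty_strata(a, b, masks)
  expect_equal(sum(st$n[st$stratum %in% c("small", "medium", "large")]), n)
  expect_equal(st$mean_diff[st$stratum == "small"], 0.01, tolerance = 1e-12)
  expect_equal(st$mean_diff[st$stratum == "medium"], 0, tolerance = 1e-12)
  expect_equal(st$mean_diff[st$stratum == "large"], 0, tolerance = 1e-12)
  # identical models: all zero
  st0 <- difficulty_strata(a, a, masks)
  expect_true(all(st0$mean_diff == 0))
})
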