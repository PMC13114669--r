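# Schedule, augmentation, early stopping, optimization sanity, and the
# cross-validation plumbing.

test_that("the warm-restart schedule reproduces closed-form values for three cycles", {
  lr0 <- 1e-4
  expect_equal(lr_at(0, lr0), lr0)
  expect_equal(lr_at(10, lr0), lr0 / 2, tolerance = 1e-12)
  expect_equal(lr_at(20, lr0), lr0)            # restart, cycle length 40
  expect_equal(lr_at(40, lr0), lr0 / 2)        # mid second cycle
  expect_equal(lr_at(60, lr0), lr0)            # second restart, length 80
  expect_equal(lr_at(100, lr0), lr0 / 2)       # mid third cycle
  # closed form at every epoch across the first three cycles
  starts <- c(0, 20, 60); lens <- c(20, 40, 80)
  for (c in 1:3) {
    for (e in seq(starts[c], starts[c] + lens[c] - 1)) {
      expect_equal(lr_at(e, lr0),
                   lr0 * (1 + cos(pi * (e - starts[c]) / lens[c])) / 2,
                   tolerance = 1e-12)
    }
  }
})

test_that("augmentation preserves the sample contracts", {
  sp <- phantom_spec(image_size = 32L, seed = 8L)
  s <- generate_phantom(sp, 1L)
  # identity draw leaves the sample unchanged
  set.seed(1)
  s_id <- augment_sample(s, flip_p = 0, max_rotate = 0, max_translate = 0,
                         scale_range = c(1, 1))
  expect_identical(s_id$image, s$image)
  expect_identical(s_id$mask, s$mask)
  # flip is an involution
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(flip(flip(s$image)), s$image)
  # arbitrary draws keep the contracts
  set.seed(2)
  for (i in 1:10) {
    a <- augment_sample(s)
    expect_true(all(a$image >= 0 & a$image <= 1))
    expect_true(all(a$mask %in% c(0, 1)))
    expect_identical(dim(a$image), dim(s$image))
  }
})

test_that("early stopping semantics match the forced validation trace", {
  bs <- getFromNamespace("best_and_stop", "busseg")
  r <- bs(c(1.0, 0.9, 0.95, 0.96, 0.97), patience = 2L)
  expect_equal(r$best_epoch, 2L)   # 0.9
  expect_equal(r$stop_epoch, 4L)   # two non-improving epochs after the best
  r2 <- bs(c(1, 0.9, 0.8, 0.7), patience = 2L)
  expect_equal(r2$best_epoch, 4L)
  expect_equal(r2$stop_epoch, 4L)  # never triggered
})

test_that("one-batch overfitting halves the training loss within 50 steps", {
  set.seed(50)
  gs <- tiny_phantoms(2, seed = 31L)
  b <- getFromNamespace("samples_to_batch", "busseg")(gs$samples,
                                                      gs$manifest$id)
  model <- build_model(tiny_cfg(), seed = 2L)
  params <- getFromNamespace("collect_params", "busseg")(model)
  opt <- getFromNamespace("adamw_new", "busseg")(params)
  step <- getFromNamespace("adamw_step", "busseg")
  losses <- numeric(50)
  for (i in 1:50) {
    getFromNamespace("with_tape", "busseg")({
      fw <- model_forward(model, b$x, training = FALSE)
      l <- getFromNamespace("dbr_loss_ag", "busseg")(fw$logits, b$y)
      getFromNamespace("ag_backward", "busseg")(l$total)
    })
    opt <- step(params, opt, 1e-3, 1e-4)
    getFromNamespace("ag_zero_grad", "busseg")(params)
    losses[i] <- getFromNamespace("ag_val", "busseg")(l$total)
  }
  expect_lt(min(losses), 0.5 * losses[1])
})

test_that("a micro cross-validation run is leakage-free and reproducible", {
  gs <- tiny_phantoms(12, seed = 17L)
  tc <- train_config(lr0 = 1e-3, batch_size = 6L, max_epochs = 2L, T0 = 10L,
                     patience = 1L, seed = 5L, augment = FALSE)
  cv <- run_cv(gs$samples, gs$manifest, tiny_cfg(), tc, loss_config())
  expect_equal(nrow(cv$records), 12L)
  # every image is evaluated exactly once, by the model of its own fold
  expect_setequal(cv$records$id, gs$manifest$id)
  for (f in 1:2) {
    ids_f <- gs$manifest$id[gs$manifest$fold == f]
    expect_setequal(cv$records$id[cv$records$fold == f], ids_f)
  }
  # summary means equal hand-averaged per-image values
  hand <- mean(vapply(1:2, function(f)
    mean(cv$records$dsc[cv$records$fold == f]), numeric(1)))
  expect_equal(cv$summary$summary$mean[cv$summary$summary$metric == "dsc"],
               hand, tolerance = 1e-12)
  # best epoch recorded in the history is the argmin of validation loss
  for (h in cv$histories) {
    expect_equal(which.min(h$val_loss),
                 getFromNamespace("best_and_stop", "busseg")(
                   h$val_loss, tc$patience)$best_epoch)
  }
  # identical seed: identical history
  cv2 <- run_cv(gs$samples, gs$manifest, tiny_cfg(), tc, loss_config())
  expect_identical(cv$histories, cv2$histories)
  expect_identical(cv$records, cv2$records)
})

test_that("ablation runs share fold seeds so loss-only variants start identically", {
  gs <- tiny_phantoms(8, seed = 19L)
  tc <- train_config(lr0 = 1e-3, batch_size = 4L, max_epochs = 1L, T0 = 10L,
                     patience = 0.5, seed = 3L, augment = FALSE)
  expect_error(train_config(patience = 100L, max_epochs = 10L), "patience")
  a <- build_variant("full_affm", tiny_cfg(), seed = 4L)
  b <- build_variant("no_dbr_loss", tiny_cfg(), seed = 4L)
  img <- gs$samples[[1]]$image
  expect_equal(predict_prob(a$model, img), predict_prob(b$model, img),
               tolerance = 1e-12)
})
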