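# Network-level contracts: branch shapes, fusion semantics, decoder
# contracts, the variant factory, and structural parameter counts.

ns <- function(f) getFromNamespace(f, "busseg")

test_that("forward produces in-range probabilities and normalized fusion weights", {
  m <- build_model(tiny_cfg(), seed = 1L)
  img <- generate_phantom(phantom_spec(image_size = 32L, seed = 2L), 1L)$image
  fw <- model_forward(m, img)
  expect_identical(dim(fw$prob), c(32L, 32L, 1L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  for (l in 1:4) {
    w <- fw$weights[[l]]
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-6)
  }
  expect_error(model_forward(m, matrix(NaN, 32, 32)), "finite")
  expect_error(model_forward(m, matrix(0.5, 32, 16)), "square")
})

test_that("cnn stages halve resolution and produce the configured widths", {
  m <- build_model(tiny_cfg(), seed = 1L)
  img <- matrix(runif(32 * 32), 32, 32)
  fw <- model_forward(m, img)
  sizes <- c(16L, 8L, 4L, 2L)
  for (l in 1:4) {
    d <- dim(ns("ag_val")(fw$cache$levels[[l]]$cnn))
    expect_identical(d[1:3], c(sizes[l], sizes[l], tiny_cfg()$level_channels[l]))
  }
})

test_that("affm softmax arithmetic: equal logits average, ln 2 shifts to (1/2, 1/4, 1/4)", {
  set.seed(3)
  mk <- ns("make_affm"); fuse <- ns("affm_fuse_fwd")
  agt <- ns("ag_tensor"); val <- ns("ag_val")
  p <- mk(4L, 3L)
  # force the fusion MLP to produce fixed logits via zero weights + bias
  p$mlp2$W$v <- p$mlp2$W$v * 0
  maps <- lapply(1:3, function(i) agt(array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))))
  p$mlp2$b$v <- c(0, 0, 0)
  r <- fuse(maps, p)
  expect_equal(r$weights, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  avg <- (val(maps[[1]]) + val(maps[[2]]) + val(maps[[3]])) / 3
  expect_equal(val(r$fused), avg, tolerance = 1e-12)
  p$mlp2$b$v <- c(log(2), 0, 0)
  r2 <- fuse(maps, p)
  expect_equal(r2$weights[1, ], c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # one-hot override reproduces the selected branch exactly
  r3 <- fuse(maps, p, weight_override = c(1, 0, 0))
  expect_identical(val(r3$fused), val(maps[[1]]))
})

test_that("affm weights are differentiable in the logits (finite differences)", {
  set.seed(4)
  agt <- ns("ag_tensor"); val <- ns("ag_val")
  sm <- ns("ag_softmax_rows"); dot <- ns("ag_dot")
  logits <- matrix(rnorm(6), 2, 3)
  tgt <- matrix(rnorm(6), 2, 3)
  tl <- agt(logits, requires_grad = TRUE)
  ns("with_tape")({
    ns("ag_backward")(dot(sm(tl), tgt))
  })
  gn <- fd_grad(function(x) sum(val(sm(agt(x))) * tgt), logits)
  expect_lt(max(abs(tl$g - gn)) / max(abs(gn)), 1e-3)
})

test_that("fusion alternatives match their defining reductions", {
  set.seed(5)
  mkalt <- ns("make_fusion_alt"); falt <- ns("fuse_alternative_fwd")
  agt <- ns("ag_tensor"); val <- ns("ag_val")
  maps <- lapply(1:3, function(i) agt(array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))))
  # average of identical maps is that map
  same <- falt(list(maps[[1]], maps[[1]], maps[[1]]), list(), "average")
  expect_equal(val(same$fused), val(maps[[1]]), tolerance = 1e-12)
  avg <- falt(maps, list(), "average")
  expect_equal(val(avg$fused),
               (val(maps[[1]]) + val(maps[[2]]) + val(maps[[3]])) / 3,
               tolerance = 1e-12)
  # concat+1x1 conv with a block-averaging kernel equals the plain average
  p <- mkalt(4L, 3L, "concat_conv")
  W <- array(0, c(1, 1, 12, 4))
  for (c in 1:4) for (b in 0:2) W[1, 1, b * 4 + c, c] <- 1 / 3
  p$red$W$v <- W
  p$red$b$v <- p$red$b$v * 0
  cc <- falt(maps, p, "concat_conv")
  expect_equal(val(cc$fused), val(avg$fused), tolerance = 1e-10)
  expect_error(falt(maps, p, "nope"), "unknown")
})

test_that("attention rows are stochastic and constant fields map to constant outputs", {
  set.seed(6)
  mk <- ns("make_transformer_block"); fwd <- ns("transformer_block_fwd")
  agt <- ns("ag_tensor"); val <- ns("ag_val")
  p <- mk(8L, 16L)
  x <- matrix(rnorm(16 * 8), 16, 8)
  r <- fwd(agt(x), p, heads = 2L, N = 1L, dropout = 0, collect_attn = TRUE)
  A <- r$attn[[1]]
  expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-6)
  # constant token field (plus zeroed positional embedding) stays constant
  p$pos$v <- p$pos$v * 0
  xc <- matrix(1.3, 16, 8) * rep(1, 16) %o% rnorm(8)
  rc <- fwd(agt(xc), p, heads = 2L, N = 1L, dropout = 0)
  out <- val(rc$out)
  expect_lt(max(apply(out, 2L, function(cl) diff(range(cl)))), 1e-10)
})

test_that("decoder contracts: full-resolution output, plain decoder is smaller", {
  m <- build_model(tiny_cfg(), seed = 7L)
  img <- matrix(runif(32 * 32), 32, 32)
  fw <- model_forward(m, img)
  expect_identical(dim(ns("ag_val")(fw$logits)), c(32L, 32L, 1L, 1L))
  nodes <- names(fw$cache$decoder_nodes)
  expect_setequal(grep("_0$", nodes, invert = TRUE, value = TRUE),
                  c("X0_1", "X1_1", "X2_1", "X0_2", "X1_2", "X0_3"))
  dense <- build_variant("full_affm", tiny_cfg(), 1L)$model
  plain <- build_variant("no_dense_decoder", tiny_cfg(), 1L)$model
  np <- function(mm) sum(vapply(ns("collect_params")(mm$decoder),
                                function(p) length(p$v), numeric(1)))
  expect_lt(np(plain), np(dense))
})

test_that("all nine variants build and map to their defining configurations", {
  cfgs <- lapply(variant_names(), build_variant, base_config = tiny_cfg(),
                 seed = 1L)
  names(cfgs) <- variant_names()
  expect_identical(cfgs$cnn_only$model$config$branches, "cnn")
  expect_identical(sort(cfgs$cnn_mamba$model$config$branches),
                   c("cnn", "mamba"))
  expect_identical(cfgs$concat_conv$model$config$fusion, "concat_conv")
  expect_identical(cfgs$se_attention$model$config$fusion, "se")
  expect_identical(cfgs$simple_average$model$config$fusion, "average")
  expect_identical(cfgs$no_dense_decoder$model$config$decoder, "plain")
  expect_identical(cfgs$no_dbr_loss$loss_config$lambda_boundary, 0)
  # no_dbr_loss shares the full model architecture parameter-for-parameter
  pa <- ns("param_values")(cfgs$full_affm$model)
  pb <- ns("param_values")(cfgs$no_dbr_loss$model)
  expect_identical(pa, pb)
  expect_error(build_variant("bogus", tiny_cfg()), "arg")
})

test_that("branch removal strictly reduces parameter counts", {
  n <- vapply(variant_names(), function(v)
    n_params(build_variant(v, tiny_cfg(), 1L)$model), numeric(1))
  expect_lt(n[["cnn_only"]], n[["cnn_transformer"]])
  expect_lt(n[["cnn_transformer"]], n[["full_affm"]])
  expect_lt(n[["cnn_mamba"]], n[["full_affm"]])
  expect_lt(n[["simple_average"]], n[["full_affm"]])
})

test_that("cnn_only forward equals the full model with one-hot cnn fusion weights", {
  cfg <- tiny_cfg()
  full <- build_model(cfg, seed = 8L)
  cfg_cnn <- cfg
  cfg_cnn$branches <- "cnn"
  solo <- build_model(cfg_cnn, seed = 9L)
  # copy the shared components (stem, stages, decoder) from the full model
  pf <- ns("collect_params")(full)
  ps <- ns("collect_params")(solo)
  shared <- intersect(names(pf), names(ps))
  shared <- grep("^(stem|stages|decoder)", shared, value = TRUE)
  for (nm in shared) ps[[nm]]$v <- pf[[nm]]$v
  img <- matrix(runif(32 * 32), 32, 32)
  p_full <- model_forward(full, img,
                          weight_override = rep(list(c(1, 0, 0)), 4))$prob
  p_solo <- model_forward(solo, img)$prob
  expect_equal(p_full, p_solo, tolerance = 1e-10)
})

test_that("checkpoints round-trip parameters and predictions", {
  m <- build_model(tiny_cfg(), seed = 10L)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict_prob(m, img)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f, epoch = 3L, best_val_loss = 0.5)
  m2 <- load_checkpoint(f)
  expect_equal(predict_prob(m2, img), p1, tolerance = 1e-12)
  expect_identical(attr(m2, "epoch"), 3L)
})
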