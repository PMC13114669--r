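# Shared fixtures. Heavy objects (the miniature cross-validation run used by
# the end-to-end and uncertainty checks) are built once per session and
# cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  if (is.null(dim(x))) g <- as.numeric(g)
  g
}

tiny_cfg <- function(...) mini_model_config(image_size = 32L, ...)

tiny_phantoms <- function(n, image_size = 32L, k_folds = 2L, seed = 11L) {
  generate_samples(phantom_spec(image_size = image_size, seed = seed,
                                lesion_area_fraction_range = c(0.05, 0.2)),
                   n, k_folds)
}

# the miniature end-to-end protocol: 160 phantoms at 64 px, 2 folds,
# miniature architecture, 5 training epochs
mini_protocol_train_config <- function() mini_train_config()

get_mini_cv <- function() {
  if (!is.null(.fixtures$mini_cv)) return(.fixtures$mini_cv)
  gs <- generate_samples(phantom_spec(image_size = 64L, seed = 42L),
                         160L, k_folds = 2L)
  cv <- run_cv(gs$samples, gs$manifest, mini_model_config(),
               mini_protocol_train_config(), loss_config())
  .fixtures$mini_cv <- list(gs = gs, cv = cv)
  .fixtures$mini_cv
}

# a small trained model for attribution checks (32 px, short training)
get_tiny_trained <- function() {
  if (!is.null(.fixtures$tiny_trained)) return(.fixtures$tiny_trained)
  gs <- tiny_phantoms(24, seed = 5L)
  tr <- train_fold(gs$samples, gs$manifest, 2L, tiny_cfg(),
                   train_config(lr0 = 1e-3, batch_size = 8L, max_epochs = 3L,
                                T0 = 10L, patience = 2L, seed = 3L,
                                augment = FALSE),
                   loss_config())
  .fixtures$tiny_trained <- list(gs = gs, model = tr$model)
  .fixtures$tiny_trained
}
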