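# Model configuration, construction, forward pass, and the ablation-variant
# factory.
#
# Architecture: a CNN-anchored hierarchical parallel encoder. A grayscale
# image passes a 7x7/2 stem; four residual CNN stages produce feature maps at
# 1/2, 1/4, 1/8, 1/16 resolution. At every level the CNN stage output is fed
# in parallel to a Visual State Space block (selective scan over four spatial
# orders) and a pre-norm multi-head self-attention block; the three branch
# maps are fused (adaptive softmax-weighted fusion by default) and the fused
# map feeds the next CNN stage. A dense nested decoder turns the four fused
# maps into a full-resolution logit map.

#' Model configuration
#'
#' @param image_size working resolution in pixels (square); must be a
#'   multiple of 16 so four halvings are exact.
#' @param level_channels 4 strictly increasing channel widths.
#' @param heads_per_level attention heads per level; each must divide the
#'   level's channel width.
#' @param d_state state dimension of the selective SSM.
#' @param expand channel expansion factor inside the VSS block.
#' @param conv_kernel depthwise convolution kernel inside the VSS block.
#' @param mlp_ratio MLP expansion ratio of the attention and VSS blocks.
#' @param dropout dropout rate in the attention block.
#' @param affm_reduction reduction ratio r of the fusion MLP.
#' @param decoder "dense_nested" or "plain".
#' @param fusion "affm", "concat_conv", "se" or "average".
#' @param branches subset of c("cnn","mamba","transformer"); must contain
#'   "cnn" (the anchor branch).
#' @param blocks_per_level residual blocks per CNN stage (ResNet-34 depths by
#'   default).
#' @return a validated list of class "busseg_config".
#' @export
model_config <- function(image_size = 256L,
                         level_channels = c(64L, 128L, 256L, 512L),
                         heads_per_level = c(2L, 4L, 8L, 16L),
                         d_state = 16L, expand = 2L, conv_kernel = 3L,
                         mlp_ratio = 4, dropout = 0.1, affm_reduction = 4L,
                         decoder = c("dense_nested", "plain"),
                         fusion = c("affm", "concat_conv", "se", "average"),
                         branches = c("cnn", "mamba", "transformer"),
                         blocks_per_level = c(3L, 4L, 6L, 3L)) {
  decoder <- match.arg(decoder)
  fusion <- match.arg(fusion)
  stopifnot(length(level_channels) == 4L, length(heads_per_level) == 4L,
            length(blocks_per_level) == 4L)
  if (any(diff(level_channels) <= 0)) stop("level_channels must be strictly increasing")
  if (any(level_channels %% heads_per_level != 0)) {
    stop("heads_per_level must divide level_channels elementwise")
  }
  if (!"cnn" %in% branches) stop("branches must contain the cnn anchor branch")
  if (!all(branches %in% c("cnn", "mamba", "transformer"))) stop("unknown branch")
  if (image_size < 32L || image_size %% 16L != 0L) {
    stop("image_size must be a multiple of 16 and >= 32")
  }
  cfg <- list(image_size = as.integer(image_size),
              level_channels = as.integer(level_channels),
              heads_per_level = as.integer(heads_per_level),
              d_state = as.integer(d_state), expand = as.integer(expand),
              conv_kernel = as.integer(conv_kernel), mlp_ratio = mlp_ratio,
              dropout = dropout, affm_reduction = as.integer(affm_reduction),
              decoder = decoder, fusion = fusion, branches = branches,
              blocks_per_level = as.integer(blocks_per_level))
  class(cfg) <- "busseg_config"
  cfg
}

#' Reduced configuration for desk-scale experiments
#'
#' A miniature of the full architecture (channels 8-64, 64 px working
#' resolution) small enough to train on CPU while exercising every component.
#' @param image_size working resolution (default 64).
#' @param ... overrides passed to \code{\link{model_config}}.
#' @export
mini_model_config <- function(image_size = 64L, ...) {
  args <- list(image_size = image_size,
               level_channels = c(8L, 16L, 32L, 64L),
               heads_per_level = c(1L, 2L, 2L, 4L),
               d_state = 8L,
               blocks_per_level = c(1L, 1L, 1L, 1L))
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

level_sizes <- function(config) config$image_size %/% c(2L, 4L, 8L, 16L)

#' Build a model from a configuration
#'
#' Initializes all parameters with fan-in-scaled random draws under the given
#' seed, so construction is reproducible.
#' @param config a \code{\link{model_config}}.
#' @param seed integer RNG seed for initialization.
#' @return list of class "busseg_model".
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "busseg_config"))
  set.seed(seed)
  ch <- config$level_channels
  sizes <- level_sizes(config)
  nb <- length(config$branches)
  m <- list(config = config, seed = as.integer(seed))
  m$stem <- make_stem(ch[1])
  m$stages <- vector("list", 4L)
  m$vss <- vector("list", 4L)
  m$trans <- vector("list", 4L)
  m$fuse <- vector("list", 4L)
  for (l in 1:4) {
    cin <- if (l == 1L) ch[1] else ch[l - 1L]
    m$stages[[l]] <- make_cnn_stage(cin, ch[l], config$blocks_per_level[l],
                                    first_stride = if (l == 1L) 1L else 2L)
    if ("mamba" %in% config$branches) {
      m$vss[[l]] <- make_vss_block(ch[l], config$d_state, config$expand,
                                   config$conv_kernel, config$mlp_ratio)
    }
    if ("transformer" %in% config$branches) {
      m$trans[[l]] <- make_transformer_block(ch[l], sizes[l]^2, config$mlp_ratio)
    }
    if (nb > 1L) {
      m$fuse[[l]] <- if (config$fusion == "affm") {
        make_affm(ch[l], nb, config$affm_reduction)
      } else {
        make_fusion_alt(ch[l], nb, config$fusion, config$affm_reduction)
      }
    }
  }
  m$decoder <- make_decoder(ch, config$decoder)
  class(m) <- "busseg_model"
  m
}

#' Number of trainable parameters
#' @param model a built model.
#' @export
n_params <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$v), numeric(1)))
}

#' @export
print.busseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<busseg_model> %dpx, channels [%s], branches {%s}, fusion=%s, decoder=%s\n",
    cfg$image_size, paste(cfg$level_channels, collapse = ","),
    paste(cfg$branches, collapse = ","), cfg$fusion, cfg$decoder))
  cat(sprintf("  parameters: %s\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}

# Convert a list of H x W image matrices (or an H x W x N array) to the
# (H, W, 1, N) batch layout.
images_to_batch <- function(images) {
  if (is.list(images)) {
    H <- nrow(images[[1]]); W <- ncol(images[[1]])
    x <- array(0, c(H, W, 1L, length(images)))
    for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
    return(x)
  }
  d <- dim(images)
  if (length(d) == 2L) {
    dim(images) <- c(d[1], d[2], 1L, 1L)
  } else if (length(d) == 3L) {
    images <- array(images, c(d[1], d[2], 1L, d[3]))[, , 1L, , drop = FALSE]
    x <- array(0, c(d[1], d[2], 1L, d[3]))
    x[, , 1L, ] <- images
    images <- x
  }
  images
}

#' Forward pass
#'
#' Runs the triple-branch encoder, per-level fusion and the decoder.
#'
#' @param model a built model.
#' @param x input batch: an (H, W, 1, N) array, an H x W matrix, or a list of
#'   H x W matrices with values in [0, 1].
#' @param training logical; enables dropout (and gradient recording must be
#'   arranged by the caller via the internal tape).
#' @param collect_attn logical; also return head-averaged attention matrices
#'   per level (needed for attention rollout).
#' @param weight_override NULL, or a list of 4 numeric weight vectors (one
#'   per level) pinning the fusion weights instead of the learned softmax;
#'   only valid for affm fusion.
#' @param branch_mask NULL, or a 0/1 vector over branches: learned fusion
#'   weights are multiplied by it and renormalized per sample (used by the
#'   branch-deactivation analysis).
#' @return list with elements \code{logits} (internal tensor), \code{prob}
#'   (H x W x N array of sigmoid probabilities), \code{weights} (list of
#'   per-level N x k fusion-weight matrices, AFFM only), \code{cache}
#'   (per-level branch tensors, decoder node tensors, attention matrices).
#' @export
model_forward <- function(model, x, training = FALSE, collect_attn = FALSE,
                          weight_override = NULL, branch_mask = NULL) {
  x <- images_to_batch(x)
  model_forward_tensor(model, ag_tensor(x), training, collect_attn,
                       weight_override, branch_mask)
}

# Core forward taking an already-wrapped (possibly requires_grad) input
# tensor of shape (H, W, 1, N); used by the attribution layer for input
# gradients.
model_forward_tensor <- function(model, xt, training = FALSE,
                                 collect_attn = FALSE, weight_override = NULL,
                                 branch_mask = NULL) {
  x <- ag_val(xt)
  d <- dim(x)
  if (d[1] != d[2]) stop("input images must be square")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  if (d[1] != model$config$image_size) {
    stop(sprintf("input is %dpx but the model expects %dpx", d[1],
                 model$config$image_size))
  }
  cfg <- model$config
  N <- d[4]
  nb <- length(cfg$branches)
  has_mamba <- "mamba" %in% cfg$branches
  has_trans <- "transformer" %in% cfg$branches
  cur <- stem_fwd(xt, model$stem)
  weights <- vector("list", 4L)
  cache <- list(levels = vector("list", 4L), attn = vector("list", 4L))
  for (l in 1:4) {
    f_cnn <- cnn_stage_fwd(cur, model$stages[[l]])
    hw <- dim(ag_val(f_cnn))[1]
    branch_maps <- list(cnn = f_cnn)
    attn_l <- NULL
    if (has_mamba || has_trans) {
      toks <- ag_to_tokens(f_cnn)
      if (has_mamba) {
        branch_maps$mamba <- ag_from_tokens(
          vss_block_fwd(toks, model$vss[[l]], hw, hw, N), hw, hw, N)
      }
      if (has_trans) {
        tb <- transformer_block_fwd(toks, model$trans[[l]],
                                    cfg$heads_per_level[l], N, cfg$dropout,
                                    training, collect_attn)
        branch_maps$trans <- ag_from_tokens(tb$out, hw, hw, N)
        if (collect_attn) attn_l <- tb$attn
      }
    }
    if (nb == 1L) {
      fused <- f_cnn
    } else if (cfg$fusion == "affm") {
      ov <- if (is.null(weight_override)) NULL else weight_override[[l]]
      fz <- affm_fuse_fwd(unname(branch_maps), model$fuse[[l]], ov, branch_mask)
      fused <- fz$fused
      weights[[l]] <- fz$weights
    } else {
      if (!is.null(weight_override)) {
        stop("weight_override is only supported with affm fusion")
      }
      fz <- fuse_alternative_fwd(unname(branch_maps), model$fuse[[l]], cfg$fusion)
      fused <- fz$fused
    }
    cache$levels[[l]] <- c(branch_maps, list(fused = fused))
    cache$attn[[l]] <- attn_l
    cur <- fused
  }
  dec <- decoder_fwd(lapply(cache$levels, `[[`, "fused"), model$decoder,
                     cfg$image_size)
  prob <- plogis(ag_val(dec$logits))
  dim(prob) <- c(d[1], d[2], N)
  list(logits = dec$logits, prob = prob,
       weights = if (cfg$fusion == "affm" && nb > 1L) weights else NULL,
       cache = c(cache, list(decoder_nodes = dec$nodes)))
}

#' Predict probability maps in evaluation mode
#' @param model a built model.
#' @param x input batch (see \code{\link{model_forward}}).
#' @return H x W x N array of probabilities.
#' @export
predict_prob <- function(model, x) model_forward(model, x, training = FALSE)$prob

# ---- ablation variant factory ----------------------------------------------

#' The nine ablation variant names
#' @export
variant_names <- function() c("full_affm", "cnn_mamba", "cnn_transformer",
                              "cnn_only", "concat_conv", "se_attention",
                              "simple_average", "no_dbr_loss",
                              "no_dense_decoder")

#' Build an ablation variant
#'
#' Maps each variant name to its architecture/loss configuration: branch
#' removals, fusion replacements, the plain decoder, and the plain BCE+Dice
#' loss variant (identical model, loss override only).
#'
#' @param name one of \code{\link{variant_names}}.
#' @param base_config configuration the variant is derived from.
#' @param seed initialization seed.
#' @return list with \code{model}, \code{loss_config} and \code{name}.
#' @export
build_variant <- function(name, base_config = model_config(), seed = 1L) {
  name <- match.arg(name, variant_names())
  cfg <- base_config
  lc <- loss_config()
  if (name == "cnn_mamba") cfg$branches <- c("cnn", "mamba")
  if (name == "cnn_transformer") cfg$branches <- c("cnn", "transformer")
  if (name == "cnn_only") cfg$branches <- "cnn"
  if (name == "concat_conv") cfg$fusion <- "concat_conv"
  if (name == "se_attention") cfg$fusion <- "se"
  if (name == "simple_average") cfg$fusion <- "average"
  if (name == "no_dense_decoder") cfg$decoder <- "plain"
  if (name == "no_dbr_loss") {
    lc <- loss_config(lambda_boundary = 0, w_boundary = 1, w_interior = 1)
  }
  list(name = name, model = build_model(cfg, seed), loss_config = lc)
}

# ---- checkpoints ------------------------------------------------------------

#' Save model parameters and metadata
#' @param model a built model.
#' @param path file path (.rds).
#' @param epoch,best_val_loss optional training metadata.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            best_val_loss = NA_real_) {
  ps <- collect_params(model)
  saveRDS(list(config = model$config, seed = model$seed,
               values = lapply(ps, function(p) p$v),
               epoch = epoch, best_val_loss = best_val_loss), path)
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#' @param path file written by \code{\link{save_checkpoint}}.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, ck$seed)
  ps <- collect_params(model)
  stopifnot(identical(sort(names(ps)), sort(names(ck$values))))
  for (nm in names(ps)) ps[[nm]]$v <- ck$values[[nm]]
  attr(model, "epoch") <- ck$epoch
  attr(model, "best_val_loss") <- ck$best_val_loss
  model
}

# Snapshot/restore parameter values (used for best-epoch selection).
param_values <- function(model) lapply(collect_params(model), function(p) p$v)

set_param_values <- function(model, values) {
  ps <- collect_params(model)
  for (nm in names(values)) ps[[nm]]$v <- values[[nm]]
  invisible(model)
}
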