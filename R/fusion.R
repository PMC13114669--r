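# Branch-fusion modules: the adaptive feature fusion module (AFFM) producing
# per-sample softmax weights over branches, plus the three ablation
# alternatives (concatenation + 1x1 conv, squeeze-excitation, simple average).

make_affm <- function(C, n_branches, reduction = 4L) {
  hid <- max(1L, C %/% reduction)
  list(red = make_conv(1L, n_branches * C, C),
       mlp1 = make_linear(C, hid),
       mlp2 = make_linear(hid, n_branches, sd = sqrt(1 / hid)))
}

# maps: list of (H,W,C,N) tensors. Returns list(fused, weights (N x k matrix),
# logits). weight_override: fixed numeric weight vector (length k) applied to
# every sample instead of the learned softmax weights. branch_mask: 0/1
# vector; learned weights are multiplied by it and renormalized per sample
# (branch-deactivation analysis).
affm_fuse_fwd <- function(maps, p, weight_override = NULL, branch_mask = NULL) {
  k <- length(maps)
  N <- dim(ag_val(maps[[1]]))[4]
  if (!is.null(weight_override)) {
    stopifnot(length(weight_override) == k)
    fused <- ag_scale(maps[[1]], weight_override[1])
    if (k > 1L) for (i in 2:k) {
      fused <- ag_add(fused, ag_scale(maps[[i]], weight_override[i]))
    }
    return(list(fused = fused,
                weights = matrix(weight_override, N, k, byrow = TRUE),
                logits = NULL))
  }
  cat <- ag_concat_chan(maps)
  red <- ag_conv2d(cat, p$red$W, p$red$b, 1L, 0L)
  feats <- ag_transpose(ag_gap(red))            # N x C
  logits <- linear_fwd(ag_relu(linear_fwd(feats, p$mlp1)), p$mlp2)  # N x k
  w <- ag_softmax_rows(logits)
  if (!is.null(branch_mask)) {
    wm <- sweep(ag_val(w), 2L, branch_mask, "*")
    wm <- wm / rowSums(wm)
    w <- ag_tensor(wm)  # analysis mode: detached, renormalized weights
  }
  fused <- ag_scale_sample(maps[[1]], ag_cols(w, 1L))
  for (i in seq_len(k - 1L) + 1L) {
    fused <- ag_add(fused, ag_scale_sample(maps[[i]], ag_cols(w, i)))
  }
  list(fused = fused, weights = ag_val(w), logits = logits)
}

make_fusion_alt <- function(C, n_branches, mode, reduction = 4L) {
  switch(mode,
    average = list(),
    concat_conv = list(red = make_conv(1L, n_branches * C, C)),
    se = {
      hid <- max(1L, C %/% reduction)
      list(red = make_conv(1L, n_branches * C, C),
           se1 = make_linear(C, hid),
           se2 = make_linear(hid, C, sd = sqrt(1 / hid)))
    },
    stop("unknown fusion mode: ", mode))
}

fuse_alternative_fwd <- function(maps, p, mode) {
  k <- length(maps)
  if (mode == "average") {
    fused <- maps[[1]]
    if (k > 1L) for (i in 2:k) fused <- ag_add(fused, maps[[i]])
    return(list(fused = ag_scale(fused, 1 / k), weights = NULL))
  }
  cat <- ag_concat_chan(maps)
  red <- ag_conv2d(cat, p$red$W, p$red$b, 1L, 0L)
  if (mode == "concat_conv") return(list(fused = red, weights = NULL))
  if (mode == "se") {
    feats <- ag_transpose(ag_gap(red))           # N x C
    gates <- ag_sigmoid(linear_fwd(ag_relu(linear_fwd(feats, p$se1)), p$se2))
    return(list(fused = ag_scale_chan(red, ag_transpose(gates)), weights = NULL))
  }
  stop("unknown fusion mode: ", mode)
}
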