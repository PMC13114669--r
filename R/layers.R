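# Parameter constructors and layer forwards for the encoder/decoder blocks.
# All parameters are ag_tensor environments created under the caller's RNG
# state, so model initialization is reproducible from a single seed.

param <- function(v) ag_tensor(v, requires_grad = TRUE)

he_init <- function(dims, fan_in) param(array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims))

make_linear <- function(din, dout, sd = NULL) {
  sd <- if (is.null(sd)) sqrt(2 / din) else sd
  list(W = param(matrix(rnorm(din * dout, sd = sd), din, dout)),
       b = param(numeric(dout)))
}

linear_fwd <- function(x, p) ag_add_rowvec(ag_matmul(x, p$W), p$b)

make_conv <- function(k, cin, cout, bias_init = 0) {
  list(W = he_init(c(k, k, cin, cout), k * k * cin),
       b = param(rep(bias_init, cout)))
}

make_norm <- function(C) list(g = param(rep(1, C)), b = param(numeric(C)))

# at least 4 channels per group so the group statistics stay well-behaved
gn_groups <- function(C) {
  g <- min(8L, C %/% 4L)
  while (g > 1L && C %% g != 0L) g <- g - 1L
  max(1L, g)
}

gn_fwd <- function(x, p) ag_groupnorm(x, p$g, p$b, gn_groups(length(ag_val(p$g))))

ln_fwd <- function(x, p) ag_layernorm_rows(x, p$g, p$b)

# ---- residual CNN stage (ResNet-style basic blocks) -------------------------

make_res_block <- function(cin, cout, stride) {
  p <- list(conv1 = make_conv(3L, cin, cout),
            n1 = make_norm(cout),
            conv2 = make_conv(3L, cout, cout),
            n2 = make_norm(cout),
            stride = stride)
  if (stride != 1L || cin != cout) {
    p$proj <- make_conv(1L, cin, cout)
    p$nproj <- make_norm(cout)
  }
  p
}

res_block_fwd <- function(x, p) {
  h <- ag_relu(gn_fwd(ag_conv2d(x, p$conv1$W, p$conv1$b, p$stride, 1L), p$n1))
  h <- gn_fwd(ag_conv2d(h, p$conv2$W, p$conv2$b, 1L, 1L), p$n2)
  short <- if (!is.null(p$proj)) {
    gn_fwd(ag_conv2d(x, p$proj$W, p$proj$b, p$stride, 0L), p$nproj)
  } else x
  ag_relu(ag_add(h, short))
}

make_cnn_stage <- function(cin, cout, n_blocks, first_stride) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- make_res_block(cin, cout, first_stride)
  for (i in seq_len(n_blocks - 1L)) blocks[[i + 1L]] <- make_res_block(cout, cout, 1L)
  blocks
}

cnn_stage_fwd <- function(x, blocks) {
  for (b in blocks) x <- res_block_fwd(x, b)
  x
}

make_stem <- function(cout) {
  list(conv = make_conv(7L, 1L, cout), n = make_norm(cout))
}

stem_fwd <- function(x, p) ag_relu(gn_fwd(ag_conv2d(x, p$conv$W, p$conv$b, 2L, 3L), p$n))

# ---- transformer block ------------------------------------------------------

make_transformer_block <- function(C, n_tokens, mlp_ratio = 4) {
  hid <- round(C * mlp_ratio)
  list(pos = param(matrix(rnorm(n_tokens * C, sd = 0.02), n_tokens, C)),
       ln1 = make_norm(C),
       qkv = make_linear(C, 3L * C, sd = sqrt(1 / C)),
       proj = make_linear(C, C, sd = sqrt(1 / C)),
       ln2 = make_norm(C),
       mlp1 = make_linear(C, hid),
       mlp2 = make_linear(hid, C, sd = sqrt(1 / hid)))
}

# x: stacked tokens ((T*N) x C), sample-contiguous blocks of T rows.
# Token-wise linear algebra is batched across samples; only the attention
# product is per sample (and per head). Dropout sits on the attention-output
# projection and the MLP (not on the attention weights). Returns list(out,
# attn = per-sample list of head-averaged post-softmax attention matrices
# when collect_attn).
transformer_block_fwd <- function(x, p, heads, N, dropout = 0.1,
                                  training = FALSE, collect_attn = FALSE) {
  C <- ncol(ag_val(x))
  Tn <- nrow(ag_val(x)) %/% N
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  x <- ag_add_tiled(x, p$pos, N)
  h <- ln_fwd(x, p$ln1)
  qkv <- linear_fwd(h, p$qkv)
  attns <- if (collect_attn) vector("list", N) else NULL
  outs <- vector("list", heads)
  for (i in seq_len(heads)) {
    idx <- (i - 1L) * dh + seq_len(dh)
    q <- ag_cols(qkv, idx)
    k <- ag_cols(qkv, C + idx)
    v <- ag_cols(qkv, 2L * C + idx)
    a <- ag_attention(q, k, v, N, 1 / sqrt(dh))
    if (collect_attn) {
      soft <- attr(a, "soft")
      for (n in seq_len(N)) {
        an <- t(soft[, (n - 1L) * Tn + seq_len(Tn), drop = FALSE])
        attns[[n]] <- if (is.null(attns[[n]])) an / heads
                      else attns[[n]] + an / heads
      }
    }
    outs[[i]] <- a
  }
  o <- if (heads == 1L) outs[[1]] else ag_cbind(outs)
  o <- ag_dropout(linear_fwd(o, p$proj), dropout, training)
  x <- ag_add(x, o)
  m <- linear_fwd(ag_gelu(linear_fwd(ln_fwd(x, p$ln2), p$mlp1)), p$mlp2)
  m <- ag_dropout(m, dropout, training)
  list(out = ag_add(x, m), attn = attns)
}
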