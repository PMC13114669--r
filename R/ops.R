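# Differentiable operations. Each op computes its value eagerly and, when a
# tape is active and an input is tracked, registers a backward closure.
# Shapes are strict: elementwise ops require equal shapes or a length-1
# operand; no silent recycling beyond that.

same_or_scalar <- function(a, b) length(a) == 1L || length(b) == 1L ||
  identical(dim(a), dim(b)) || (is.null(dim(a)) && is.null(dim(b)) && length(a) == length(b))

reduce_like <- function(g, v) {
  # gradient of a broadcast length-1 operand
  if (length(v) == 1L) sum(g) else g
}

ag_add <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  stopifnot(same_or_scalar(xv, yv))
  ag_node(xv + yv, list(x, y), function(g) {
    list(reduce_like(g, xv), reduce_like(g, yv))
  })
}

ag_sub <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  stopifnot(same_or_scalar(xv, yv))
  ag_node(xv - yv, list(x, y), function(g) {
    list(reduce_like(g, xv), reduce_like(-g, yv))
  })
}

ag_mul <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  stopifnot(same_or_scalar(xv, yv))
  ag_node(xv * yv, list(x, y), function(g) {
    list(reduce_like(g * yv, xv), reduce_like(g * xv, yv))
  })
}

ag_div <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  stopifnot(same_or_scalar(xv, yv))
  ag_node(xv / yv, list(x, y), function(g) {
    list(reduce_like(g / yv, xv), reduce_like(-g * xv / (yv * yv), yv))
  })
}

ag_scale <- function(x, c) {
  xv <- ag_val(x)
  ag_node(xv * c, list(x), function(g) list(g * c))
}

ag_relu <- function(x) {
  xv <- ag_val(x)
  v <- xv * (xv > 0)
  ag_node(v, list(x), function(g) list(g * (xv > 0)))
}

ag_sigmoid <- function(x) {
  s <- plogis(ag_val(x))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(x) {
  xv <- ag_val(x)
  r <- silu_fwd_cpp(xv)
  ag_node(r$v, list(x), function(g) list(silu_bwd_cpp(g, xv, r$s)))
}

ag_gelu <- function(x) {
  xv <- ag_val(x)
  r <- gelu_fwd_cpp(xv)
  ag_node(r$v, list(x), function(g) list(gelu_bwd_cpp(g, xv, r$p)))
}

ag_softplus <- function(x) {
  xv <- ag_val(x)
  v <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  if (!is.null(dim(xv))) dim(v) <- dim(xv)
  ag_node(v, list(x), function(g) list(g * plogis(xv)))
}

ag_matmul <- function(a, b, transA = FALSE, transB = FALSE) {
  av <- ag_val(a); bv <- ag_val(b)
  v <- if (!transA && !transB) av %*% bv
  else if (transA && !transB) crossprod(av, bv)
  else if (!transA && transB) tcrossprod(av, bv)
  else t(bv %*% av)
  ag_node(v, list(a, b), function(g) {
    ga <- if (!transA && !transB) tcrossprod(g, bv)
    else if (transA && !transB) tcrossprod(bv, g)
    else if (!transA && transB) g %*% bv
    else crossprod(bv, t(g))
    gb <- if (!transA && !transB) crossprod(av, g)
    else if (transA && !transB) av %*% g
    else if (!transA && transB) crossprod(g, av)
    else tcrossprod(t(g), av)
    list(ga, gb)
  })
}

ag_cbind <- function(xs) {
  vs <- lapply(xs, ag_val)
  v <- do.call(cbind, vs)
  ncols <- vapply(vs, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_cols <- function(x, idx) {
  xv <- ag_val(x)
  ag_node(xv[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, idx] <- g
    list(gx)
  })
}

# row permutation (idx is a permutation of 1:nrow)
ag_rows <- function(x, idx) {
  xv <- ag_val(x)
  ag_node(xv[idx, , drop = FALSE], list(x), function(g) {
    list(g[order(idx), , drop = FALSE])
  })
}

ag_reshape <- function(x, dims) {
  xv <- ag_val(x)
  v <- xv
  dim(v) <- dims
  old <- dim(xv)
  ag_node(v, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

# Extract sample n of an (H,W,C,N) array as a (H*W) x C token matrix.
ag_sample_tokens <- function(x, n) {
  xv <- ag_val(x)
  d <- dim(xv)
  v <- xv[, , , n, drop = FALSE]
  dim(v) <- c(d[1] * d[2], d[3])
  ag_node(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , n] <- g
    list(gx)
  })
}

# Recombine per-sample (H*W) x C token matrices into an (H,W,C,N) array.
ag_stack_tokens <- function(xs, H, W) {
  vs <- lapply(xs, ag_val)
  C <- ncol(vs[[1]]); N <- length(xs)
  v <- array(0, c(H, W, C, N))
  for (n in seq_len(N)) v[, , , n] <- vs[[n]]
  ag_node(v, xs, function(g) {
    lapply(seq_len(N), function(n) {
      gn <- g[, , , n, drop = FALSE]
      dim(gn) <- c(H * W, C)
      gn
    })
  })
}

ag_sum <- function(x) {
  xv <- ag_val(x)
  ag_node(sum(xv), list(x), function(g) {
    gx <- array(as.numeric(g), if (is.null(dim(xv))) length(xv) else dim(xv))
    if (is.null(dim(xv))) gx <- as.numeric(gx)
    list(gx)
  })
}

ag_mean <- function(x) ag_scale(ag_sum(x), 1 / length(ag_val(x)))

ag_dot <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  ag_node(sum(xv * yv), list(x, y), function(g) {
    list(as.numeric(g) * yv, as.numeric(g) * xv)
  })
}

ag_softmax_rows <- function(x) {
  xv <- ag_val(x)
  rmax <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - rmax)
  s <- e / rowSums(e)
  ag_node(s, list(x), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

# Row-wise layer normalization of a tokens x channels matrix (compiled).
ag_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  r <- layernorm_fwd_cpp(xv, gv, bv, eps)
  ag_node(r$v, list(x, gamma, beta), function(g) {
    gr <- layernorm_bwd_cpp(g, r$xhat, r$sd, gv)
    list(gr$gx, gr$ggamma, gr$gbeta)
  })
}

# Fused scaled-dot-product attention over N stacked sequences; q,k,v are
# (L*N) x dh single-head matrices. attr(out, "soft") exposes the cached
# softmax (L x L*N, transposed rows) for rollout collection.
ag_attention <- function(q, k, v, N, scale) {
  qv <- ag_val(q); kv <- ag_val(k); vv <- ag_val(v)
  r <- attn_fwd_cpp(qv, kv, vv, N, scale)
  node <- ag_node(r$out, list(q, k, v), function(g) {
    gr <- attn_bwd_cpp(qv, kv, vv, r$soft, g, N, scale)
    list(gr$gQ, gr$gK, gr$gV)
  })
  attr(node, "soft") <- r$soft
  node
}

# Group normalization on an (H,W,C,N) array; gamma/beta length C (compiled
# forward/backward).
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  d <- dim(xv)
  stopifnot(d[3] %% groups == 0L)
  r <- groupnorm_fwd_cpp(xv, d[1], d[2], d[3], d[4], groups, gv, bv, eps)
  ag_node(r$v, list(x, gamma, beta), function(g) {
    gr <- groupnorm_bwd_cpp(g, r$xhat, r$sd, d[1], d[2], d[3], d[4], groups, gv)
    list(gr$gx, gr$ggamma, gr$gbeta)
  })
}

# 2-D convolution via im2col. x (H,W,C,N); w (kh,kw,Cin,Cout); b length Cout.
ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  d <- dim(xv)
  dw <- dim(wv)
  stopifnot(d[3] == dw[3])
  kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  oh <- (d[1] + 2L * pad - kh) %/% stride + 1L
  ow <- (d[2] + 2L * pad - kw) %/% stride + 1L
  cols <- im2col_cpp(xv, d[1], d[2], d[3], d[4], kh, kw, stride, pad)
  wm <- wv
  dim(wm) <- c(kh * kw * d[3], Cout)
  om <- cols %*% wm
  om <- sweep(om, 2L, bv, "+")
  # rows ordered (oy, ox, n) -> array (oh, ow, N, Cout) -> (oh, ow, Cout, N)
  v <- om
  dim(v) <- c(oh, ow, d[4], Cout)
  v <- aperm(v, c(1L, 2L, 4L, 3L))
  ag_node(v, list(x, w, b), function(g) {
    gm <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(gm) <- c(oh * ow * d[4], Cout)
    gcols <- tcrossprod(gm, wm)
    gx <- col2im_cpp(gcols, d[1], d[2], d[3], d[4], kh, kw, stride, pad)
    gw <- crossprod(cols, gm)
    dim(gw) <- dw
    list(gx, gw, colSums(gm))
  })
}

# Depthwise k x k conv, stride 1, same padding. w (k,k,C); b length C.
ag_dwconv <- function(x, w, b) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  d <- dim(xv)
  k <- dim(wv)[1]
  v <- dwconv_fwd_cpp(xv, d[1], d[2], d[3], d[4], wv, bv, k)
  ag_node(v, list(x, w, b), function(g) {
    r <- dwconv_bwd_cpp(xv, g, d[1], d[2], d[3], d[4], wv, k)
    list(r$gx, r$gw, r$gb)
  })
}

# Linear-map bilinear interpolation matrix (out x in), half-pixel centers.
interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    M[, 1] <- 1
    return(M)
  }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  fr <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - fr[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + fr[i]
  }
  M
}

apply_rows_then_cols <- function(x, My, Mx) {
  d <- dim(x)
  oh <- nrow(My); ow <- nrow(Mx)
  m <- x
  dim(m) <- c(d[1], prod(d[-1]))
  a <- My %*% m                     # (oh, W*C*N)
  dim(a) <- c(oh, d[2], d[3], d[4])
  a <- aperm(a, c(2L, 1L, 3L, 4L))  # (W, oh, C, N)
  dim(a) <- c(d[2], oh * d[3] * d[4])
  bm <- Mx %*% a                    # (ow, oh*C*N)
  dim(bm) <- c(ow, oh, d[3], d[4])
  aperm(bm, c(2L, 1L, 3L, 4L))
}

ag_resize_bilinear <- function(x, oh, ow) {
  xv <- ag_val(x)
  d <- dim(xv)
  My <- interp_matrix(oh, d[1])
  Mx <- interp_matrix(ow, d[2])
  v <- apply_rows_then_cols(xv, My, Mx)
  ag_node(v, list(x), function(g) {
    list(apply_rows_then_cols(g, t(My), t(Mx)))
  })
}

# Global average pool (H,W,C,N) -> (C,N) matrix.
ag_gap <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  m <- xv
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  v <- matrix(colMeans(m), d[3], d[4])
  ag_node(v, list(x), function(g) {
    gx <- array(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]), d)
    list(gx)
  })
}

# Multiply each sample's map by a per-sample scalar: x (H,W,C,N), s length N.
ag_scale_sample <- function(x, s) {
  xv <- ag_val(x); sv <- as.numeric(ag_val(s))
  d <- dim(xv)
  sarr <- array(rep(sv, each = prod(d[1:3])), d)
  ag_node(xv * sarr, list(x, s), function(g) {
    gs <- g * xv
    dim(gs) <- c(prod(d[1:3]), d[4])
    list(g * sarr, colSums(gs))
  })
}

# Multiply channels per sample: x (H,W,C,N), s (C,N).
ag_scale_chan <- function(x, s) {
  xv <- ag_val(x); sv <- ag_val(s)
  d <- dim(xv)
  sarr <- array(rep(as.numeric(sv), each = d[1] * d[2]), d)
  ag_node(xv * sarr, list(x, s), function(g) {
    gsm <- g * xv
    dim(gsm) <- c(d[1] * d[2], d[3] * d[4])
    gs <- matrix(colSums(gsm), d[3], d[4])
    list(g * sarr, gs)
  })
}

ag_concat_chan <- function(xs) {
  vs <- lapply(xs, ag_val)
  d1 <- dim(vs[[1]])
  Cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  v <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  at <- 0L
  for (i in seq_along(vs)) {
    v[, , at + seq_len(Cs[i]), ] <- vs[[i]]
    at <- at + Cs[i]
  }
  ends <- cumsum(Cs)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , starts[i]:ends[i], , drop = FALSE])
  })
}

ag_dropout <- function(x, p, training) {
  xv <- ag_val(x)
  if (!training || p <= 0) return(ag_node(xv, list(x), function(g) list(g)))
  keep <- (runif(length(xv)) >= p) / (1 - p)
  if (!is.null(dim(xv))) dim(keep) <- dim(xv)
  ag_node(xv * keep, list(x), function(g) list(g * keep))
}

# Fused selective-scan op over one sequence (see src/kernels.cpp).
ag_ssm_scan <- function(u, delta, B, C, A, Dskip) {
  uv <- ag_val(u); dv <- ag_val(delta); Bv <- ag_val(B)
  Cv <- ag_val(C); Av <- ag_val(A); Dv <- ag_val(Dskip)
  r <- ssm_scan_fwd_cpp(uv, dv, Bv, Cv, Av, Dv)
  ag_node(r$y, list(u, delta, B, C, A, Dskip), function(g) {
    gr <- ssm_scan_bwd_cpp(uv, dv, Bv, Cv, Av, Dv, r$h, r$abar, r$phi, g)
    list(gr$gu, gr$gdelta, gr$gB, gr$gC, gr$gA, gr$gD)
  })
}

# Weighted binary cross-entropy from logits (numerically stable, fused).
# target and weights are plain arrays; normalizes by sum of weights.
ag_wbce_logits <- function(logits, target, weights) {
  zv <- ag_val(logits)
  sw <- sum(weights)
  bce <- pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))
  v <- sum(weights * bce) / sw
  ag_node(v, list(logits), function(g) {
    list(as.numeric(g) * weights * (plogis(zv) - target) / sw)
  })
}

ag_transpose <- function(x) {
  xv <- ag_val(x)
  ag_node(t(xv), list(x), function(g) list(t(g)))
}

ag_exp <- function(x) {
  v <- exp(ag_val(x))
  ag_node(v, list(x), function(g) list(g * v))
}

# add a length-ncol row vector to every row of a matrix
ag_add_rowvec <- function(x, b) {
  xv <- ag_val(x); bv <- ag_val(b)
  ag_node(sweep(xv, 2L, bv, "+"), list(x, b), function(g) {
    list(g, colSums(g))
  })
}

# (H,W,C,N) -> stacked token matrix ((H*W*N) x C); rows are grouped by
# sample: row = hw + H*W*(n-1).
ag_to_tokens <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  v <- aperm(xv, c(1L, 2L, 4L, 3L))
  dim(v) <- c(d[1] * d[2] * d[4], d[3])
  ag_node(v, list(x), function(g) {
    dim(g) <- c(d[1], d[2], d[4], d[3])
    list(aperm(g, c(1L, 2L, 4L, 3L)))
  })
}

ag_from_tokens <- function(x, H, W, N) {
  xv <- ag_val(x)
  C <- ncol(xv)
  v <- xv
  dim(v) <- c(H, W, N, C)
  v <- aperm(v, c(1L, 2L, 4L, 3L))
  ag_node(v, list(x), function(g) {
    g <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(g) <- c(H * W * N, C)
    list(g)
  })
}

# contiguous row block of a matrix
ag_rowrange <- function(x, from, to) {
  xv <- ag_val(x)
  ag_node(xv[from:to, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[from:to, ] <- g
    list(gx)
  })
}

# add a (T x C) parameter to each of N stacked sample blocks
ag_add_tiled <- function(x, pos, N) {
  xv <- ag_val(x); pv <- ag_val(pos)
  Tn <- nrow(pv)
  tile <- pv[rep(seq_len(Tn), N), , drop = FALSE]
  ag_node(xv + tile, list(x, pos), function(g) {
    gp <- g
    dim(gp) <- c(Tn, N, ncol(pv))
    list(g, colSums(aperm(gp, c(2L, 1L, 3L))))
  })
}

ag_rbind <- function(xs) {
  vs <- lapply(xs, ag_val)
  v <- do.call(rbind, vs)
  nrows <- vapply(vs, nrow, integer(1))
  ends <- cumsum(nrows)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# Fused stacked-batch selective scan: N independent sequences stored as
# sample-contiguous row blocks.
ag_ssm_scan_batch <- function(u, delta, B, C, A, Dskip, N) {
  uv <- ag_val(u); dv <- ag_val(delta); Bv <- ag_val(B)
  Cv <- ag_val(C); Av <- ag_val(A); Dv <- ag_val(Dskip)
  r <- ssm_scan_fwd_batch_cpp(uv, dv, Bv, Cv, Av, Dv, N)
  ag_node(r$y, list(u, delta, B, C, A, Dskip), function(g) {
    gr <- ssm_scan_bwd_batch_cpp(uv, dv, Bv, Cv, Av, Dv, r$h, r$abar, g, N)
    list(gr$gu, gr$gdelta, gr$gB, gr$gC, gr$gA, gr$gD)
  })
}
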