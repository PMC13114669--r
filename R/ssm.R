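# Selective state-space machinery: zero-order-hold discretization, the
# selective (S6) scan, and the Visual State Space (VSS) block that applies
# four-directional scans to 2-D feature maps.

#' Zero-order-hold discretization of a continuous state-space system
#'
#' Converts continuous parameters (A, B) and a step size delta into their
#' discrete counterparts: \code{Abar = exp(delta * A)} and
#' \code{Bbar = (delta A)^{-1} (exp(delta A) - I) delta B}, evaluated
#' elementwise for the diagonal state-transition convention used by selective
#' state-space models. The \code{Bbar} factor \code{(exp(z)-1)/z} is computed
#' with \code{expm1} so it is continuous through \code{z = 0} (where it
#' reduces to the limit \code{Bbar = delta * B}).
#'
#' @param A numeric array of continuous state-transition coefficients
#'   (per-channel diagonal entries).
#' @param B numeric array of input coefficients, broadcastable against
#'   \code{A * delta}.
#' @param delta positive step size(s).
#' @return list with elements \code{Abar} and \code{Bbar}.
#' @examples
#' zoh_discretize(-1, 1, 1)  # Abar = exp(-1), Bbar = 1 - exp(-1)
#' @export
zoh_discretize <- function(A, B, delta) {
  if (any(delta <= 0)) stop("delta must be positive")
  z <- delta * A
  abar <- exp(z)
  phi <- ifelse(abs(z) < 1e-12, 1, expm1(z) / ifelse(z == 0, 1, z))
  list(Abar = abar, Bbar = phi * delta * B)
}

#' Selective state-space scan
#'
#' Runs the discrete recurrence \code{h_t = Abar_t h_{t-1} + Bbar_t x_t},
#' \code{y_t = C_t h_t (+ D x_t)} over a token sequence, with per-token step
#' sizes and input/output matrices (the selective parameterization: delta, B
#' and C vary along the sequence). Discretization follows
#' \code{\link{zoh_discretize}} elementwise; the initial state is zero.
#'
#' @param x numeric matrix, length-L sequence of D-channel tokens (L x D).
#' @param A continuous state-transition matrix (D x n_state), typically
#'   negative.
#' @param B per-token input coefficients (L x n_state).
#' @param C per-token output coefficients (L x n_state).
#' @param delta per-token positive step sizes (L x D).
#' @param D_skip optional length-D direct feed-through term (default zero).
#' @return L x D matrix of outputs.
#' @examples
#' # A -> 0 limit with delta = 1, B = C = 1 accumulates a running sum
#' y <- selective_scan(matrix(c(1, 2, 3)), matrix(0, 1, 1),
#'                     matrix(1, 3, 1), matrix(1, 3, 1), matrix(1, 3, 1))
#' stopifnot(all.equal(as.numeric(y), c(1, 3, 6)))
#' @export
selective_scan <- function(x, A, B, C, delta, D_skip = NULL) {
  x <- as.matrix(x); A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  delta <- as.matrix(delta)
  L <- nrow(x); Dd <- ncol(x)
  if (L < 1L) stop("sequence length must be >= 1")
  if (any(delta <= 0)) stop("delta must be positive")
  stopifnot(nrow(A) == Dd, nrow(B) == L, nrow(C) == L,
            ncol(B) == ncol(A), ncol(C) == ncol(A),
            nrow(delta) == L, ncol(delta) == Dd)
  if (is.null(D_skip)) D_skip <- numeric(Dd)
  ssm_scan_fwd_cpp(x, delta, B, C, A, as.numeric(D_skip))$y
}

# Four flattening orders of an H x W token grid stored column-major
# (token index = h + H * (w - 1)): down columns, up columns, along rows,
# backwards along rows.
scan_orders <- function(H, W) {
  Tn <- H * W
  colmaj <- seq_len(Tn)
  rowmaj <- as.vector(t(matrix(colmaj, H, W)))
  list(colmaj, rev(colmaj), rowmaj, rev(rowmaj))
}

# ---- VSS block --------------------------------------------------------------

make_vss_block <- function(C, d_state, expand = 2L, conv_kernel = 3L,
                           mlp_ratio = 4) {
  D <- expand * C
  dt_rank <- max(1L, ceiling(D / 16))
  dirs <- lapply(1:4, function(k) {
    dt0 <- exp(runif(D, log(1e-3), log(0.1)))
    list(Wx = param(matrix(rnorm(D * (dt_rank + 2L * d_state), sd = sqrt(1 / D)),
                           D, dt_rank + 2L * d_state)),
         Wdt = param(matrix(rnorm(dt_rank * D, sd = sqrt(1 / dt_rank)) * 0.1,
                            dt_rank, D)),
         bdt = param(log(expm1(dt0))),     # softplus^-1 of the initial dt
         A_log = param(matrix(log(rep(seq_len(d_state), each = D)), D, d_state)),
         Dskip = param(rep(1, D)))
  })
  hid <- round(C * mlp_ratio)
  list(C = C, D = D, d_state = d_state, dt_rank = dt_rank, k = conv_kernel,
       ln1 = make_norm(C),
       in_proj = make_linear(C, 2L * D, sd = sqrt(1 / C)),
       dw = list(W = param(array(rnorm(conv_kernel^2 * D,
                                       sd = sqrt(2 / conv_kernel^2)),
                                 c(conv_kernel, conv_kernel, D))),
                 b = param(numeric(D))),
       dirs = dirs,
       out_ln = make_norm(D),
       out_proj = make_linear(D, C, sd = sqrt(1 / D)),
       ln2 = make_norm(C),
       mlp1 = make_linear(C, hid),
       mlp2 = make_linear(hid, C, sd = sqrt(1 / hid)))
}

# x: stacked tokens ((T*N) x C), sample-contiguous blocks of T rows, on an
# H x W grid. Token-wise linear algebra is batched across samples; the scan
# itself runs per sample per direction.
vss_block_fwd <- function(x, p, H, W, N) {
  D <- p$D; S <- p$d_state; dtr <- p$dt_rank
  Tn <- H * W
  r <- ln_fwd(x, p$ln1)
  xz <- linear_fwd(r, p$in_proj)
  xp <- ag_cols(xz, seq_len(D))
  z <- ag_cols(xz, D + seq_len(D))
  x4 <- ag_from_tokens(xp, H, W, N)
  u <- ag_to_tokens(ag_silu(ag_dwconv(x4, p$dw$W, p$dw$b)))
  orders <- scan_orders(H, W)
  ys <- vector("list", 4L)
  for (k in 1:4) {
    d <- p$dirs[[k]]
    stacked_perm <- as.integer(outer(orders[[k]], (seq_len(N) - 1L) * Tn, "+"))
    uk <- ag_rows(u, stacked_perm)
    pr <- ag_matmul(uk, d$Wx)
    dt_raw <- ag_cols(pr, seq_len(dtr))
    Bk <- ag_cols(pr, dtr + seq_len(S))
    Ck <- ag_cols(pr, dtr + S + seq_len(S))
    delta <- ag_softplus(ag_add_rowvec(ag_matmul(dt_raw, d$Wdt), d$bdt))
    A <- ag_scale(ag_exp(d$A_log), -1)
    yk <- ag_ssm_scan_batch(uk, delta, Bk, Ck, A, d$Dskip, N)
    ys[[k]] <- ag_rows(yk, order(stacked_perm))
  }
  y <- ag_scale(ag_add(ag_add(ys[[1]], ys[[2]]), ag_add(ys[[3]], ys[[4]])), 0.25)
  y <- ln_fwd(y, p$out_ln)
  y <- ag_mul(y, ag_silu(z))
  x <- ag_add(x, linear_fwd(y, p$out_proj))
  m <- linear_fwd(ag_gelu(linear_fwd(ln_fwd(x, p$ln2), p$mlp1)), p$mlp2)
  ag_add(x, m)
}
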