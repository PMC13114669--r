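# Decoders. The dense nested decoder builds U-Net++-style nodes X(i,j) for
# i + j <= 3, j >= 1, where X(i,j) receives the upsampled X(i+1, j-1)
# concatenated with X(i, 0), ..., X(i, j-1); node widths equal the encoder
# width of row i. The plain decoder keeps only the single chain X(i,1)
# (classic U-Net), used by the no-dense-decoder ablation.

make_decoder_node <- function(cin, cout) {
  list(conv1 = make_conv(3L, cin, cout), n1 = make_norm(cout))
}

decoder_node_fwd <- function(x, p) {
  ag_relu(gn_fwd(ag_conv2d(x, p$conv1$W, p$conv1$b, 1L, 1L), p$n1))
}

make_decoder <- function(channels, mode = c("dense_nested", "plain")) {
  mode <- match.arg(mode)
  nodes <- list()
  if (mode == "dense_nested") {
    for (j in 1:3) {
      for (i in 0:(3 - j)) {
        cin <- channels[i + 2L] + j * channels[i + 1L]
        nodes[[sprintf("X%d_%d", i, j)]] <- make_decoder_node(cin, channels[i + 1L])
      }
    }
    head_in <- channels[1]
  } else {
    for (i in 2:0) {
      cin <- channels[i + 2L] + channels[i + 1L]
      nodes[[sprintf("X%d_1", i)]] <- make_decoder_node(cin, channels[i + 1L])
    }
    head_in <- channels[1]
  }
  list(mode = mode, nodes = nodes,
       head = make_conv(1L, head_in, 1L, bias_init = -2))
}

# features: list of 4 fused (H,W,C,N) tensors at 1/2 .. 1/16 resolution.
# Returns list(logits at full input resolution, nodes = named list of node
# output tensors for the XAI layer).
decoder_fwd <- function(features, p, out_size) {
  up <- function(x) {
    d <- dim(ag_val(x))
    ag_resize_bilinear(x, 2L * d[1], 2L * d[2])
  }
  X <- list()
  for (i in 0:3) X[[key <- sprintf("X%d_0", i)]] <- features[[i + 1L]]
  if (p$mode == "dense_nested") {
    for (j in 1:3) {
      for (i in 0:(3 - j)) {
        inputs <- c(list(up(X[[sprintf("X%d_%d", i + 1L, j - 1L)]])),
                    lapply(0:(j - 1L), function(jj) X[[sprintf("X%d_%d", i, jj)]]))
        X[[sprintf("X%d_%d", i, j)]] <-
          decoder_node_fwd(ag_concat_chan(inputs), p$nodes[[sprintf("X%d_%d", i, j)]])
      }
    }
    top <- X[["X0_3"]]
  } else {
    prev <- X[["X3_0"]]
    for (i in 2:0) {
      inp <- ag_concat_chan(list(up(prev), X[[sprintf("X%d_0", i)]]))
      prev <- decoder_node_fwd(inp, p$nodes[[sprintf("X%d_1", i)]])
      X[[sprintf("X%d_1", i)]] <- prev
    }
    top <- X[["X0_1"]]
  }
  logits <- ag_conv2d(top, p$head$W, p$head$b, 1L, 0L)
  logits <- ag_resize_bilinear(logits, out_size, out_size)
  list(logits = logits, nodes = X)
}
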