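# Minimal tape-based reverse-mode autodiff over dense R arrays.
#
# A tensor is an environment holding $v (value array/matrix/scalar), $g
# (accumulated gradient, NULL until backward touches it), $tracked (whether it
# participates in the current tape), and for op outputs a $bw closure plus
# $parents. The tape is a flat list in creation order; backward() walks it in
# reverse. Ops only record when a tape is active, so evaluation-mode forward
# passes carry no graph overhead.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tensor <- function(v, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$g <- NULL
  t$requires_grad <- requires_grad
  t$tracked <- FALSE
  t$bw <- NULL
  class(t) <- "ag_tensor"
  t
}

is_tensor <- function(x) inherits(x, "ag_tensor")

ag_val <- function(x) if (is_tensor(x)) x$v else x

ag_recording <- function() !is.null(.ag$tape)

ag_tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_tape_push <- function(node) {
  tp <- .ag$tape
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- node
  tp$n <- n
  invisible(node)
}

#' Run an expression while recording an autodiff tape
#' @noRd
with_tape <- function(expr) {
  old <- .ag$tape
  .ag$tape <- ag_tape_new()
  on.exit(.ag$tape <- old)
  expr
}

ag_tracked <- function(x) {
  is_tensor(x) && (x$tracked || (x$requires_grad && ag_recording()))
}

# Register an op node. parents: list of tensors (constants may be plain
# arrays and are skipped). bw: function(g) -> list of gradients aligned with
# parents (NULL entries allowed for untracked parents).
ag_node <- function(v, parents, bw) {
  out <- ag_tensor(v)
  if (ag_recording() && any(vapply(parents, ag_tracked, logical(1)))) {
    out$tracked <- TRUE
    out$parents <- parents
    out$bw <- bw
    ag_tape_push(out)
  }
  out
}

ag_accum <- function(p, g) {
  if (!is.null(g) && is_tensor(p) && (p$tracked || p$requires_grad)) {
    p$g <- if (is.null(p$g)) g else p$g + g
  }
  invisible(NULL)
}

#' Reverse sweep from a scalar tensor
#'
#' retain = TRUE keeps every node gradient on the tensors (needed when
#' intermediate activations are inspected, e.g. CAM attributions); the
#' default frees them eagerly to bound training memory.
#' @noRd
ag_backward <- function(loss, retain = FALSE) {
  stopifnot(is_tensor(loss), length(loss$v) == 1L)
  tp <- .ag$tape
  if (is.null(tp)) stop("ag_backward() called with no active tape")
  loss$g <- 1
  for (i in seq(tp$n, 1L)) {
    node <- tp$nodes[[i]]
    if (is.null(node$g) || is.null(node$bw)) next
    grads <- node$bw(node$g)
    for (j in seq_along(node$parents)) ag_accum(node$parents[[j]], grads[[j]])
    if (!retain) node$g <- NULL  # free intermediate gradients eagerly
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# Flatten a nested list of tensors into a flat named list of parameters.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (is_tensor(x)) {
    out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      sub <- collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", key))
      out <- c(out, sub)
    }
  }
  out
}
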