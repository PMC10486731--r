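# Minimal reverse-mode automatic differentiation over R arrays.
#
# Values live in environments ("ag" nodes) so gradients accumulate in place.
# Every op records its parents and a backward closure; ag_backward() replays
# the tape in reverse creation order. Gradient recording can be switched off
# for inference (ag_no_grad), in which case ops return value-only nodes.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0
.ag$grad_on <- TRUE

ag_node <- function(value, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- FALSE
  track <- .ag$grad_on && !is.null(bw) &&
    any(vapply(parents, function(p) p$requires_grad || !is.null(p$bw), logical(1)))
  if (track) {
    .ag$id <- .ag$id + 1
    e$id <- .ag$id
    e$parents <- parents
    e$bw <- bw
  } else {
    e$id <- 0
    e$parents <- list()
    e$bw <- NULL
  }
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- TRUE
  e$parents <- list()
  e$bw <- NULL
  .ag$id <- .ag$id + 1
  e$id <- .ag$id
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_const <- function(x) if (is_ag(x)) x else ag_node(x)

#' @noRd
ag_no_grad <- function(expr) {
  old <- .ag$grad_on
  .ag$grad_on <- FALSE
  on.exit(.ag$grad_on <- old)
  force(expr)
}

# Backpropagate from a scalar node. Accumulates into $grad of every
# reachable node (parameters included).
ag_backward <- function(root) {
  stopifnot(is_ag(root))
  .ag$visit <- (.ag$visit %||% 0) + 1
  mark <- .ag$visit
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  stack <- vector("list", 256L)
  stack[[1L]] <- root
  top <- 1L
  while (top > 0L) {
    n <- stack[[top]]
    top <- top - 1L
    if (n$id == 0 || identical(n$seen, mark)) next
    n$seen <- mark
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- n
    for (p in n$parents) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[[top]] <- p
    }
  }
  nodes <- nodes[seq_len(n_nodes)]
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  root$grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  for (n in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (i in seq_along(n$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    n$grad <- NULL  # free intermediate gradients eagerly
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
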