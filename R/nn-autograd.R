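# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A node is an environment holding a value, its parent nodes and a backward
# closure mapping the node's output gradient to a list of parent gradients.
# Graphs are built define-by-run during a forward pass; ag_backward() walks
# the tape in reverse topological order and accumulates gradients.
# In evaluation mode ops are called with training = FALSE and record nothing.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  node$id <- ag_id()
  class(node) <- "ag_node"
  node
}

# Trainable parameter: a leaf node whose gradient the optimizer consumes.
ag_param <- function(value) ag_node(value)

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Reverse-mode sweep from `root`, seeding with `grad` (d loss / d root).
ag_backward <- function(root, grad) {
  # iterative DFS post-order for a reverse topological ordering
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    } else if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
        }
      }
    }
  }
  root$grad <- grad
  for (i in seq_len(n_ord)) {
    node <- order[[n_ord - i + 1L]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- node$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!identical(node, root)) node$grad <- NULL  # release memory early
  }
  invisible(NULL)
}
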