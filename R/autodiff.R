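# Reverse-mode automatic differentiation over dense numeric matrices.
#
# Every differentiable quantity is an `adnode`: an environment holding a
# numeric matrix `value`, the parent nodes it was computed from, and one
# backward closure per parent mapping the output cotangent to that parent's
# cotangent. All op helpers (`ad_*`) accept plain matrices as well; when no
# argument is a node they return a plain matrix, so the same forward code
# serves both training (gradients) and evaluation (numbers).

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

#' Test whether an object is an autodiff node
#' @param x object
#' @return logical scalar
#' @keywords internal
#' @export
is_adnode <- function(x) inherits(x, "adnode")

#' Numeric value of a node or matrix
#'
#' @param x an `adnode` or numeric vector/matrix.
#' @return a numeric matrix (vectors become single-column matrices).
#' @export
ad_value <- function(x) {
  if (is_adnode(x)) return(x$value)
  if (is.matrix(x)) x else as.matrix(x)
}

ad_new_node <- function(value, parents = list(), backs = list()) {
  stopifnot(length(parents) == length(backs))
  node <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  node$id <- .ad$counter
  node$value <- value
  node$parents <- parents
  node$backs <- backs
  node$grad <- NULL
  class(node) <- "adnode"
  node
}

#' Wrap a matrix as a leaf node (parameter or constant)
#' @param x numeric vector or matrix
#' @return an `adnode` leaf
#' @export
ad_param <- function(x) ad_new_node(ad_value(x))

#' Detach a value from the tape
#' @param x node or matrix
#' @return plain numeric matrix (constant from the tape's point of view)
#' @export
ad_detach <- function(x) ad_value(x)

#' @export
print.adnode <- function(x, ...) {
  cat(sprintf("<adnode %dx%d id=%d>\n", nrow(x$value), ncol(x$value), x$id))
  invisible(x)
}

# Build an op node; `args` may mix nodes and plain matrices. `backs_all` is a
# list of backward closures aligned with `args`; closures for non-node args
# are dropped.
ad_make <- function(out, args, backs_all) {
  keep <- vapply(args, is_adnode, logical(1))
  if (!any(keep)) return(out)
  ad_new_node(out, parents = args[keep], backs = backs_all[keep])
}

# reduce a cotangent to the shape of the (possibly scalar) argument
ad_fit_shape <- function(g, v) {
  if (length(v) == 1L && length(g) > 1L) matrix(sum(g), 1L, 1L) else g
}

#' Elementwise addition (equal shapes or scalar broadcast)
#' @param a,b nodes or matrices
#' @export
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- if (length(av) == 1L) av[1L] + bv else if (length(bv) == 1L) av + bv[1L] else av + bv
  ad_make(out, list(a, b), list(
    function(g) ad_fit_shape(g, av),
    function(g) ad_fit_shape(g, bv)
  ))
}

#' Elementwise subtraction
#' @param a,b nodes or matrices
#' @export
ad_sub <- function(a, b) ad_add(a, ad_neg(b))

#' Elementwise negation
#' @param a node or matrix
#' @export
ad_neg <- function(a) {
  av <- ad_value(a)
  ad_make(-av, list(a), list(function(g) -g))
}

#' Elementwise product (equal shapes or scalar broadcast)
#' @param a,b nodes or matrices
#' @export
ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- if (length(av) == 1L) av[1L] * bv else if (length(bv) == 1L) av * bv[1L] else av * bv
  ad_make(out, list(a, b), list(
    function(g) ad_fit_shape(if (length(bv) == 1L) g * bv[1L] else g * bv, av),
    function(g) ad_fit_shape(if (length(av) == 1L) g * av[1L] else g * av, bv)
  ))
}

#' Matrix product
#' @param a,b nodes or matrices with conforming dimensions
#' @export
ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av %*% bv, list(a, b), list(
    function(g) g %*% t(bv),
    function(g) t(av) %*% g
  ))
}

#' Matrix transpose
#' @param a node or matrix
#' @export
ad_t <- function(a) ad_make(t(ad_value(a)), list(a), list(function(g) t(g)))

#' Elementwise exponential
#' @param a node or matrix
#' @export
ad_exp <- function(a) {
  ev <- exp(ad_value(a))
  ad_make(ev, list(a), list(function(g) g * ev))
}

#' Elementwise natural logarithm
#' @param a node or matrix (positive entries)
#' @export
ad_log <- function(a) {
  av <- ad_value(a)
  ad_make(log(av), list(a), list(function(g) g / av))
}

#' Elementwise square root
#' @param a node or matrix (non-negative entries)
#' @export
ad_sqrt <- function(a) {
  sv <- sqrt(ad_value(a))
  ad_make(sv, list(a), list(function(g) g / (2 * sv)))
}

#' Elementwise hyperbolic tangent
#' @param a node or matrix
#' @export
ad_tanh <- function(a) {
  tv <- tanh(ad_value(a))
  ad_make(tv, list(a), list(function(g) g * (1 - tv^2)))
}

#' Elementwise reciprocal
#' @param a node or matrix (non-zero entries)
#' @export
ad_recip <- function(a) {
  av <- ad_value(a)
  ad_make(1 / av, list(a), list(function(g) -g / av^2))
}

#' Sum of all entries
#' @param a node or matrix
#' @return 1x1 node/matrix
#' @export
ad_sum <- function(a) {
  av <- ad_value(a)
  ad_make(matrix(sum(av), 1L, 1L), list(a),
          list(function(g) matrix(g[1L], nrow(av), ncol(av))))
}

#' Mean of all entries
#' @param a node or matrix
#' @return 1x1 node/matrix
#' @export
ad_mean <- function(a) {
  av <- ad_value(a)
  n <- length(av)
  ad_make(matrix(mean(av), 1L, 1L), list(a),
          list(function(g) matrix(g[1L] / n, nrow(av), ncol(av))))
}

#' Row sums as a column matrix
#' @param a node or matrix
#' @export
ad_rowsums <- function(a) {
  av <- ad_value(a)
  nc <- ncol(av)
  ad_make(matrix(rowSums(av), ncol = 1L), list(a),
          list(function(g) g[, rep(1L, nc), drop = FALSE]))
}

#' Add a 1 x n bias row to every row of an m x n matrix
#' @param a node or matrix, m x n
#' @param b node or matrix, 1 x n
#' @export
ad_addbias <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(ncol(av) == ncol(bv), nrow(bv) == 1L)
  out <- sweep(av, 2L, as.vector(bv), "+")
  ad_make(out, list(a, b), list(
    function(g) g,
    function(g) matrix(colSums(g), 1L)
  ))
}

#' Scale each row of an m x n matrix by an m x 1 column
#' @param a node or matrix, m x n
#' @param s node or matrix, m x 1
#' @export
ad_rowscale <- function(a, s) {
  av <- ad_value(a); sv <- ad_value(s)
  stopifnot(nrow(av) == nrow(sv), ncol(sv) == 1L)
  out <- av * as.vector(sv)
  ad_make(out, list(a, s), list(
    function(g) g * as.vector(sv),
    function(g) matrix(rowSums(g * av), ncol = 1L)
  ))
}

#' Select rows (with gradient scatter-add for duplicates)
#' @param a node or matrix
#' @param idx integer vector of row indices
#' @export
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  idx <- as.integer(idx)
  ad_make(av[idx, , drop = FALSE], list(a), list(function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    agg <- rowsum(g, group = idx)
    z[as.integer(rownames(agg)), ] <- agg
    z
  }))
}

#' Gather scalar entries a[i, j] as a column
#' @param a node or matrix
#' @param ij two-column integer matrix of (row, col) indices
#' @export
ad_gather <- function(a, ij) {
  av <- ad_value(a)
  ij <- cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))
  ad_make(matrix(av[ij], ncol = 1L), list(a), list(function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    for (r in seq_len(nrow(ij))) {
      z[ij[r, 1L], ij[r, 2L]] <- z[ij[r, 1L], ij[r, 2L]] + g[r, 1L]
    }
    z
  }))
}

#' Column-bind two blocks
#' @param a,b nodes or matrices with equal row counts
#' @export
ad_cbind <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- ncol(av)
  ad_make(cbind(av, bv), list(a, b), list(
    function(g) g[, seq_len(na), drop = FALSE],
    function(g) g[, -seq_len(na), drop = FALSE]
  ))
}

#' Row-wise log-softmax
#' @param a node or matrix of logits
#' @export
ad_log_softmax <- function(a) {
  av <- ad_value(a)
  m <- apply(av, 1L, max)
  ls <- av - m - log(rowSums(exp(av - m)))
  sm <- exp(ls)
  ad_make(ls, list(a), list(function(g) g - sm * rowSums(g)))
}

#' Gradient reversal: identity forward, negated scaled cotangent backward
#' @param a node or matrix
#' @param strength non-negative scale applied to the reversed gradient
#' @export
ad_grad_reverse <- function(a, strength) {
  av <- ad_value(a)
  ad_make(av, list(a), list(function(g) -strength * g))
}

#' Backpropagate from a scalar node
#'
#' Accumulates cotangents into `$grad` of every node reachable from `root`.
#' @param root a 1x1 `adnode`
#' @return invisibly, `root`
#' @export
ad_backward <- function(root) {
  stopifnot(is_adnode(root), length(root$value) == 1L)
  # iterative post-order DFS for a reverse topological order
  order <- vector("list", 256L); n_ord <- 0L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- top$node
    } else if (is.null(visited[[key]])) {
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
      for (p in top$node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
        }
      }
    }
  }
  root$grad <- matrix(1, 1L, 1L)
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    if (is.null(node$grad)) next
    g <- node$grad
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      contrib <- node$backs[[i]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(root)
}

#' Read the accumulated gradient of a leaf
#' @param node an `adnode`
#' @return matrix of the node's shape (zeros if it never received gradient)
#' @export
ad_grad <- function(node) {
  stopifnot(is_adnode(node))
  if (is.null(node$grad)) matrix(0, nrow(node$value), ncol(node$value)) else node$grad
}
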