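# Reverse-mode automatic differentiation on a flat tape.
#
# Values are plain R matrices (or scalars); a node is an environment holding the
# forward value, the list of parent nodes and a closure computing parent
# gradients from its own. Creation order is a valid topological order, so
# backward() is a single reverse sweep over the tape. Constants never allocate
# nodes: any numeric argument is treated as a constant and receives no gradient.

.ag <- new.env(parent = emptyenv())
.ag$n <- 0L
.ag$enabled <- TRUE

#' Reset the autodiff tape
#'
#' Discards all intermediate nodes recorded since the last reset. Called at the
#' start of every training step; leaf parameters (and their accumulated
#' gradients) are unaffected.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ag_tape_reset <- function() {
  .ag$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#'
#' @param expr Expression to evaluate. All autodiff ops inside return plain
#'   numeric values, so inference costs no tape memory.
#' @return The value of `expr`.
#' @keywords internal
#' @export
ag_no_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  force(expr)
}

is_ag <- function(x) is.environment(x)

#' Numeric value of a tensor or constant
#' @param x An `ag` node or a numeric.
#' @return The underlying numeric value.
#' @keywords internal
#' @export
ag_val <- function(x) if (is_ag(x)) x$value else x

ag_node <- function(value, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  n <- .ag$n + 1L
  .ag$n <- n
  e$idx <- n
  class(e) <- "ag"
  e
}

# record only when tracking is on and at least one parent is tracked
ag_track <- function(...) {
  if (!.ag$enabled) return(FALSE)
  for (p in list(...)) if (is_ag(p)) return(TRUE)
  FALSE
}

#' Create a trainable parameter leaf
#' @param value Initial numeric value (matrix or vector).
#' @return An `ag` leaf whose gradient persists across tape resets.
#' @keywords internal
#' @export
ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- list()
  e$backward <- NULL
  e$grad <- NULL
  e$idx <- 0L
  class(e) <- "ag"
  e
}

accum <- function(node, g) {
  if (!is.environment(node)) return(invisible(NULL))
  if (is.null(dim(g))) {
    dv <- dim(node$value)
    if (!is.null(dv) && length(g) == length(node$value)) dim(g) <- dv
  }
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward sweep from a scalar loss
#'
#' @param loss A scalar `ag` node.
#' @return Invisibly, `NULL`. Leaf parameter gradients are accumulated in place.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(ag_val(loss)) == 1L, loss$idx > 0L)
  # gather reachable interior nodes; creation index is a topological order
  n <- .ag$n
  nodes <- vector("list", n)
  seen <- logical(n)
  stack <- vector("list", 64L)
  stack[[1L]] <- loss
  sp <- 1L
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    i <- nd$idx
    if (i > 0L && !seen[i]) {
      seen[i] <- TRUE
      nodes[[i]] <- nd
      for (p in nd$parents) {
        if (is.environment(p) && p$idx > 0L && !seen[p$idx]) {
          sp <- sp + 1L
          stack[[sp]] <- p
        }
      }
    }
  }
  loss$grad <- 1
  for (i in seq(loss$idx, 1L)) {
    nd <- nodes[[i]]
    if (!is.null(nd) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise arithmetic ---------------------------------------------------

#' Elementwise tensor arithmetic
#'
#' `ag_add`, `ag_sub`, `ag_mul`, `ag_div` operate elementwise on operands of
#' identical shape; either operand may be a scalar.
#' @param x,y `ag` nodes or numerics.
#' @return An `ag` node (or plain numeric when gradients are off).
#' @keywords internal
#' @export
ag_add <- function(x, y) {
  v <- ag_val(x) + ag_val(y)
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, if (length(ag_val(x)) == 1L) sum(g) else g)
    if (is_ag(y)) accum(y, if (length(ag_val(y)) == 1L) sum(g) else g)
  })
}

#' @rdname ag_add
#' @export
ag_sub <- function(x, y) {
  v <- ag_val(x) - ag_val(y)
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, if (length(ag_val(x)) == 1L) sum(g) else g)
    if (is_ag(y)) accum(y, if (length(ag_val(y)) == 1L) -sum(g) else -g)
  })
}

#' @rdname ag_add
#' @export
ag_mul <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  v <- xv * yv
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) {
      gx <- g * yv
      accum(x, if (length(xv) == 1L) sum(gx) else gx)
    }
    if (is_ag(y)) {
      gy <- g * xv
      accum(y, if (length(yv) == 1L) sum(gy) else gy)
    }
  })
}

#' @rdname ag_add
#' @export
ag_div <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  v <- xv / yv
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) {
      gx <- g / yv
      accum(x, if (length(xv) == 1L) sum(gx) else gx)
    }
    if (is_ag(y)) {
      gy <- -g * xv / (yv * yv)
      accum(y, if (length(yv) == 1L) sum(gy) else gy)
    }
  })
}

#' Broadcast arithmetic over rows and columns
#'
#' `ag_add_rowvec(x, b)` adds a length-`ncol(x)` vector to every row (bias add);
#' `ag_mul_rowvec(x, w)` scales every column `j` by `w[j]`;
#' `ag_mul_colvec(x, w)` scales every row `i` by `w[i]`;
#' `ag_outer_add(a, b)` forms the matrix `a[i] + b[j]`.
#' @param x Matrix-valued node.
#' @param a,b,w Vector-valued nodes or numerics.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_add_rowvec <- function(x, b) {
  xv <- ag_val(x); bv <- as.vector(ag_val(b))
  v <- xv + rep(bv, each = nrow(xv))
  if (!ag_track(x, b)) return(v)
  ag_node(v, list(x, b), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g)
    if (is_ag(b)) accum(b, colSums(g))
  })
}

#' @rdname ag_add_rowvec
#' @export
ag_mul_rowvec <- function(x, w) {
  xv <- ag_val(x); wv <- as.vector(ag_val(w))
  wbk <- rep(wv, each = nrow(xv))
  v <- xv * wbk
  if (!ag_track(x, w)) return(v)
  ag_node(v, list(x, w), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g * wbk)
    if (is_ag(w)) accum(w, colSums(g * xv))
  })
}

#' @rdname ag_add_rowvec
#' @export
ag_mul_colvec <- function(x, w) {
  xv <- ag_val(x); wv <- as.vector(ag_val(w))
  v <- xv * wv  # recycles down columns: row i scaled by w[i]
  if (!ag_track(x, w)) return(v)
  ag_node(v, list(x, w), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g * wv)
    if (is_ag(w)) accum(w, matrix(rowSums(g * xv), ncol = 1))
  })
}

#' @rdname ag_add_rowvec
#' @export
ag_outer_add <- function(a, b) {
  av <- as.vector(ag_val(a)); bv <- as.vector(ag_val(b))
  v <- outer(av, bv, "+")
  if (!ag_track(a, b)) return(v)
  ag_node(v, list(a, b), function(node) {
    g <- node$grad
    if (is_ag(a)) accum(a, matrix(rowSums(g), ncol = 1))
    if (is_ag(b)) accum(b, colSums(g))
  })
}

# ---- linear algebra -----------------------------------------------------------

#' Matrix product with gradient
#' @param x,y Conformable matrix nodes or numerics.
#' @return An `ag` node holding `x %*% y`.
#' @keywords internal
#' @export
ag_matmul <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  v <- xv %*% yv
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, tcrossprod(g, yv))
    if (is_ag(y)) accum(y, crossprod(xv, g))
  })
}

#' Matrix product against a transposed right factor
#'
#' Computes `x %*% t(y)` without materializing the transpose (the hot path of
#' attention score computation).
#' @param x,y Matrix nodes or numerics with matching column counts.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_matmul_t <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  v <- tcrossprod(xv, yv)
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g %*% yv)
    if (is_ag(y)) accum(y, crossprod(g, xv))
  })
}

#' Matrix transpose with gradient
#' @param x Matrix node.
#' @return An `ag` node holding `t(x)`.
#' @keywords internal
#' @export
ag_t <- function(x) {
  v <- t(ag_val(x))
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, t(node$grad)))
}

# ---- nonlinearities -----------------------------------------------------------

#' Pointwise nonlinearities
#'
#' Sigmoid, hyperbolic tangent, exponential, natural log, square root, ReLU and
#' SiLU (`x * sigmoid(x)`), each with its exact derivative.
#' @param x Node or numeric.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ag_val(x)))
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad * v * (1 - v)))
}

#' @rdname ag_sigmoid
#' @export
ag_tanh <- function(x) {
  v <- tanh(ag_val(x))
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad * (1 - v * v)))
}

#' @rdname ag_sigmoid
#' @export
ag_exp <- function(x) {
  v <- exp(ag_val(x))
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad * v))
}

#' @rdname ag_sigmoid
#' @export
ag_log <- function(x) {
  xv <- ag_val(x)
  v <- log(xv)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad / xv))
}

#' @rdname ag_sigmoid
#' @export
ag_sqrt <- function(x) {
  v <- sqrt(ag_val(x))
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad / (2 * v)))
}

#' @rdname ag_sigmoid
#' @export
ag_relu <- function(x) {
  xv <- ag_val(x)
  v <- pmax(xv, 0)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad * (xv > 0)))
}

#' @rdname ag_sigmoid
#' @export
ag_silu <- function(x) {
  xv <- ag_val(x)
  s <- 1 / (1 + exp(-xv))
  v <- xv * s
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, node$grad * (s + xv * s * (1 - s))))
}

#' Elementwise maximum / minimum of two tensors
#'
#' Subgradient convention: ties route the gradient to `x`.
#' @param x,y Nodes or numerics of identical shape (or scalar).
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_pmax2 <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  take_x <- xv >= yv
  v <- pmax(xv, yv)
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g * take_x)
    if (is_ag(y)) {
      gy <- g * (!take_x)
      accum(y, if (length(yv) == 1L) sum(gy) else gy)
    }
  })
}

#' @rdname ag_pmax2
#' @export
ag_pmin2 <- function(x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  take_x <- xv <= yv
  v <- pmin(xv, yv)
  if (!ag_track(x, y)) return(v)
  ag_node(v, list(x, y), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g * take_x)
    if (is_ag(y)) {
      gy <- g * (!take_x)
      accum(y, if (length(yv) == 1L) sum(gy) else gy)
    }
  })
}

# ---- reductions ---------------------------------------------------------------

#' Reductions with gradient
#'
#' `ag_sum` / `ag_mean` reduce to a scalar; `ag_rowsums` returns an
#' `nrow(x)` x 1 matrix; `ag_rowmeans` its mean analogue.
#' @param x Matrix node.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_sum <- function(x) {
  xv <- ag_val(x)
  v <- sum(xv)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) accum(x, array(node$grad, dim(as.matrix(xv)))))
}

#' @rdname ag_sum
#' @export
ag_mean <- function(x) {
  xv <- ag_val(x)
  v <- mean(xv)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    accum(x, array(node$grad / length(xv), dim(as.matrix(xv))))
  })
}

#' @rdname ag_sum
#' @export
ag_rowsums <- function(x) {
  xv <- ag_val(x)
  v <- matrix(rowSums(xv), ncol = 1)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    accum(x, matrix(node$grad, nrow(xv), ncol(xv)))
  })
}

#' @rdname ag_sum
#' @export
ag_rowmax <- function(x) {
  xv <- ag_val(x)
  jm <- max.col(xv, ties.method = "first")
  v <- matrix(xv[cbind(seq_len(nrow(xv)), jm)], ncol = 1)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[cbind(seq_len(nrow(xv)), jm)] <- node$grad
    accum(x, gx)
  })
}

#' @rdname ag_sum
#' @export
ag_rowmeans <- function(x) {
  xv <- ag_val(x)
  v <- matrix(rowMeans(xv), ncol = 1)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    accum(x, matrix(node$grad / ncol(xv), nrow(xv), ncol(xv)))
  })
}

# ---- softmax ------------------------------------------------------------------

#' Row-wise softmax with gradient
#'
#' Numerically stabilized by subtracting the row maximum before
#' exponentiation; each output row sums to one.
#' @param x Matrix node of logits.
#' @return An `ag` node of row-stochastic probabilities.
#' @keywords internal
#' @export
ag_softmax_rows <- function(x) {
  xv <- ag_val(x)
  m <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - m)
  v <- e / rowSums(e)
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    g <- node$grad
    accum(x, (g - rowSums(g * v)) * v)
  })
}

# ---- structural ops -----------------------------------------------------------

#' Row gather with implicit zero row
#'
#' Selects rows of `x` by index; index 0 yields a zero row (used for "same"
#' padding in convolutions). Backward scatter-adds gradients back.
#' @param x Matrix node.
#' @param idx Integer vector of row indices in `0..nrow(x)`.
#' @return An `ag` node with `length(idx)` rows.
#' @keywords internal
#' @export
ag_index_rows <- function(x, idx) {
  xv <- ag_val(x)
  v <- rbind(numeric(ncol(xv)), xv)[idx + 1L, , drop = FALSE]
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    g <- node$grad
    keep <- idx > 0L
    gs <- rowsum(g[keep, , drop = FALSE], group = idx[keep])
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[as.integer(rownames(gs)), ] <- gs
    accum(x, gx)
  })
}

#' Column / row slicing with gradient
#' @param x Matrix node.
#' @param j,i Integer indices to keep.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_slice_cols <- function(x, j) {
  xv <- ag_val(x)
  v <- xv[, j, drop = FALSE]
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    g <- node$grad
    gx <- matrix(0, nrow(xv), ncol(xv))
    if (anyDuplicated(j)) {
      gs <- rowsum(t(g), group = j)
      gx[, as.integer(rownames(gs))] <- t(gs)
    } else {
      gx[, j] <- g
    }
    accum(x, gx)
  })
}

#' @rdname ag_slice_cols
#' @export
ag_slice_rows <- function(x, i) {
  xv <- ag_val(x)
  v <- xv[i, , drop = FALSE]
  if (!ag_track(x)) return(v)
  ag_node(v, list(x), function(node) {
    g <- node$grad
    gx <- matrix(0, nrow(xv), ncol(xv))
    if (anyDuplicated(i)) {
      gs <- rowsum(g, group = i)
      gx[as.integer(rownames(gs)), ] <- gs
    } else {
      gx[i, ] <- g
    }
    accum(x, gx)
  })
}

#' Column-wise concatenation with gradient
#' @param xs List of matrix nodes with equal row counts.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_cbind <- function(xs) {
  vals <- lapply(xs, ag_val)
  v <- do.call(cbind, vals)
  tracked <- any(vapply(xs, is_ag, logical(1))) && .ag$enabled
  if (!tracked) return(v)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(v, xs, function(node) {
    g <- node$grad
    for (k in seq_along(xs)) {
      if (is_ag(xs[[k]])) accum(xs[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

#' Row-wise concatenation with gradient
#' @param xs List of matrix nodes with equal column counts.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_rbind <- function(xs) {
  vals <- lapply(xs, ag_val)
  v <- do.call(rbind, vals)
  tracked <- any(vapply(xs, is_ag, logical(1))) && .ag$enabled
  if (!tracked) return(v)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_node(v, xs, function(node) {
    g <- node$grad
    for (k in seq_along(xs)) {
      if (is_ag(xs[[k]])) accum(xs[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

#' Detach a value from the tape
#' @param x Node or numeric.
#' @return The plain numeric value; gradients do not flow through.
#' @keywords internal
#' @export
ag_detach <- function(x) ag_val(x)

# ---- numerical gradient check -------------------------------------------------

#' Central finite-difference gradient of a scalar function
#'
#' Independent oracle used by the test-suite to validate analytic gradients.
#' @param f Function taking a numeric vector, returning a scalar.
#' @param x0 Point at which to differentiate.
#' @param eps Step size.
#' @return Numeric gradient vector.
#' @keywords internal
#' @export
ag_numgrad <- function(f, x0, eps = 1e-5) {
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
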