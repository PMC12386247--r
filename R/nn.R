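# Neural-network building blocks over the autodiff tape.
#
# Feature maps are (H*W) x C token matrices in R's column-major spatial order
# (token p = (x-1)*H + y for pixel row y, column x). Convolutions gather
# k x k patches with a single fused im2col node, then one matrix product.

#' Additive per-row broadcast
#'
#' Adds a length-`nrow(x)` column vector to every column of `x`.
#' @param x Matrix node.
#' @param v Column-vector node or numeric.
#' @return An `ag` node.
#' @keywords internal
#' @export
ag_add_colvec <- function(x, v) {
  xv <- ag_val(x); vv <- as.vector(ag_val(v))
  out <- xv + vv
  if (!ag_track(x, v)) return(out)
  ag_node(out, list(x, v), function(node) {
    g <- node$grad
    if (is_ag(x)) accum(x, g)
    if (is_ag(v)) accum(v, matrix(rowSums(g), ncol = 1))
  })
}

#' Fused patch extraction (im2col) with gradient
#'
#' @param x `(H*W) x C` feature matrix node.
#' @param idx Integer `N_out x K` matrix of input token indices per kernel
#'   offset; 0 denotes zero padding.
#' @return An `ag` node of shape `N_out x (C*K)`, kernel-offset-major columns.
#' @keywords internal
#' @export
ag_im2col <- function(x, idx) {
  xv <- ag_val(x)
  cin <- ncol(xv); nout <- nrow(idx); K <- ncol(idx)
  X0 <- rbind(numeric(cin), xv)
  R <- X0[as.vector(idx) + 1L, , drop = FALSE]
  P <- aperm(array(R, c(nout, K, cin)), c(1L, 3L, 2L))
  dim(P) <- c(nout, cin * K)
  if (!ag_track(x)) return(P)
  ag_node(P, list(x), function(node) {
    g <- node$grad
    dim(g) <- c(nout, cin, K)
    g <- aperm(g, c(1L, 3L, 2L))
    dim(g) <- c(nout * K, cin)
    iv <- as.vector(idx)
    keep <- iv > 0L
    gs <- rowsum(g[keep, , drop = FALSE], group = iv[keep])
    gx <- matrix(0, nrow(xv), cin)
    gx[as.integer(rownames(gs)), ] <- gs
    accum(x, gx)
  })
}

#' Kernel-offset index table for a 2-D convolution
#'
#' @param H,W Input spatial extent.
#' @param k Kernel size (odd).
#' @param stride Stride.
#' @param dilation Kernel dilation.
#' @param pad Zero padding on each side ("same" default for stride 1).
#' @return List with `idx` (`N_out x k^2` index matrix, 0 = padding), `H_out`,
#'   `W_out`.
#' @keywords internal
#' @export
conv_index <- function(H, W, k, stride = 1L, dilation = 1L,
                       pad = dilation * (k - 1L) %/% 2L) {
  span <- dilation * (k - 1L) + 1L
  H_out <- (H + 2L * pad - span) %/% stride + 1L
  W_out <- (W + 2L * pad - span) %/% stride + 1L
  yo <- rep(seq_len(H_out), times = W_out)
  xo <- rep(seq_len(W_out), each = H_out)
  idx <- matrix(0L, H_out * W_out, k * k)
  u <- 0L
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      u <- u + 1L
      yi <- (yo - 1L) * stride + dy * dilation + 1L - pad
      xi <- (xo - 1L) * stride + dx * dilation + 1L - pad
      ok <- yi >= 1L & yi <= H & xi >= 1L & xi <= W
      idx[, u] <- ifelse(ok, (xi - 1L) * H + yi, 0L)
    }
  }
  list(idx = idx, H_out = H_out, W_out = W_out)
}

# cache of conv index tables keyed by geometry
.nn_cache <- new.env(parent = emptyenv())

conv_index_cached <- function(H, W, k, stride = 1L, dilation = 1L,
                              pad = dilation * (k - 1L) %/% 2L) {
  key <- paste(H, W, k, stride, dilation, pad, sep = "_")
  ci <- .nn_cache[[key]]
  if (is.null(ci)) {
    ci <- conv_index(H, W, k, stride, dilation, pad)
    .nn_cache[[key]] <- ci
  }
  ci
}

#' Averaging matrix for adaptive average pooling
#'
#' Each output cell averages the input cells of its (torch-convention) bin;
#' handles upsampling (`out > in`) by bin overlap.
#' @param H_in,W_in,H_out,W_out Spatial extents.
#' @return A dense `(H_out*W_out) x (H_in*W_in)` averaging matrix.
#' @keywords internal
#' @export
adaptive_pool_matrix <- function(H_in, W_in, H_out, W_out) {
  key <- paste("pool", H_in, W_in, H_out, W_out, sep = "_")
  P <- .nn_cache[[key]]
  if (!is.null(P)) return(P)
  bins <- function(n_in, n_out) {
    lapply(seq_len(n_out), function(i) {
      lo <- floor((i - 1) * n_in / n_out) + 1L
      hi <- ceiling(i * n_in / n_out)
      lo:hi
    })
  }
  by <- bins(H_in, H_out); bx <- bins(W_in, W_out)
  P <- matrix(0, H_out * W_out, H_in * W_in)
  for (xo in seq_len(W_out)) {
    for (yo in seq_len(H_out)) {
      r <- (xo - 1L) * H_out + yo
      cells <- as.vector(outer(by[[yo]], (bx[[xo]] - 1L) * H_in, "+"))
      P[r, cells] <- 1 / length(cells)
    }
  }
  .nn_cache[[key]] <- P
  P
}

# ---- layers -------------------------------------------------------------------

he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Construct a dense (affine) layer
#' @param fan_in,fan_out Widths.
#' @return A `linear` layer (list of `W`, `b` parameters).
#' @keywords internal
#' @export
linear_new <- function(fan_in, fan_out) {
  structure(list(W = ag_param(he_init(fan_in, fan_out)),
                 b = ag_param(numeric(fan_out))),
            class = "pf_linear")
}

#' Apply a dense layer to a token matrix
#' @param layer A `linear_new()` layer.
#' @param x `N x fan_in` node.
#' @return `N x fan_out` node.
#' @keywords internal
#' @export
linear_apply <- function(layer, x) {
  ag_add_rowvec(ag_matmul(x, layer$W), layer$b)
}

#' Construct / apply a 2-D convolution on token matrices
#' @param cin,cout Channel counts.
#' @param k Kernel size.
#' @param stride Stride.
#' @param dilation Kernel dilation.
#' @return `conv_new()`: a layer; `conv_apply()`: list `x` (`N_out x cout`
#'   node), `H`, `W`.
#' @keywords internal
#' @export
conv_new <- function(cin, cout, k, stride = 1L, dilation = 1L) {
  structure(list(W = ag_param(he_init(k * k * cin, cout)),
                 b = ag_param(numeric(cout)),
                 k = k, stride = stride, dilation = dilation,
                 cin = cin, cout = cout),
            class = "pf_conv")
}

#' @rdname conv_new
#' @param layer Conv layer.
#' @param x Feature node `(H*W) x cin`.
#' @param H,W Input spatial extent.
#' @export
conv_apply <- function(layer, x, H, W) {
  ci <- conv_index_cached(H, W, layer$k, layer$stride, layer$dilation)
  patches <- ag_im2col(x, ci$idx)
  out <- ag_add_rowvec(ag_matmul(patches, layer$W), layer$b)
  list(x = out, H = ci$H_out, W = ci$W_out)
}

#' Root-mean-square normalization over rows
#' @param x `N x C` node.
#' @param gain Length-`C` gain parameter.
#' @param eps Stabilizer.
#' @return Normalized node.
#' @keywords internal
#' @export
rmsnorm_apply <- function(x, gain, eps = 1e-6) {
  ms <- ag_rowmeans(ag_mul(x, x))
  inv <- ag_div(1, ag_sqrt(ag_add(ms, eps)))
  ag_mul_rowvec(ag_mul_colvec(x, inv), gain)
}

#' Layer normalization over rows
#' @param x `N x C` node.
#' @param gain,bias Length-`C` parameters.
#' @param eps Stabilizer.
#' @return Normalized node.
#' @keywords internal
#' @export
layernorm_apply <- function(x, gain, bias, eps = 1e-6) {
  mu <- ag_rowmeans(x)
  xc <- ag_add_colvec(x, ag_mul(mu, -1))
  va <- ag_rowmeans(ag_mul(xc, xc))
  inv <- ag_div(1, ag_sqrt(ag_add(va, eps)))
  ag_add_rowvec(ag_mul_rowvec(ag_mul_colvec(xc, inv), gain), bias)
}

#' Construct a multi-head attention block
#' @param d Model width (divisible by `h`).
#' @param h Number of heads.
#' @param tie_qk_init Initialize the query and key projections identically,
#'   so attention logits start as a similarity of (positional) inputs -
#'   attention is local from the first step when queries and keys share a
#'   positional code.
#' @return An attention layer.
#' @keywords internal
#' @export
mha_new <- function(d, h, tie_qk_init = TRUE) {
  Wq <- linear_new(d, d)
  Wk <- linear_new(d, d)
  if (tie_qk_init) Wk$W$value <- Wq$W$value
  structure(list(Wq = Wq, Wk = Wk,
                 Wv = linear_new(d, d), Wo = linear_new(d, d),
                 d = d, h = h),
            class = "pf_mha")
}

#' Apply multi-head attention
#' @param layer `mha_new()` layer.
#' @param qx Query token node `Nq x d`.
#' @param kvx Key token node `Nk x d`.
#' @param vx Value token node (defaults to `kvx`; pass the content stream
#'   when keys carry positional encodings).
#' @return `Nq x d` node.
#' @keywords internal
#' @export
mha_apply <- function(layer, qx, kvx, vx = kvx) {
  d <- layer$d; h <- layer$h; dh <- d %/% h
  Q <- linear_apply(layer$Wq, qx)
  K <- linear_apply(layer$Wk, kvx)
  V <- linear_apply(layer$Wv, vx)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    Qh <- ag_slice_cols(Q, cols)
    Kh <- ag_slice_cols(K, cols)
    Vh <- ag_slice_cols(V, cols)
    A <- ag_softmax_rows(ag_mul(ag_matmul_t(Qh, Kh), 1 / sqrt(dh)))
    heads[[i]] <- ag_matmul(A, Vh)
  }
  linear_apply(layer$Wo, ag_cbind(heads))
}

#' 2-D sinusoidal positional encoding
#'
#' Standard DETR-style encoding: half the channels encode the y coordinate,
#' half the x coordinate, each with interleaved sine/cosine at geometric
#' frequencies.
#' @param H,W Spatial extent.
#' @param d Encoding width (multiple of 4).
#' @return `(H*W) x d` numeric matrix in column-major token order.
#' @keywords internal
#' @export
posenc_2d <- function(H, W, d) {
  key <- paste("pe", H, W, d, sep = "_")
  pe <- .nn_cache[[key]]
  if (!is.null(pe)) return(pe)
  stopifnot(d %% 4 == 0)
  dq <- d %/% 4L
  freq <- 1 / (10000^((seq_len(dq) - 1) / dq))
  ys <- rep(seq_len(H), times = W)
  xs <- rep(seq_len(W), each = H)
  pe <- cbind(
    sin(outer(ys, freq)), cos(outer(ys, freq)),
    sin(outer(xs, freq)), cos(outer(xs, freq)))
  .nn_cache[[key]] <- pe
  pe
}

#' Sinusoidal encoding of continuous normalized positions
#'
#' Evaluates the same frequency bank as [posenc_2d()] at arbitrary normalized
#' centres, so anchor-derived query encodings align with the memory grid.
#' @param cx,cy Normalized coordinates in `[0, 1]`.
#' @param H,W Grid extent the encoding aligns with.
#' @param d Encoding width (multiple of 4).
#' @return `length(cx) x d` numeric matrix.
#' @keywords internal
#' @export
posenc_xy <- function(cx, cy, H, W, d) {
  dq <- d %/% 4L
  freq <- 1 / (10000^((seq_len(dq) - 1) / dq))
  y <- cy * H + 0.5
  x <- cx * W + 0.5
  cbind(sin(outer(y, freq)), cos(outer(y, freq)),
        sin(outer(x, freq)), cos(outer(x, freq)))
}

# ---- parameter handling -------------------------------------------------------

#' Collect all trainable parameters from a nested module list
#' @param module Arbitrarily nested list containing `ag` parameter leaves.
#' @return Flat named list of parameters.
#' @keywords internal
#' @export
collect_params <- function(module) {
  out <- list()
  walk <- function(x, prefix) {
    if (inherits(x, "ag")) {
      out[[prefix]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste(prefix, nm, sep = "."))
      }
    }
  }
  walk(module, "p")
  out
}

#' Export / restore parameter values
#'
#' `params_state()` snapshots values as plain numerics; `params_restore()`
#' writes a snapshot back into the same module structure.
#' @param params Flat parameter list from `collect_params()`.
#' @param state Named list of numeric values.
#' @return A named list of values, or (for restore) invisibly `NULL`.
#' @keywords internal
#' @export
params_state <- function(params) lapply(params, function(p) p$value)

#' @rdname params_state
#' @export
params_restore <- function(params, state) {
  stopifnot(all(names(params) %in% names(state)))
  for (nm in names(params)) params[[nm]]$value <- state[[nm]]
  invisible(NULL)
}

# ---- optimizer ----------------------------------------------------------------

#' AdamW optimizer
#'
#' Decoupled weight decay as in Loshchilov & Hutter; gradients may first be
#' clipped to a global norm with `opt_clip()`.
#' @param params Flat parameter list.
#' @param lr Learning rate.
#' @param betas Moment decay rates.
#' @param eps Denominator stabilizer.
#' @param weight_decay Decoupled decay coefficient.
#' @return An optimizer object.
#' @keywords internal
#' @export
opt_adamw <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                      weight_decay = 1e-4) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$lr <- lr; e$b1 <- betas[1]; e$b2 <- betas[2]; e$eps <- eps
  e$wd <- weight_decay; e$t <- 0L
  e$m <- lapply(params, function(p) p$value * 0)
  e$v <- lapply(params, function(p) p$value * 0)
  class(e) <- "pf_optimizer"
  e
}

#' Clip parameter gradients to a global L2 norm
#' @param params Flat parameter list with accumulated gradients.
#' @param max_norm Norm ceiling.
#' @return The pre-clipping global norm, invisibly.
#' @keywords internal
#' @export
opt_clip <- function(params, max_norm = 1) {
  sq <- 0
  for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
  gn <- sqrt(sq)
  if (is.finite(gn) && gn > max_norm) {
    sc <- max_norm / gn
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(gn)
}

#' Take one optimizer step and clear gradients
#' @param opt Optimizer from `opt_adamw()`.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
opt_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    p$value <- p$value - opt$lr * (mh / (sqrt(vh) + opt$eps) + opt$wd * p$value)
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Clear accumulated gradients without stepping
#' @param params Flat parameter list.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
opt_zero <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
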