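# Environment-guided modality attention (EMA).
#
# A 1 Hz history of normalized (temperature, humidity, light) vectors is
# embedded to width 64, run through a depth-3 stack of
# RMSNorm -> linear -> depthwise conv (k=3) -> SiLU -> SS1D layers, and the
# final output token is expanded into a spatial modulation gate
# g in (0,1)^(H x W x C). Fusion follows
#   F_fused(i,j,c) = g(i,j,c) * [alpha F_RGB(i,j,c) + (1-alpha) F_IR(i,j,c)]
# with a learnable alpha in [0,1] (sigmoid-parameterized, initialized at 0.5).

#' One linear state-space recurrence (SS1D core)
#'
#' `h_t = A h_{t-1} + B x_t`, `y_t = C h_t` with `h_0 = 0`. `A` is diagonal
#' with entries `sigmoid(a_raw)` in `(0, 1)`, so the recurrence is stable at
#' any parameter value; `B` and `C` are dense.
#' @param x_seq `T x d_in` node of input tokens (oldest first).
#' @param a_raw Length-`d_state` pre-sigmoid diagonal of `A` (or plain values
#'   in `(0,1)` when `raw = FALSE`).
#' @param B `d_in x d_state` input matrix.
#' @param C_out `d_state x d_out` output matrix.
#' @param raw If `TRUE` (default) `a_raw` is passed through a sigmoid.
#' @return `T x d_out` node of outputs.
#' @export
#' @examples
#' # scalar case A=0.5, B=C=1, x=(1,0,0): y = (1, 0.5, 0.25)
#' y <- ss1d_scan(matrix(c(1, 0, 0), 3, 1), 0.5,
#'                matrix(1), matrix(1), raw = FALSE)
#' ag_val(y)
ss1d_scan <- function(x_seq, a_raw, B, C_out, raw = TRUE) {
  Tn <- nrow(ag_val(x_seq))
  if (Tn < 1L) stop("empty sequence")
  a <- if (raw) ag_sigmoid(a_raw) else a_raw
  xb <- ag_matmul(x_seq, B)                      # T x d_state
  d_state <- ncol(ag_val(xb))
  h <- matrix(0, 1, d_state)                     # h_0 = 0
  ys <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- ag_add(ag_mul_rowvec(h, a), ag_slice_rows(xb, t))
    ys[[t]] <- h
  }
  ag_matmul(ag_rbind(ys), C_out)
}

#' Construct the environment-guided gate module
#'
#' @param cfg A [pf_config()]; uses `ema$depth`, `ema$width`, `ema$state`,
#'   `ema$gate_h/w/c` and the env-encoder width.
#' @return A module list.
#' @export
ema_new <- function(cfg) {
  w <- cfg$ema$width; st <- cfg$ema$state
  layers <- lapply(seq_len(cfg$ema$depth), function(i) {
    list(norm_gain = ag_param(rep(1, w)),
         lin = linear_new(w, w),
         dw = ag_param(matrix(stats::rnorm(3 * w, sd = 0.5), 3, w)),
         a_raw = ag_param(stats::rnorm(st, sd = 0.5)),
         B = ag_param(he_init(w, st)),
         C_out = ag_param(he_init(st, w)))
  })
  gs <- linear_new(w, cfg$ema$gate_h * cfg$ema$gate_w)
  gc_ <- linear_new(w, cfg$ema$gate_c)
  # gate starts nearly open (logit ~ +2) with small environment sensitivity,
  # so early training sees an almost neutral modulation
  gs$W$value <- gs$W$value * 0.25
  gc_$W$value <- gc_$W$value * 0.25
  gs$b$value <- rep(1, cfg$ema$gate_h * cfg$ema$gate_w)
  gc_$b$value <- rep(1, cfg$ema$gate_c)
  structure(list(env_enc = env_encoder_new(w),
                 layers = layers,
                 gate_spatial = gs,
                 gate_channel = gc_,
                 alpha_raw = ag_param(0),        # sigmoid(0) = 0.5
                 cfg_ema = cfg$ema),
            class = "pf_ema")
}

# depthwise conv k=3, stride 1, same padding over the sequence axis
dw_conv_seq <- function(x, Wdw) {
  Tn <- nrow(ag_val(x))
  idx0 <- c(0L, seq_len(Tn - 1L))   # previous token (0 = zero pad)
  idx2 <- c(seq_len(Tn)[-1L], 0L)   # next token
  ag_add(ag_add(
    ag_mul_rowvec(ag_index_rows(x, idx0), ag_slice_rows(Wdw, 1L)),
    ag_mul_rowvec(x, ag_slice_rows(Wdw, 2L))),
    ag_mul_rowvec(ag_index_rows(x, idx2), ag_slice_rows(Wdw, 3L)))
}

#' Run the SS1D stack over a sequence of environment embeddings
#'
#' Applies `depth` layers of RMSNorm -> linear (width 64) -> depthwise conv
#' (kernel 3, stride 1, same padding) -> SiLU -> SS1D recurrence, and returns
#' the final-time output token as the guidance vector.
#' @param ema An [ema_new()] module.
#' @param emb_seq `T x width` node of environment embeddings (oldest first,
#'   `T >= 1`).
#' @return A `1 x width` guidance node.
#' @export
ssm_block <- function(ema, emb_seq) {
  x <- emb_seq
  if (nrow(ag_val(x)) < 1L) stop("empty environment sequence")
  for (ly in ema$layers) {
    x <- rmsnorm_apply(x, ly$norm_gain)
    x <- linear_apply(ly$lin, x)
    x <- dw_conv_seq(x, ly$dw)
    x <- ag_silu(x)
    x <- ss1d_scan(x, ly$a_raw, ly$B, ly$C_out)
  }
  ag_slice_rows(x, nrow(ag_val(x)))
}

#' Build the spatial modulation gate from an environment history
#'
#' The guidance vector is mapped to `H*W` spatial logits and `C` channel
#' logits; their outer sum, squashed by a sigmoid, is the gate
#' `g in (0,1)^(H x W x C)` (stored as an `(H*W) x C` matrix).
#' @param ema An [ema_new()] module.
#' @param env_history `T x 3` matrix of normalized environment vectors
#'   (oldest first), or a single length-3 vector.
#' @return List: `g` (`(H*W) x C` node with values in `(0,1)`), `H`, `W`,
#'   `C`, `guidance` (`1 x width` node).
#' @export
build_gate <- function(ema, env_history) {
  if (is.null(dim(env_history))) env_history <- matrix(env_history, nrow = 1)
  stopifnot(ncol(env_history) == 3L, all(is.finite(env_history)))
  emb <- encode_env(ema$env_enc, env_history)
  y <- ssm_block(ema, emb)
  s_log <- linear_apply(ema$gate_spatial, y)    # 1 x (H*W)
  c_log <- linear_apply(ema$gate_channel, y)    # 1 x C
  g <- ag_sigmoid(ag_outer_add(ag_t(s_log), c_log))
  list(g = g, H = ema$cfg_ema$gate_h, W = ema$cfg_ema$gate_w,
       C = ema$cfg_ema$gate_c, guidance = y)
}

#' Environment-gated fusion of two modality feature maps
#'
#' Exact elementwise evaluation of
#' `F_fused = g * (alpha F_RGB + (1 - alpha) F_IR)`.
#' @param F_rgb,F_ir `(N x C)` nodes of matching shape.
#' @param g Gate node of the same shape (or the scalar 1 to disable gating).
#' @param alpha Scalar node or numeric in `[0, 1]`.
#' @return An `N x C` node.
#' @export
fuse_gate <- function(F_rgb, F_ir, g, alpha) {
  va <- ag_val(alpha)
  stopifnot(va >= 0, va <= 1)
  mix <- ag_add(ag_mul(F_rgb, alpha), ag_mul(F_ir, ag_sub(1, alpha)))
  ag_mul(g, mix)
}

#' Adapter mapping the fused visual stream into the gate's geometry
#'
#' At the published scale the gate (`32 x 32 x 64`) and the fused visual map
#' (`32 x 64 x 64` channels-first) disagree; a 1x1 channel conv plus adaptive
#' average pooling reconciles them. When shapes already agree (tiny preset)
#' the adapter is the identity and owns no parameters.
#' @param cfg A [pf_config()].
#' @return An adapter module (possibly identity).
#' @export
gate_adapter_new <- function(cfg) {
  same <- cfg$ema$gate_c == cfg$cma$cprime &&
    cfg$ema$gate_h == cfg$encoder$spatial &&
    cfg$ema$gate_w == cfg$encoder$spatial
  if (same) {
    structure(list(identity = TRUE), class = "pf_gate_adapter")
  } else {
    structure(list(identity = FALSE,
                   chan = conv_new(cfg$cma$cprime, cfg$ema$gate_c, 1L),
                   gate_h = cfg$ema$gate_h, gate_w = cfg$ema$gate_w),
              class = "pf_gate_adapter")
  }
}

#' @rdname gate_adapter_new
#' @param adapter A `gate_adapter_new()` module.
#' @param fm A [feature_map()].
#' @return A `pf_fmap` in the gate's geometry.
#' @export
gate_adapter_apply <- function(adapter, fm) {
  if (adapter$identity) return(fm)
  x <- conv_apply(adapter$chan, fm$x, fm$H, fm$W)$x
  P <- adaptive_pool_matrix(fm$H, fm$W, adapter$gate_h, adapter$gate_w)
  feature_map(ag_matmul(P, x), adapter$gate_h, adapter$gate_w, "fused")
}
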