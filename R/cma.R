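# Cross-modal attention-guided fusion (CMA).
#
# Pipeline: local activation histograms per modality -> KL-divergence
# inconsistency field -> alignment weights exp(-KL/tau) down-weighting
# conflicting regions -> 1x1 channel reduction to C' (plus a dilated 3x3
# branch) -> convolutional spatial gate -> bidirectional cross attention
# between the modalities -> per-modality residual gates -> learned 1x1 merge
# to a C' x H x W fused map. The KL field is computed on detached activations:
# it steers fusion but is not itself differentiated, matching its role as an
# information-theoretic alignment score rather than a learned map.

#' Smoothed activation histogram of a set of values
#'
#' Histogram over fixed bin edges, convolved with a discrete Gaussian kernel
#' (bandwidth = one bin width), floored at `1e-8` and renormalized, so every
#' bin is strictly positive and the vector sums to one.
#' @param values Numeric values.
#' @param edges Bin edges (length `bins + 1`, strictly increasing).
#' @return A probability vector of length `length(edges) - 1`.
#' @export
prob_histogram <- function(values, edges) {
  if (length(values) == 0) stop("empty region: cannot estimate a distribution")
  B <- length(edges) - 1L
  stopifnot(B >= 2L, all(diff(edges) > 0))
  k <- findInterval(values, edges, rightmost.closed = TRUE)
  k[k < 1L] <- 1L; k[k > B] <- B
  counts <- tabulate(k, nbins = B)
  # Gaussian kernel smoothing on the bin index lattice, sd = 1 bin
  off <- -3:3
  kern <- exp(-off^2 / 2); kern <- kern / sum(kern)
  sm <- numeric(B)
  for (j in seq_along(off)) {
    src <- seq_len(B) - off[j]
    src <- pmin(pmax(src, 1L), B)  # reflect mass at the edges
    sm <- sm + kern[j] * counts[src]
  }
  p <- pmax(sm / sum(sm), 1e-8)
  p / sum(p)
}

#' Per-region activation histograms of a feature map
#'
#' Activations are channel-pooled (mean over channels per spatial position,
#' the map's "spatial energy"), the spatial domain is tiled into a
#' `grid x grid` set of local regions, and each region yields one smoothed
#' histogram over shared bin edges.
#' @param fmap A [feature_map()] (or plain `(H*W) x C` matrix with `H`, `W`).
#' @param grid Regions per side.
#' @param bins Histogram bins.
#' @param range Optional shared value range `c(lo, hi)`; defaults to the
#'   map's own range. Pass a common range to compare two modalities.
#' @param H,W Spatial extent when `fmap` is a plain matrix.
#' @return List with `probs` (`grid^2 x bins` matrix, one histogram per
#'   region, regions in column-major order) and `edges`.
#' @export
estimate_distribution <- function(fmap, grid = 8L, bins = 16L, range = NULL,
                                  H = NULL, W = NULL) {
  if (inherits(fmap, "pf_fmap")) {
    v <- ag_val(fmap$x); H <- fmap$H; W <- fmap$W
  } else {
    v <- ag_val(fmap)
    stopifnot(!is.null(H), !is.null(W))
  }
  stopifnot(bins >= 2L, grid >= 1L, H %% grid == 0L, W %% grid == 0L)
  energy <- matrix(rowMeans(v), H, W)
  if (is.null(range)) range <- base::range(energy)
  if (range[2] <= range[1]) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  rh <- H %/% grid; rw <- W %/% grid
  probs <- matrix(0, grid * grid, bins)
  r <- 0L
  for (gx in seq_len(grid)) {
    for (gy in seq_len(grid)) {
      r <- r + 1L
      block <- energy[((gy - 1L) * rh + 1L):(gy * rh),
                      ((gx - 1L) * rw + 1L):(gx * rw)]
      probs[r, ] <- prob_histogram(as.vector(block), edges)
    }
  }
  list(probs = probs, edges = edges)
}

#' Kullback-Leibler divergence between two histograms
#'
#' `D_KL(P || Q) = sum_i P(i) log(P(i) / Q(i))`, natural log; zero-mass `P`
#' bins contribute zero. `Q` must be strictly positive (guaranteed by
#' histogram smoothing).
#' @param p,q Probability vectors with matching bin structure.
#' @return A nonnegative scalar (up to smoothing epsilon).
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75)) # 0.5*log(2) + 0.5*log(2/3)
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("histogram bin structures do not match")
  stopifnot(all(q > 0), all(p >= 0))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Alignment weights from a KL inconsistency field
#'
#' Monotone decreasing map `w = exp(-KL / tau)`: zero divergence gives weight
#' 1 (fusion unaffected), high inconsistency is down-weighted towards 0.
#' @param kl_field Nonnegative KL values (any shape).
#' @param tau Temperature (default 1).
#' @return Weights in `(0, 1]`, same shape.
#' @export
alignment_attention <- function(kl_field, tau = 1) {
  stopifnot(all(is.finite(kl_field)), tau > 0)
  exp(-pmax(kl_field, 0) / tau)
}

#' Single-head cross attention over spatial tokens
#'
#' The standard operation `Softmax(Q K^T / sqrt(d)) V` with tokens = spatial
#' positions and `d` = the channel width of `Q`. Rows of the attention matrix
#' sum to one.
#' @param Qsrc,Ksrc,Vsrc `(N x d)` token matrices or nodes (the query, key
#'   and attended-modality value sources).
#' @return An `N x d_v` node.
#' @export
cross_attention <- function(Qsrc, Ksrc, Vsrc) {
  d <- ncol(ag_val(Qsrc))
  stopifnot(d == ncol(ag_val(Ksrc)),
            nrow(ag_val(Ksrc)) == nrow(ag_val(Vsrc)))
  A <- ag_softmax_rows(ag_mul(ag_matmul_t(Qsrc, Ksrc), 1 / sqrt(d)))
  ag_matmul(A, Vsrc)
}

#' Residual gate combining original and enhanced features
#'
#' `out = original + sigmoid(gamma) * enhanced` with a learnable per-channel
#' gate, keeping either modality from dominating the fusion.
#' @param original,enhanced `(N x C)` nodes of matching shape.
#' @param gamma_raw Length-`C` pre-sigmoid gate parameter.
#' @return An `N x C` node.
#' @export
residual_gate <- function(original, enhanced, gamma_raw) {
  stopifnot(identical(dim(ag_val(original)), dim(ag_val(enhanced))))
  ag_add(original, ag_mul_rowvec(enhanced, ag_sigmoid(gamma_raw)))
}

#' Construct the CMA module
#' @param cfg A [pf_config()] (fields `encoder$channels`, `cma$*`).
#' @return A module list of parameters.
#' @export
cma_new <- function(cfg) {
  C <- cfg$encoder$channels; Cp <- cfg$cma$cprime
  mk_branch <- function() {
    dil <- if (isTRUE(cfg$cma$dilated_branch)) {
      d <- conv_new(C, Cp, 3L, dilation = 2L)
      d$W$value <- d$W$value * 0.1          # auxiliary scale branch starts small
      d
    }
    sp <- conv_new(2L, 1L, cfg$cma$spatial_kernel)
    sp$b$value <- 2                          # spatial gate opens near 1 at init
    list(reduce = conv_new(C, Cp, 1L),
         dilated = dil,
         sp_conv = sp,
         # residual cross-modal branch starts nearly closed (sigma(-2) ~ 0.12)
         gamma = ag_param(rep(-2, Cp)))
  }
  # learned merge starts as the average of the two enhanced streams
  merge <- conv_new(2L * Cp, Cp, 1L)
  merge$W$value <- rbind(diag(0.5, Cp), diag(0.5, Cp)) +
    matrix(stats::rnorm(2 * Cp * Cp, sd = 0.02), 2 * Cp, Cp)
  structure(list(rgb = mk_branch(), ir = mk_branch(),
                 merge = merge,
                 cfg_cma = cfg$cma),
            class = "pf_cma")
}

# multi-scale channel reduction: 1x1 conv (+ dilated 3x3 branch)
project_reduce_branch <- function(branch, x, H, W) {
  out <- conv_apply(branch$reduce, x, H, W)$x
  if (!is.null(branch$dilated)) {
    out <- ag_add(out, conv_apply(branch$dilated, x, H, W)$x)
  }
  out
}

# convolutional spatial gate: [channel-mean, channel-max] -> kxk conv -> sigmoid
spatial_gate <- function(branch, x, H, W) {
  stat <- ag_cbind(list(ag_rowmeans(x), ag_rowmax(x)))
  g <- ag_sigmoid(conv_apply(branch$sp_conv, stat, H, W)$x)
  ag_mul_colvec(x, g)
}

#' Run cross-modal attention-guided fusion
#'
#' @param cma A [cma_new()] module.
#' @param fm_rgb,fm_ir Same-shape [feature_map()]s from the image encoders.
#' @param reweight If `FALSE`, skip the KL alignment weighting (weights
#'   identically 1) - the "w/o modality reweighting" ablation.
#' @return List: `fused` (`pf_fmap`, `C'` channels), `enhanced_rgb`,
#'   `enhanced_ir` (per-modality post-attention maps consumed by the
#'   environment gate), `kl_field` (per-region KL values), `align_weights`.
#' @export
cma_forward <- function(cma, fm_rgb, fm_ir, reweight = TRUE) {
  stopifnot(fm_rgb$H == fm_ir$H, fm_rgb$W == fm_ir$W, fm_rgb$C == fm_ir$C)
  H <- fm_rgb$H; W <- fm_rgb$W
  cc <- cma$cfg_cma
  grid <- cc$grid

  # --- KL alignment field on detached activations -------------------------
  if (reweight) {
    e_rgb <- matrix(rowMeans(ag_val(fm_rgb$x)), H, W)
    e_ir <- matrix(rowMeans(ag_val(fm_ir$x)), H, W)
    rng <- base::range(c(e_rgb, e_ir))
    h_rgb <- estimate_distribution(fm_rgb, grid = grid, bins = cc$bins, range = rng)
    h_ir <- estimate_distribution(fm_ir, grid = grid, bins = cc$bins, range = rng)
    kl_field <- vapply(seq_len(grid * grid), function(r) {
      kl_divergence(h_rgb$probs[r, ], h_ir$probs[r, ])
    }, numeric(1))
    w_region <- alignment_attention(kl_field, tau = cc$tau)
    # expand region weights to per-position weights (column-major regions)
    rh <- H %/% grid; rw <- W %/% grid
    wmat <- matrix(w_region, grid, grid)[rep(seq_len(grid), each = rh),
                                         rep(seq_len(grid), each = rw)]
    w_pos <- matrix(as.vector(wmat), ncol = 1)
  } else {
    kl_field <- numeric(grid * grid)
    w_region <- rep(1, grid * grid)
    w_pos <- matrix(1, H * W, 1)
  }

  x_rgb <- ag_mul_colvec(fm_rgb$x, w_pos)
  x_ir <- ag_mul_colvec(fm_ir$x, w_pos)

  # --- multi-scale projection to C' and spatial gating ---------------------
  r_rgb <- spatial_gate(cma$rgb, project_reduce_branch(cma$rgb, x_rgb, H, W), H, W)
  r_ir <- spatial_gate(cma$ir, project_reduce_branch(cma$ir, x_ir, H, W), H, W)

  # --- bidirectional cross attention + residual gates ----------------------
  att_rgb <- cross_attention(r_rgb, r_ir, r_ir)   # RGB queries attend to IR
  att_ir <- cross_attention(r_ir, r_rgb, r_rgb)   # IR queries attend to RGB
  enh_rgb <- residual_gate(r_rgb, att_rgb, cma$rgb$gamma)
  enh_ir <- residual_gate(r_ir, att_ir, cma$ir$gamma)

  fused <- conv_apply(cma$merge, ag_cbind(list(enh_rgb, enh_ir)), H, W)$x
  list(fused = feature_map(fused, H, W, "fused"),
       enhanced_rgb = feature_map(enh_rgb, H, W, "fused"),
       enhanced_ir = feature_map(enh_ir, H, W, "fused"),
       kl_field = kl_field, align_weights = w_region)
}
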