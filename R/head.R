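# Decoupled dual-target set-prediction head.
#
# DETR-style: the fused visual map is projected to d_model, flattened to
# tokens with 2-D sinusoidal positional encoding and passed through N
# transformer encoder blocks; two independent query sets (pest / predator)
# are decoded against the shared memory by M decoder blocks; per-branch
# three-layer MLPs emit sigmoid-normalized (cx, cy, w, h) boxes and
# softmax class distributions over the 8 classes plus a no-object slot.
# Training matches queries to ground truth by Hungarian assignment and
# minimizes  L = lambda_cls L_cls + lambda_bbox L_bbox + lambda_giou L_giou
# (+ mu L_contrastive),  with inverse-frequency class weights in L_cls.

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Exact O(n^3) potentials implementation for rectangular cost matrices;
#' `min(nrow, ncol)` pairs are matched. Ties resolve deterministically toward
#' the lowest column index.
#' @param cost Finite numeric cost matrix (queries x targets).
#' @return A tibble with columns `query`, `target` (1-based indices), one row
#'   per matched pair.
#' @export
#' @examples
#' hungarian_assign(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  if (ncol(cost) == 0L || nrow(cost) == 0L) {
    return(tibble::tibble(query = integer(0), target = integer(0)))
  }
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  if (nrow(cost) >= ncol(cost)) {
    # rows = queries (more), run the core on targets x queries
    a <- hungarian_core(t(cost))
    tibble::tibble(query = a, target = seq_along(a))
  } else {
    a <- hungarian_core(cost)
    tibble::tibble(query = seq_along(a), target = a)
  }
}

# core: n x m with n <= m; returns col index assigned to each row
hungarian_core <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  J <- m + 1L                       # virtual start column
  u <- numeric(n); v <- numeric(J)
  p <- integer(J)                   # row matched to each column (0 = free)
  way <- integer(J)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[J] <- i
    j0 <- J
    minv <- rep(Inf, J)
    used <- rep(FALSE, J)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- cols[!used[cols]]
      cur <- cost[i0, free] - u[i0] - v[free]
      better <- cur < minv[free]
      if (any(better)) {
        jb <- free[better]
        minv[jb] <- cur[better]
        way[jb] <- j0
      }
      k <- which.min(minv[free])
      delta <- minv[free][k]
      j1 <- free[k]
      uu <- which(used)
      ur <- p[uu]
      u[ur[ur > 0L]] <- u[ur[ur > 0L]] + delta
      v[uu] <- v[uu] - delta
      minv[cols[!used[cols]]] <- minv[cols[!used[cols]]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J) break
    }
  }
  out <- integer(n)
  for (j in cols) if (p[j] > 0L) out[p[j]] <- j
  out
}

#' Inverse-frequency class weights
#'
#' `w_i = N_total / (C * n_i)`, capped at 10x the median weight; zero-count
#' classes receive the largest finite weight before capping. Balanced counts
#' give unit weights and the weights are invariant to rescaling all counts.
#' @param counts Nonnegative per-class instance counts.
#' @return Positive weight vector of `length(counts)`.
#' @export
#' @examples
#' class_weights(c(3, 1)) # (4/6, 4/2)
class_weights <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all class counts are zero")
  C <- length(counts)
  w <- sum(counts) / (C * counts)
  if (any(!is.finite(w))) w[!is.finite(w)] <- max(w[is.finite(w)])
  cap <- 10 * stats::median(w)
  pmin(w, cap)
}

#' Class-weighted cross-entropy of one prediction row
#'
#' `L = -omega_y log(p_y)` (natural log), the single-row form of the weighted
#' classification loss. Probabilities below `1e-12` are clamped with a
#' warning.
#' @param p Probability row (sums to 1).
#' @param label 1-based true-class index (the no-object slot is a class like
#'   any other).
#' @param weights Per-class weights aligned with `p`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' weighted_ce(c(0.5, 0.5), 1, c(2, 1)) # -2 log 0.5
weighted_ce <- function(p, label, weights) {
  stopifnot(length(p) == length(weights), label >= 1, label <= length(p))
  pi <- p[label]
  if (pi < 1e-12) {
    warning("true-class probability clamped at 1e-12")
    pi <- 1e-12
  }
  -weights[label] * log(pi)
}

#' Construct the set-prediction head
#' @param cfg A [pf_config()].
#' @return A module list (encoder stack plus one decoder branch per target
#'   group when `flags$decoupled_head`, otherwise a single shared branch).
#' @export
head_new <- function(cfg) {
  d <- cfg$head$d_model; h <- cfg$head$heads; ffn <- cfg$head$ffn
  C1 <- cfg$head$n_classes + 1L
  enc_layer <- function() list(
    ln1g = ag_param(rep(1, d)), ln1b = ag_param(numeric(d)),
    att = mha_new(d, h),
    ln2g = ag_param(rep(1, d)), ln2b = ag_param(numeric(d)),
    ff1 = linear_new(d, ffn), ff2 = linear_new(ffn, d))
  dec_layer <- function() list(
    ln1g = ag_param(rep(1, d)), ln1b = ag_param(numeric(d)),
    self_att = mha_new(d, h),
    ln2g = ag_param(rep(1, d)), ln2b = ag_param(numeric(d)),
    cross_att = mha_new(d, h),
    ln3g = ag_param(rep(1, d)), ln3b = ag_param(numeric(d)),
    ff1 = linear_new(d, ffn), ff2 = linear_new(ffn, d))
  # queries follow the anchor convention: a learned positional embedding plus
  # a learnable reference box (pre-sigmoid); the box MLP predicts offsets from
  # the reference, which makes localization learnable in few epochs
  nq <- cfg$head$n_queries
  branch <- function() list(
    query_pos = ag_param(matrix(stats::rnorm(nq * d, sd = 0.1), ncol = d)),
    anchors = ag_param(anchor_init(nq)),
    layers = lapply(seq_len(cfg$head$n_dec), function(i) dec_layer()),
    lnfg = ag_param(rep(1, d)), lnfb = ag_param(numeric(d)),
    box1 = linear_new(d, d), box2 = linear_new(d, d), box3 = linear_new(d, 4L),
    cls1 = linear_new(d, d), cls2 = linear_new(d, d), cls3 = linear_new(d, C1))
  branches <- if (isTRUE(cfg$flags$decoupled_head)) {
    list(pest = branch(), predator = branch())
  } else {
    list(shared = branch())
  }
  structure(list(
    proj = conv_new(cfg$ema$gate_c, d, 1L),
    con_proj = linear_new(d, max(16L, d %/% 4L)),
    enc_layers = lapply(seq_len(cfg$head$n_enc), function(i) enc_layer()),
    branches = branches, d = d, n_queries = cfg$head$n_queries,
    n_classes = cfg$head$n_classes),
    class = "pf_head")
}

# pre-sigmoid reference boxes spread over a regular grid
anchor_init <- function(nq) {
  g <- ceiling(sqrt(nq))
  cx <- (rep(seq_len(g), times = g) - 0.5) / g
  cy <- (rep(seq_len(g), each = g) - 0.5) / g
  inv_sig <- function(p) log(p / (1 - p))
  m <- cbind(inv_sig(cx), inv_sig(cy), inv_sig(0.35), inv_sig(0.35))
  m[seq_len(nq), , drop = FALSE]
}

#' Transformer-encode a fused feature map into memory tokens
#'
#' Projects to `d_model` and runs the pre-norm encoder stack; the 2-D
#' sinusoidal positional encoding is added to queries and keys at every
#' attention layer (the DETR convention), values carry content only. Token
#' count equals `H * W` of the input map.
#' @param head A [head_new()] module.
#' @param fused_fm A [feature_map()] with `C'` channels.
#' @return `(H*W) x d_model` memory node.
#' @export
transformer_encode <- function(head, fused_fm) {
  x <- conv_apply(head$proj, fused_fm$x, fused_fm$H, fused_fm$W)$x
  pe <- posenc_2d(fused_fm$H, fused_fm$W, head$d)
  for (ly in head$enc_layers) {
    a <- layernorm_apply(x, ly$ln1g, ly$ln1b)
    ap <- ag_add(a, pe)
    x <- ag_add(x, mha_apply(ly$att, ap, ap, a))
    f <- layernorm_apply(x, ly$ln2g, ly$ln2b)
    x <- ag_add(x, linear_apply(ly$ff2, ag_relu(linear_apply(ly$ff1, f))))
  }
  x
}

#' Decode one branch's query set against shared memory
#'
#' Branches never exchange information: each runs its own decoder stack of
#' self-attention, cross-attention to the memory, and a feed-forward block.
#' Content embeddings start at zero; the learned query positional embedding is
#' added to queries/keys at each layer, and the memory positional encoding to
#' the cross-attention keys.
#' @param head A [head_new()] module.
#' @param memory Encoder output node.
#' @param branch Branch name (`"pest"`, `"predator"`, or `"shared"`).
#' @param pe_mem Positional encoding of the memory tokens (matrix, or NULL
#'   for none).
#' @return `N_q x d_model` embedding node.
#' @export
transformer_decode <- function(head, memory, branch, pe_mem = NULL,
                               geom = NULL) {
  br <- head$branches[[branch]]
  if (is.null(br)) stop(sprintf("unknown branch '%s'", branch))
  qpos <- br$query_pos
  if (!is.null(geom)) {
    # anchor-conditioned query encoding: the sinusoidal code of each query
    # reference centre (detached), so cross attention starts out local
    av <- 1 / (1 + exp(-ag_val(br$anchors)))
    qpos <- ag_add(qpos, posenc_xy(av[, 1], av[, 2], geom[1], geom[2], head$d))
  }
  x <- matrix(0, nrow(ag_val(qpos)), head$d)
  mem_k <- if (is.null(pe_mem)) memory else ag_add(memory, pe_mem)
  for (ly in br$layers) {
    a <- layernorm_apply(ag_add(x, 0), ly$ln1g, ly$ln1b)
    aq <- ag_add(a, qpos)
    x <- ag_add(x, mha_apply(ly$self_att, aq, aq, a))
    q <- layernorm_apply(x, ly$ln2g, ly$ln2b)
    x <- ag_add(x, mha_apply(ly$cross_att, ag_add(q, qpos), mem_k, memory))
    f <- layernorm_apply(x, ly$ln3g, ly$ln3b)
    x <- ag_add(x, linear_apply(ly$ff2, ag_relu(linear_apply(ly$ff1, f))))
  }
  layernorm_apply(x, br$lnfg, br$lnfb)
}

#' Predict boxes and class distributions from query embeddings
#'
#' Three-layer MLPs per branch; boxes are sigmoid-normalized `(cx, cy, w, h)`
#' in `[0,1]^4`, class rows are softmax distributions over the 8 classes plus
#' the no-object slot.
#' @param head A [head_new()] module.
#' @param emb `N_q x d_model` node from [transformer_decode()].
#' @param branch Branch name.
#' @return A `pf_detout` list: `boxes` (`N_q x 4` node), `class_probs`
#'   (`N_q x (C+1)` node), `branch`.
#' @export
head_predict <- function(head, emb, branch) {
  br <- head$branches[[branch]]
  bx <- linear_apply(br$box3, ag_relu(linear_apply(br$box2,
          ag_relu(linear_apply(br$box1, emb)))))
  cl <- linear_apply(br$cls3, ag_relu(linear_apply(br$cls2,
          ag_relu(linear_apply(br$cls1, emb)))))
  structure(list(boxes = ag_sigmoid(ag_add(bx, br$anchors)),
                 class_probs = ag_softmax_rows(cl),
                 branch = branch),
            class = "pf_detout")
}

#' Matching cost matrix between predictions and ground truth
#'
#' `cost[q, t] = lambda_cls (1 - p_q(label_t)) + lambda_bbox |b_q - b_t|_1 +
#' lambda_giou (1 - GIoU(b_q, b_t))`, evaluated on detached values.
#' @param class_probs `N_q x (C+1)` probability matrix (values).
#' @param boxes `N_q x 4` normalized `(cx, cy, w, h)` matrix (values).
#' @param gt_boxes `n_gt x 4` normalized `(cx, cy, w, h)` matrix.
#' @param gt_labels 0-based class indices of the targets.
#' @param lw List with `lambda_cls`, `lambda_bbox`, `lambda_giou`.
#' @return `N_q x n_gt` numeric matrix (0 columns when no targets).
#' @export
match_cost <- function(class_probs, boxes, gt_boxes, gt_labels, lw) {
  class_probs <- ag_val(class_probs); boxes <- ag_val(boxes)
  n_gt <- nrow(gt_boxes)
  if (is.null(n_gt) || n_gt == 0L) return(matrix(0, nrow(boxes), 0L))
  pc <- cxcywh_to_corners(boxes, 1)
  gc <- cxcywh_to_corners(gt_boxes, 1)
  cost <- matrix(0, nrow(boxes), n_gt)
  for (t in seq_len(n_gt)) {
    l1 <- rowSums(abs(boxes - matrix(gt_boxes[t, ], nrow(boxes), 4, byrow = TRUE)))
    gi <- vapply(seq_len(nrow(boxes)), function(q) giou_box(pc[q, ], gc[t, ]),
                 numeric(1))
    cost[, t] <- lw$lambda_cls * (1 - class_probs[, gt_labels[t] + 1L]) +
      lw$lambda_bbox * l1 + lw$lambda_giou * (1 - gi)
  }
  cost
}

# differentiable GIoU of predicted (cx,cy,w,h) rows against constant gt rows
giou_ag <- function(pred, gt) {
  cx <- ag_slice_cols(pred, 1L); cy <- ag_slice_cols(pred, 2L)
  w <- ag_slice_cols(pred, 3L); h <- ag_slice_cols(pred, 4L)
  x1 <- ag_sub(cx, ag_mul(w, 0.5)); x2 <- ag_add(cx, ag_mul(w, 0.5))
  y1 <- ag_sub(cy, ag_mul(h, 0.5)); y2 <- ag_add(cy, ag_mul(h, 0.5))
  g <- cxcywh_to_corners(gt, 1)
  gx1 <- g[, 1, drop = FALSE]; gy1 <- g[, 2, drop = FALSE]
  gx2 <- g[, 3, drop = FALSE]; gy2 <- g[, 4, drop = FALSE]
  iw <- ag_relu(ag_sub(ag_pmin2(x2, gx2), ag_pmax2(x1, gx1)))
  ih <- ag_relu(ag_sub(ag_pmin2(y2, gy2), ag_pmax2(y1, gy1)))
  inter <- ag_mul(iw, ih)
  area_p <- ag_mul(w, h)
  area_g <- (gx2 - gx1) * (gy2 - gy1)
  union <- ag_add(ag_sub(ag_add(area_p, area_g), inter), 1e-9)
  hw <- ag_sub(ag_pmax2(x2, gx2), ag_pmin2(x1, gx1))
  hh <- ag_sub(ag_pmax2(y2, gy2), ag_pmin2(y1, gy1))
  hull <- ag_add(ag_mul(hw, hh), 1e-9)
  ag_sub(ag_div(inter, union), ag_div(ag_sub(hull, union), hull))
}

#' Supervised contrastive loss over group-labelled embeddings
#'
#' Embeddings are L2-normalized; for each anchor with at least one same-group
#' positive, the loss is the mean over positives of
#' `-log exp(s_ip / tau) / sum_{a != i} exp(s_ia / tau)`, averaged over
#' anchors. Invariant to global rotations; a single-group batch contributes
#' only the intra-group pull term.
#' @param emb `M x d` embedding node (`M >= 2` for a nonzero loss).
#' @param groups Character vector of group labels (`"pest"` / `"predator"`).
#' @param tau Temperature (default 0.1).
#' @return A nonnegative scalar node.
#' @export
contrastive_loss <- function(emb, groups, tau = 0.1) {
  M <- nrow(ag_val(emb))
  if (M < 2L) return(ag_mul(ag_sum(ag_mul(emb, 0)), 0))
  inv <- ag_div(1, ag_sqrt(ag_add(ag_rowsums(ag_mul(emb, emb)), 1e-12)))
  z <- ag_mul_colvec(emb, inv)
  sim <- ag_mul(ag_matmul_t(z, z), 1 / tau)
  off <- 1 - diag(M)
  mrow <- apply(ag_val(sim) * off - 1e9 * diag(M), 1L, max)  # detached stabilizer
  sim_s <- ag_add_colvec(sim, -mrow)
  E <- ag_mul(ag_exp(sim_s), off)
  lse <- ag_log(ag_add(ag_rowsums(E), 1e-30))
  logp <- ag_add_colvec(sim_s, ag_mul(lse, -1))
  pos <- outer(groups, groups, "==") * off
  npos <- rowSums(pos)
  anchors <- npos > 0
  if (!any(anchors)) return(ag_mul(ag_sum(ag_mul(emb, 0)), 0))
  Wm <- pos / pmax(npos, 1)
  Wm[!anchors, ] <- 0
  ag_mul(ag_sum(ag_mul(logp, Wm)), -1 / sum(anchors))
}

#' Per-branch detection loss with Hungarian matching
#'
#' Matches queries to targets on the detached cost of [match_cost()], then
#' computes the weighted classification loss over all queries (matched and
#' no-object) and L1 + GIoU box losses over matched pairs only.
#' @param det A `pf_detout` from [head_predict()].
#' @param gt_boxes `n_gt x 4` normalized `(cx, cy, w, h)` matrix.
#' @param gt_labels 0-based class indices.
#' @param omega Per-class weights over `C + 1` slots (no-object last).
#' @param lw Loss-weight list (see [match_cost()]).
#' @return List: `L_cls`, `L_bbox`, `L_giou` (scalar nodes), `assignment`
#'   (tibble), `matched_queries` (integer vector).
#' @export
detection_loss <- function(det, gt_boxes, gt_labels, omega, lw) {
  probs <- det$class_probs
  pv <- ag_val(probs)
  Nq <- nrow(pv); C1 <- ncol(pv)
  n_gt <- if (is.null(nrow(gt_boxes))) 0L else nrow(gt_boxes)
  target_class <- rep(C1, Nq)  # no-object slot
  assignment <- tibble::tibble(query = integer(0), target = integer(0))
  if (n_gt > 0L) {
    cost <- match_cost(pv, ag_val(det$boxes), gt_boxes, gt_labels, lw)
    assignment <- hungarian_assign(cost)
    target_class[assignment$query] <- gt_labels[assignment$target] + 1L
  }
  Y <- matrix(0, Nq, C1)
  Y[cbind(seq_len(Nq), target_class)] <- 1
  wq <- omega[target_class]
  logp <- ag_log(ag_pmax2(probs, 1e-12))
  L_cls <- ag_div(ag_mul(ag_sum(ag_mul(logp, Y * wq)), -1), sum(wq))
  if (n_gt > 0L) {
    pb <- ag_slice_rows(det$boxes, assignment$query)
    gb <- gt_boxes[assignment$target, , drop = FALSE]
    L_bbox <- ag_div(ag_sum(ag_relu_abs(ag_sub(pb, gb))), n_gt)
    L_giou <- ag_div(ag_sum(ag_sub(1, giou_ag(pb, gb))), n_gt)
  } else {
    L_bbox <- ag_mul(ag_sum(ag_mul(det$boxes, 0)), 0)
    L_giou <- ag_mul(ag_sum(ag_mul(det$boxes, 0)), 0)
  }
  list(L_cls = L_cls, L_bbox = L_bbox, L_giou = L_giou,
       assignment = assignment, matched_queries = assignment$query)
}

# |x| with subgradient 0 at the kink
ag_relu_abs <- function(x) ag_pmax2(x, ag_mul(x, -1))
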