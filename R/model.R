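# Full multimodal detector: encoders -> CMA fusion -> environment gate ->
# set-prediction head, with the ablation switches rewiring the graph.
#
# Dataflow. The two image encoders emit C x H x W maps. CMA produces
# per-modality enhanced maps plus a merged map (all C' channels). A shared
# adapter carries each into the gate's geometry (identity at tiny scale),
# where the environment gate g and the learnable mixing coefficient alpha
# apply F_fused = g * (alpha F_RGB + (1 - alpha) F_IR) to the enhanced maps.
# The gated map and the adapted CMA merge are combined by a learned 1x1 conv
# and fed to the transformer head, so both the bottom-up (cross-modal
# attention) and top-down (environment gating) paths shape the final features.
#
# Ablations: use_cma = FALSE replaces CMA by per-modality 1x1 projections plus
# channel concatenation + 1x1 conv; use_ema = FALSE fixes g == 1 (alpha stays
# learnable); use_reweighting = FALSE freezes alpha at 0.5 and disables the
# KL alignment weighting inside CMA; decoupled_head = FALSE uses one shared
# query set over all 8 classes. A missing thermal or sensor modality is
# replaced by a learned constant stream.

#' Construct the full detection model
#'
#' @param cfg A [pf_config()]. Weight initialization is controlled by
#'   `cfg$seed`.
#' @return A `pf_model` module tree.
#' @export
pf_model_new <- function(cfg) {
  set.seed(cfg$seed)
  m <- list(cfg = cfg)
  m$enc_rgb <- image_encoder_new(3L, cfg$encoder$channels,
                                 cfg$encoder$spatial, cfg$encoder$depth)
  if ("thermal" %in% cfg$modalities) {
    m$enc_ir <- image_encoder_new(1L, cfg$encoder$channels,
                                  cfg$encoder$spatial, cfg$encoder$depth)
  } else {
    m$const_ir <- ag_param(matrix(stats::rnorm(cfg$encoder$channels, sd = 0.1),
                                  nrow = 1))
  }
  if (isTRUE(cfg$flags$use_cma)) {
    m$cma <- cma_new(cfg)
  } else {
    Cc <- cfg$encoder$channels; Cp <- cfg$cma$cprime
    nocma_merge <- conv_new(2L * Cp, Cp, 1L)
    nocma_merge$W$value <- rbind(diag(0.5, Cp), diag(0.5, Cp)) +
      matrix(stats::rnorm(2 * Cp * Cp, sd = 0.02), 2 * Cp, Cp)
    m$nocma <- list(proj_rgb = conv_new(Cc, Cp, 1L),
                    proj_ir = conv_new(Cc, Cp, 1L),
                    merge = nocma_merge)
  }
  use_env <- isTRUE(cfg$flags$use_ema) && "sensor" %in% cfg$modalities
  if (use_env) {
    m$ema <- ema_new(cfg)
  } else if (isTRUE(cfg$flags$use_reweighting)) {
    m$alpha_raw <- ag_param(0)  # sigmoid(0) = 0.5
  }
  if (!"sensor" %in% cfg$modalities && isTRUE(cfg$flags$use_ema)) {
    m$const_env <- ag_param(matrix(0, cfg$ema$history, 3L))
  }
  m$adapter <- gate_adapter_new(cfg)
  gc_ <- cfg$ema$gate_c
  # combine starts as the average of the merged and gated streams
  m$combine <- conv_new(2L * gc_, gc_, 1L)
  m$combine$W$value <- rbind(diag(0.5, gc_), diag(0.5, gc_)) +
    matrix(stats::rnorm(2 * gc_ * gc_, sd = 0.02), 2 * gc_, gc_)
  m$head <- head_new(cfg)
  structure(m, class = "pf_model")
}

model_alpha <- function(model) {
  cfg <- model$cfg
  if (!isTRUE(cfg$flags$use_reweighting)) return(0.5)
  if (!is.null(model$ema)) return(ag_sigmoid(model$ema$alpha_raw))
  ag_sigmoid(model$alpha_raw)
}

#' Forward pass over one aligned sample
#'
#' @param model A [pf_model_new()].
#' @param sample A `pf_sample` from [assemble_sample()].
#' @return List: `dets` (named list of `pf_detout` per branch), `gate`
#'   (numeric gate values), `alpha` (numeric), `embeddings` (per-branch query
#'   embedding nodes), `fused` (`pf_fmap` fed to the head), `cma` (the CMA
#'   diagnostics, when active).
#' @export
model_forward <- function(model, sample) {
  cfg <- model$cfg
  fm_rgb <- encode_image(model$enc_rgb, sample$rgb, "rgb")
  if (!is.null(model$enc_ir)) {
    fm_ir <- encode_image(model$enc_ir, sample$thermal, "thermal")
  } else {
    N <- fm_rgb$H * fm_rgb$W
    fm_ir <- feature_map(ag_matmul(matrix(1, N, 1), model$const_ir),
                         fm_rgb$H, fm_rgb$W, "thermal")
  }

  cma_out <- NULL
  if (!is.null(model$cma)) {
    cma_out <- cma_forward(model$cma, fm_rgb, fm_ir,
                           reweight = isTRUE(cfg$flags$use_reweighting))
    f_rgb <- cma_out$enhanced_rgb
    f_ir <- cma_out$enhanced_ir
    merged <- cma_out$fused
  } else {
    H <- fm_rgb$H; W <- fm_rgb$W
    f_rgb <- feature_map(conv_apply(model$nocma$proj_rgb, fm_rgb$x, H, W)$x,
                         H, W, "fused")
    f_ir <- feature_map(conv_apply(model$nocma$proj_ir, fm_ir$x, H, W)$x,
                        H, W, "fused")
    merged <- feature_map(
      conv_apply(model$nocma$merge, ag_cbind(list(f_rgb$x, f_ir$x)), H, W)$x,
      H, W, "fused")
  }

  a_rgb <- gate_adapter_apply(model$adapter, f_rgb)
  a_ir <- gate_adapter_apply(model$adapter, f_ir)
  a_merged <- gate_adapter_apply(model$adapter, merged)

  alpha <- model_alpha(model)
  if (!is.null(model$ema)) {
    if (!is.null(model$const_env)) {
      # learned-constant sensor stream: gradient flows into const_env
      hist <- ag_sigmoid(model$const_env)
      y <- ssm_block(model$ema, linear_apply(model$ema$env_enc$lin, hist))
      s_log <- linear_apply(model$ema$gate_spatial, y)
      c_log <- linear_apply(model$ema$gate_channel, y)
      g <- ag_sigmoid(ag_outer_add(ag_t(s_log), c_log))
    } else {
      g <- build_gate(model$ema, sample$env_history)$g
    }
    gate_vals <- ag_val(g)
  } else {
    g <- 1
    gate_vals <- matrix(1, a_rgb$H * a_rgb$W, a_rgb$C)
  }

  eq1 <- fuse_gate(a_rgb$x, a_ir$x, g, alpha)
  head_in <- conv_apply(model$combine, ag_cbind(list(a_merged$x, eq1)),
                        a_merged$H, a_merged$W)$x
  fused_fm <- feature_map(head_in, a_merged$H, a_merged$W, "fused")

  memory <- transformer_encode(model$head, fused_fm)
  pe_mem <- posenc_2d(fused_fm$H, fused_fm$W, model$head$d)
  branches <- names(model$head$branches)
  dets <- list(); embeddings <- list()
  for (br in branches) {
    emb <- transformer_decode(model$head, memory, br, pe_mem,
                              geom = c(fused_fm$H, fused_fm$W))
    embeddings[[br]] <- emb
    dets[[br]] <- head_predict(model$head, emb, br)
  }
  list(dets = dets, gate = gate_vals, alpha = ag_val(alpha),
       embeddings = embeddings, fused = fused_fm, cma = cma_out)
}

# ground truth of one scene in normalized (cx, cy, w, h), routed per branch
scene_targets <- function(scene, decoupled) {
  b <- scene$boxes
  S <- scene$image_size
  if (nrow(b) == 0) {
    empty <- list(boxes = matrix(numeric(0), 0, 4), labels = integer(0))
    if (decoupled) return(list(pest = empty, predator = empty))
    return(list(shared = empty))
  }
  cx <- corners_to_cxcywh(as.matrix(b[, c("xmin", "ymin", "xmax", "ymax")]), S)
  if (!decoupled) {
    return(list(shared = list(boxes = cx, labels = b$class_id)))
  }
  out <- list()
  for (gr in c("pest", "predator")) {
    sel <- b$group == gr
    out[[gr]] <- list(boxes = cx[sel, , drop = FALSE],
                      labels = b$class_id[sel])
  }
  out
}

#' Training loss over a batch of scenes
#'
#' Per scene and branch: Hungarian-matched weighted CE + L1 + GIoU; one
#' batch-level contrastive term over all matched query embeddings with their
#' pest/predator group labels. Components are averaged over scene-branch
#' pairs and combined as
#' `L = lambda_cls L_cls + lambda_bbox L_bbox + lambda_giou L_giou + mu L_con`.
#' @param model A `pf_model`.
#' @param samples List of `pf_sample`s.
#' @param scenes Matching list of `pf_scene`s (for ground truth).
#' @param omega Class-weight vector over `C + 1` slots.
#' @return List: `total` (scalar node), `breakdown` (named numerics:
#'   `L_cls`, `L_bbox`, `L_giou`, `L_contrastive`, `L_total`).
#' @export
model_loss <- function(model, samples, scenes, omega) {
  cfg <- model$cfg
  lw <- cfg$loss
  decoupled <- isTRUE(cfg$flags$decoupled_head)
  cls_terms <- list(); bbox_terms <- list(); giou_terms <- list()
  con_emb <- list(); con_grp <- character(0)
  n_units <- 0L
  for (i in seq_along(samples)) {
    fw <- model_forward(model, samples[[i]])
    tg <- scene_targets(scenes[[i]], decoupled)
    for (br in names(fw$dets)) {
      t_br <- tg[[br]]
      dl <- detection_loss(fw$dets[[br]], t_br$boxes, t_br$labels, omega, lw)
      n_units <- n_units + 1L
      cls_terms[[n_units]] <- dl$L_cls
      bbox_terms[[n_units]] <- dl$L_bbox
      giou_terms[[n_units]] <- dl$L_giou
      if (nrow(dl$assignment) > 0) {
        # contrastive term acts on a projection of the embeddings, so the
        # group-level pull cannot collapse the class-discriminative space
        con_emb[[length(con_emb) + 1L]] <- linear_apply(
          model$head$con_proj,
          ag_slice_rows(fw$embeddings[[br]], dl$assignment$query))
        con_grp <- c(con_grp,
                     class_group(t_br$labels[dl$assignment$target]))
      }
    }
  }
  sum_nodes <- function(xs) Reduce(ag_add, xs)
  L_cls <- ag_mul(sum_nodes(cls_terms), 1 / n_units)
  L_bbox <- ag_mul(sum_nodes(bbox_terms), 1 / n_units)
  L_giou <- ag_mul(sum_nodes(giou_terms), 1 / n_units)
  L_con <- if (length(con_emb) > 0) {
    contrastive_loss(ag_rbind(con_emb), con_grp, tau = lw$tau_c)
  } else {
    0
  }
  total <- ag_add(ag_add(ag_mul(L_cls, lw$lambda_cls),
                         ag_mul(L_bbox, lw$lambda_bbox)),
                  ag_add(ag_mul(L_giou, lw$lambda_giou),
                         ag_mul(L_con, lw$mu_contrastive)))
  list(total = total,
       breakdown = c(L_cls = ag_val(L_cls), L_bbox = ag_val(L_bbox),
                     L_giou = ag_val(L_giou), L_contrastive = ag_val(L_con),
                     L_total = ag_val(total)))
}

#' Run inference on one scene
#'
#' Each query becomes a candidate detection: its class is the argmax over the
#' 8 real classes and its score that class's softmax probability (the
#' no-object slot absorbs the rest, so background queries score low).
#' @param model A `pf_model`.
#' @param sample A `pf_sample`.
#' @param image_id Identifier recorded in the output rows.
#' @param image_size Frame side in pixels for box denormalization.
#' @param score_threshold Drop detections below this score.
#' @return Tibble `image_id`, `class_id`, `group`, `score`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (pixel corner boxes).
#' @export
model_predict <- function(model, sample, image_id = 1L,
                          image_size = model$cfg$data$image_size,
                          score_threshold = 0) {
  fw <- ag_no_grad(model_forward(model, sample))
  C <- model$cfg$head$n_classes
  out <- list()
  for (br in names(fw$dets)) {
    probs <- ag_val(fw$dets[[br]]$class_probs)
    boxes <- ag_val(fw$dets[[br]]$boxes)
    real <- probs[, seq_len(C), drop = FALSE]
    cls <- max.col(real, ties.method = "first")
    score <- real[cbind(seq_len(nrow(real)), cls)]
    corners <- cxcywh_to_corners(boxes, image_size)
    corners <- pmin(pmax(corners, 0), image_size)
    out[[br]] <- tibble::tibble(
      image_id = image_id, class_id = cls - 1L,
      group = class_group(cls - 1L), score = score,
      xmin = corners[, 1], ymin = corners[, 2],
      xmax = corners[, 3], ymax = corners[, 4])
  }
  res <- dplyr::bind_rows(out)
  res[res$score >= score_threshold & res$xmax > res$xmin &
        res$ymax > res$ymin, , drop = FALSE]
}
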