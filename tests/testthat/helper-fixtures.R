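# Shared fixtures: tiny scenes, aligned samples and small random tensors.

tiny_cfg <- function(...) pf_config("tiny", ...)

tiny_scenes <- function(n = 4, seed = 0, image_size = 64L, n_targets = 2L) {
  sample_dataset(n, scene_spec(image_size = image_size, n_targets = n_targets,
                               seed = seed), seed = seed)
}

tiny_samples <- function(scenes, cfg = tiny_cfg()) {
  stats <- norm_stats(dplyr::bind_rows(lapply(scenes, function(s) s$env)))
  lapply(scenes, function(sc) {
    assemble_sample(sc$rgb, sc$thermal, sc$env, sc$timestamp, stats,
                    cfg$ema$history)
  })
}

rand_mat <- function(n, m, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m, sd = sd), n, m)
}

# brute-force assignment minimum over all permutations (n <= m)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf; best_cols <- NULL
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best - 1e-12) {
        best <- tot; best_cols <- p
      }
    }
  }
  list(cost = best, cols = best_cols)
}

# rasterization oracle for IoU / GIoU on a fine grid of cell centres;
# `scale` = cells per coordinate unit, so boxes with corners on the 1/scale
# lattice are rasterized exactly
raster_iou_giou <- function(a, b, scale = 20L) {
  lo <- c(min(a[1], b[1]), min(a[2], b[2]))
  hi <- c(max(a[3], b[3]), max(a[4], b[4]))
  nx <- max(1L, round((hi[1] - lo[1]) * scale))
  ny <- max(1L, round((hi[2] - lo[2]) * scale))
  xs <- seq(lo[1], hi[1], length.out = nx + 1L)
  ys <- seq(lo[2], hi[2], length.out = ny + 1L)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  cell_area <- diff(xs)[1] * diff(ys)[1]
  inx_a <- cx > a[1] & cx < a[3]; iny_a <- cy > a[2] & cy < a[4]
  inx_b <- cx > b[1] & cx < b[3]; iny_b <- cy > b[2] & cy < b[4]
  area_a <- sum(outer(iny_a, inx_a, "&")) * cell_area
  area_b <- sum(outer(iny_b, inx_b, "&")) * cell_area
  inter <- sum(outer(iny_a & iny_b, inx_a & inx_b, "&")) * cell_area
  union <- area_a + area_b - inter
  hull <- (hi[1] - lo[1]) * (hi[2] - lo[2])
  list(iou = inter / union, giou = inter / union - (hull - union) / hull)
}

# independent nested-loop AP/mAP oracle (second matching pass, written naively)
oracle_map50 <- function(dets, gts, iou_threshold = 0.5) {
  aps <- c()
  for (cl in sort(unique(gts$class_id))) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      best_iou <- 0; best_j <- 0
      for (j in seq_len(nrow(g))) {
        if (used[j] || g$image_id[j] != d$image_id[i]) next
        iou <- box_iou(c(d$xmin[i], d$ymin[i], d$xmax[i], d$ymax[i]),
                       c(g$xmin[j], g$ymin[j], g$xmax[j], g$ymax[j]))
        if (iou > best_iou) { best_iou <- iou; best_j <- j }
      }
      if (best_iou >= iou_threshold) { tp[i] <- TRUE; used[best_j] <- TRUE }
    }
    # step-function area under the interpolated PR curve, computed naively
    n_gt <- nrow(g)
    if (!any(tp)) { aps <- c(aps, 0); next }
    prec <- cumsum(tp) / seq_along(tp)
    rec <- cumsum(tp) / n_gt
    ap <- 0
    prev_r <- 0
    for (r in unique(rec[tp])) {
      p_max <- max(prec[rec >= r])
      ap <- ap + (r - prev_r) * p_max
      prev_r <- r
    }
    aps <- c(aps, ap)
  }
  mean(aps)
}

# random toy detection problem for metric oracles
random_detection_set <- function(seed, n_classes = 4, n_images = 3) {
  set.seed(seed)
  gts <- purrr::map_dfr(seq_len(n_images), function(im) {
    n <- sample(0:4, 1)
    if (n == 0) return(NULL)
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    tibble::tibble(image_id = im, class_id = sample(n_classes, n, TRUE) - 1L,
                   xmin = x, ymin = y, xmax = x + runif(n, 10, 20),
                   ymax = y + runif(n, 10, 20))
  })
  if (nrow(gts) == 0) return(random_detection_set(seed + 1000, n_classes, n_images))
  n_det <- sample(5:30, 1)
  base <- gts[sample(nrow(gts), n_det, replace = TRUE), , drop = FALSE]
  jit <- function(v, s) v + rnorm(length(v), sd = s)
  dets <- tibble::tibble(
    image_id = base$image_id,
    class_id = ifelse(runif(n_det) < 0.75, base$class_id,
                      sample(n_classes, n_det, TRUE) - 1L),
    score = runif(n_det),
    xmin = jit(base$xmin, 4), ymin = jit(base$ymin, 4),
    xmax = jit(base$xmax, 4), ymax = jit(base$ymax, 4))
  keep <- dets$xmax > dets$xmin & dets$ymax > dets$ymin
  list(dets = dets[keep, , drop = FALSE], gts = gts)
}
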