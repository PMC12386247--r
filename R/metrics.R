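# Detection metrics: precision, recall, F1, per-class AP at IoU 0.5 and
# mAP@50. Detections and ground truth are plain tibbles, so evaluation
# composes with dplyr; the matching protocol is the PASCAL-VOC convention:
# detections sorted by descending score, each greedily matched one-to-one to
# the unmatched same-class ground-truth box of highest IoU >= 0.5 in the same
# image.

#' Match detections to ground truth at an IoU threshold
#'
#' @param dets Tibble with `image_id`, `class_id`, `score`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (pixel corner boxes).
#' @param gts Tibble with `image_id`, `class_id`, `xmin`, `ymin`, `xmax`,
#'   `ymax`.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return List: `flags` (the `dets` rows in global descending-score order
#'   with a logical `tp` column), `TP`, `FP`, `FN`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(dets) > 0) {
    dets <- dets[order(-dets$score), , drop = FALSE]
    dets$tp <- FALSE
  } else {
    dets$tp <- logical(0)
  }
  gt_used <- rep(FALSE, nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!gt_used &
                    gts$image_id == dets$image_id[i] &
                    gts$class_id == dets$class_id[i])
    if (length(cand) == 0) next
    ious <- box_iou_one_many(
      c(dets$xmin[i], dets$ymin[i], dets$xmax[i], dets$ymax[i]),
      as.matrix(gts[cand, c("xmin", "ymin", "xmax", "ymax")]))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      dets$tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  TP <- sum(dets$tp)
  list(flags = dets, TP = TP, FP = nrow(dets) - TP, FN = sum(!gt_used))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2 P R / (P + R)`; a metric whose denominator is zero is reported
#' as 0.
#' @param TP,FP,FN Nonnegative integer counts.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
#' @examples
#' precision_recall_f1(8, 2, 2)
precision_recall_f1 <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = F1)
}

#' Average precision from ordered TP/FP flags
#'
#' Area under the precision-recall curve with all-point interpolation: the
#' precision envelope is made monotone non-increasing before integrating over
#' recall steps. An 11-point variant is available for comparison.
#' @param tp_flags Logical vector, one entry per detection in descending
#'   score order.
#' @param n_gt Number of ground-truth instances of the class (>= 1).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp_flags, n_gt, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(n_gt >= 1)
  if (length(tp_flags) == 0 || !any(tp_flags)) return(0)
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p) == 0) 0 else max(p)
    }, numeric(1))))
  }
  # monotone envelope, then sum precision * recall increments
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in seq(length(mpre) - 1, 1)) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

#' Mean average precision over evaluable classes
#'
#' Unweighted mean of per-class AP; classes with no ground-truth instance are
#' excluded from the mean rather than scored 0.
#' @param ap Named numeric vector of per-class APs (already restricted to
#'   evaluable classes).
#' @return mAP@50 scalar.
#' @export
map50 <- function(ap) {
  if (length(ap) == 0) stop("no evaluable classes")
  mean(ap)
}

#' Full detection evaluation report
#'
#' Computes global TP/FP/FN, precision/recall/F1 and per-class AP at
#' IoU >= 0.5, optionally after collapsing the 8 fine classes to the
#' pest/predator super-classes.
#' @param dets,gts Tibbles as in [match_detections()].
#' @param iou_threshold IoU threshold (default 0.5).
#' @param group_map If `TRUE`, evaluate over the two super-classes (class ids
#'   0 = pest, 1 = predator) instead of fine classes.
#' @param interpolation AP interpolation mode.
#' @return A `pf_metrics` object: list with `counts` (TP/FP/FN), `precision`,
#'   `recall`, `f1`, `ap` (named per-class vector), `map50`, `n_images`.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                group_map = FALSE,
                                interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (group_map) {
    dets$class_id <- as.integer(class_group(dets$class_id) == "predator")
    gts$class_id <- as.integer(class_group(gts$class_id) == "predator")
  }
  m <- match_detections(dets, gts, iou_threshold)
  prf <- precision_recall_f1(m$TP, m$FP, m$FN)
  classes <- sort(unique(gts$class_id))
  ap <- vapply(classes, function(cl) {
    fl <- m$flags[m$flags$class_id == cl, , drop = FALSE]
    average_precision(fl$tp, sum(gts$class_id == cl), interpolation)
  }, numeric(1))
  names(ap) <- as.character(classes)
  structure(list(counts = c(TP = m$TP, FP = m$FP, FN = m$FN),
                 precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]),
                 f1 = unname(prf["f1"]),
                 ap = ap,
                 map50 = if (length(ap)) map50(ap) else NA_real_,
                 n_images = length(unique(c(dets$image_id, gts$image_id)))),
            class = "pf_metrics")
}

#' @export
print.pf_metrics <- function(x, ...) {
  cat(sprintf("Detection metrics over %d image(s)\n", x$n_images))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["FN"]))
  cat(sprintf("  Precision %.1f%%  Recall %.1f%%  F1 %.1f%%  mAP@50 %.1f%%\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1, 100 * x$map50))
  invisible(x)
}

#' Tidy a metrics report into a per-class tibble
#' @param x A `pf_metrics` object.
#' @param ... Unused.
#' @return Tibble with `class_id`, `ap`.
#' @method tidy pf_metrics
#' @export
tidy.pf_metrics <- function(x, ...) {
  tibble::tibble(class_id = as.integer(names(x$ap)), ap = unname(x$ap))
}

#' One-row summary of a metrics report
#' @param x A `pf_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with counts, precision, recall, F1 and mAP@50.
#' @method glance pf_metrics
#' @export
glance.pf_metrics <- function(x, ...) {
  tibble::tibble(TP = unname(x$counts["TP"]), FP = unname(x$counts["FP"]),
                 FN = unname(x$counts["FN"]), precision = x$precision,
                 recall = x$recall, f1 = x$f1, map50 = x$map50)
}

#' Plot per-class average precision
#' @param object A `pf_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_metrics
#' @export
autoplot.pf_metrics <- function(object, ...) {
  df <- tidy.pf_metrics(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class_id), y = .data$ap)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$map50, linetype = 2) +
    ggplot2::labs(x = "class", y = "AP@50",
                  title = sprintf("mAP@50 = %.3f", object$map50)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Render a plain-text metrics table
#'
#' One row per model/report, percentages to one decimal, mirroring the usual
#' Precision/Recall/F1/mAP@50 comparison-table layout.
#' @param reports Named list of `pf_metrics` objects.
#' @return Character vector of table lines (also printed).
#' @export
metrics_table <- function(reports) {
  lines <- c(sprintf("%-24s %10s %10s %10s %10s", "Model", "Precision",
                     "Recall", "F1-Score", "mAP@50"))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    lines <- c(lines, sprintf("%-24s %9.1f%% %9.1f%% %9.1f%% %9.1f%%", nm,
                              100 * r$precision, 100 * r$recall, 100 * r$f1,
                              100 * r$map50))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Confusion matrix over whatever label set the ground truth declares
#'
#' Each matched detection contributes its (gt class, predicted class) pair;
#' unmatched ground truth counts toward a "missed" column.
#' @param dets,gts Tibbles as in [match_detections()].
#' @param iou_threshold IoU threshold for spatial matching (class-agnostic
#'   here, so cross-class confusions are visible).
#' @return A contingency table.
#' @export
confusion_matrix <- function(dets, gts, iou_threshold = 0.5) {
  gts$pred <- NA_integer_
  used <- rep(FALSE, nrow(dets))
  if (nrow(dets)) dets <- dets[order(-dets$score), , drop = FALSE]
  for (g in seq_len(nrow(gts))) {
    cand <- which(!used & dets$image_id == gts$image_id[g])
    if (!length(cand)) next
    ious <- box_iou_one_many(
      unlist(gts[g, c("xmin", "ymin", "xmax", "ymax")]),
      as.matrix(dets[cand, c("xmin", "ymin", "xmax", "ymax")]))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      gts$pred[g] <- dets$class_id[cand[best]]
      used[cand[best]] <- TRUE
    }
  }
  table(truth = gts$class_id,
        prediction = factor(ifelse(is.na(gts$pred), "missed", gts$pred)))
}
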