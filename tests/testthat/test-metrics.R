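# Evaluation metrics: IoU, greedy matching, precision/recall/F1, AP and mAP,
# cross-checked against an independent nested-loop implementation.

det_row <- function(image_id, class_id, score, box) {
  tibble::tibble(image_id = image_id, class_id = class_id, score = score,
                 xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4])
}

gt_row <- function(image_id, class_id, box) {
  tibble::tibble(image_id = image_id, class_id = class_id,
                 xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4])
}

test_that("IoU matches hand geometry", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 1e-12)
  ref <- raster_iou_giou(c(0, 0, 2, 2), c(1, 1, 3, 3), scale = 50L)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), ref$iou,
               tolerance = 1e-9)
})

test_that("greedy matching enforces one-to-one assignment", {
  gts <- gt_row(1, 0, c(0, 0, 10, 10))
  # perfect prediction
  m <- match_detections(det_row(1, 0, 0.9, c(0, 0, 10, 10)), gts)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))
  # two detections on one gt: 1 TP + 1 FP, whichever order they arrive
  d2a <- rbind(det_row(1, 0, 0.9, c(0, 0, 10, 10)),
               det_row(1, 0, 0.8, c(1, 1, 10, 10)))
  d2b <- d2a[2:1, ]
  for (d in list(d2a, d2b)) {
    m2 <- match_detections(d, gts)
    expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))
    # the higher-scoring detection wins the gt
    expect_true(m2$flags$tp[1])
  }
  # no detections
  m0 <- match_detections(det_row(1, 0, 1, c(0, 0, 1, 1))[0, ], gts)
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0, 0, 1))
  # class and image identity are respected
  m3 <- match_detections(det_row(2, 0, 0.9, c(0, 0, 10, 10)), gts)
  expect_equal(m3$TP, 0)
  m4 <- match_detections(det_row(1, 1, 0.9, c(0, 0, 10, 10)), gts)
  expect_equal(m4$TP, 0)
  # conservation: TP + FN = gts, TP + FP = detections
  set.seed(1)
  for (i in 1:10) {
    rs <- random_detection_set(i)
    m5 <- match_detections(rs$dets, rs$gts)
    expect_equal(m5$TP + m5$FN, nrow(rs$gts))
    expect_equal(m5$TP + m5$FP, nrow(rs$dets))
  }
})

test_that("F1 reproduces the published precision/recall pairings", {
  # Comparison-table rows, percentages to one decimal
  rows <- list(c(91.5, 89.2, 90.3), c(84.2, 81.0, 82.6),
               c(85.7, 82.3, 84.0), c(88.4, 85.1, 86.7),
               c(88.7, 86.0, 87.3), c(90.2, 87.5, 88.8))
  for (r in rows) {
    f1 <- 2 * r[1] * r[2] / (r[1] + r[2])
    expect_equal(round(f1, 1), r[3])
  }
  # harmonic-mean fixed point and zero conventions
  prf <- precision_recall_f1(8, 2, 2)
  expect_equal(unname(prf), c(0.8, 0.8, 0.8))
  expect_equal(unname(precision_recall_f1(0, 0, 5)), c(0, 0, 0))
  expect_error(precision_recall_f1(-1, 0, 0))
})

test_that("average precision follows the interpolated PR-curve definition", {
  expect_equal(average_precision(TRUE, 1), 1)
  # envelope: a leading TP then an FP still gives AP 1 for a single gt
  expect_equal(average_precision(c(TRUE, FALSE), 1), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 3), 0)
  expect_equal(average_precision(logical(0), 2), 0)
  # two gts, flags TP FP TP: precision at recall 0.5 is 1, at 1 is 2/3
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # AP depends only on order, hence invariant to monotone score rescaling
  # (flags already encode order; property exercised via evaluate_detections)
  set.seed(2)
  rs <- random_detection_set(42)
  r1 <- evaluate_detections(rs$dets, rs$gts)
  ds <- rs$dets; ds$score <- ds$score^3  # strictly monotone rescale
  r2 <- evaluate_detections(ds, rs$gts)
  expect_equal(r1$ap, r2$ap, tolerance = 1e-12)
  # adding a lowest-score FP never increases AP
  worse <- dplyr::bind_rows(rs$dets, det_row(1, 0, 1e-6, c(90, 90, 95, 95)))
  r3 <- evaluate_detections(worse, rs$gts)
  expect_true(all(r3$ap <= r1$ap + 1e-12))
  # 11-point variant stays within [0, 1] and close to all-point
  ap_all <- average_precision(c(TRUE, FALSE, TRUE), 2, "all")
  ap_11 <- average_precision(c(TRUE, FALSE, TRUE), 2, "11point")
  expect_lte(abs(ap_all - ap_11), 0.1)
})

test_that("mAP averages evaluable classes and matches the independent oracle", {
  expect_equal(map50(c(a = 1, b = 0.5)), 0.75)
  expect_error(map50(numeric(0)), "no evaluable")
  # zero-gt classes are excluded, not scored 0
  dets <- dplyr::bind_rows(det_row(1, 0, 0.9, c(0, 0, 10, 10)),
                           det_row(1, 3, 0.8, c(20, 20, 30, 30)))
  gts <- gt_row(1, 0, c(0, 0, 10, 10))
  r <- evaluate_detections(dets, gts)
  expect_equal(names(r$ap), "0")
  expect_equal(r$map50, 1)
  # independent nested-loop re-implementation agrees on random toy sets
  for (seed in 1:30) {
    rs <- random_detection_set(seed)
    r1 <- evaluate_detections(rs$dets, rs$gts)
    expect_equal(r1$map50, oracle_map50(rs$dets, rs$gts), tolerance = 1e-9)
  }
})

test_that("group mapping, tidiers and the text table work", {
  dets <- dplyr::bind_rows(det_row(1, 2, 0.9, c(0, 0, 10, 10)),
                           det_row(1, 6, 0.8, c(20, 20, 31, 31)))
  gts <- dplyr::bind_rows(gt_row(1, 2, c(0, 0, 10, 10)),
                          gt_row(1, 6, c(20, 20, 30, 30)))
  fine <- evaluate_detections(dets, gts)
  grp <- evaluate_detections(dets, gts, group_map = TRUE)
  expect_equal(sort(names(grp$ap)), c("0", "1"))
  expect_equal(grp$map50, 1)
  td <- tidy(fine)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(fine)
  expect_equal(gl$TP, 2)
  expect_equal(gl$f1, 1)
  lines <- metrics_table(list(ours = fine))
  expect_length(lines, 2)
  expect_match(lines[2], "100.0%")
  p <- autoplot(fine)
  expect_s3_class(p, "ggplot")
})
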