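# Set-prediction head: Hungarian matching, losses, geometry and the
# transformer contracts.

test_that("Hungarian assignment solves small canonical cases", {
  # diagonal-zero cost: identity assignment
  a <- hungarian_assign(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  expect_equal(a$query, 1:3)
  expect_equal(a$target, 1:3)
  # 1x1
  a1 <- hungarian_assign(matrix(5, 1, 1))
  expect_equal(nrow(a1), 1)
  # empty target set
  a0 <- hungarian_assign(matrix(numeric(0), nrow = 3, ncol = 0))
  expect_equal(nrow(a0), 0)
  expect_error(hungarian_assign(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("Hungarian equals the brute-force permutation minimum", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:5, 1); m <- sample(n:7, 1)
    cost <- matrix(runif(n * m), n, m)
    res <- hungarian_assign(t(cost))  # queries = m rows, targets = n cols
    tot <- sum(t(cost)[cbind(res$query, res$target)])
    expect_equal(tot, brute_force_assignment(cost)$cost, tolerance = 1e-9)
    expect_equal(nrow(res), min(n, m))
    expect_false(any(duplicated(res$query)))
    expect_false(any(duplicated(res$target)))
  }
})

test_that("class weights follow capped inverse frequency", {
  expect_equal(class_weights(rep(10, 6)), rep(1, 6))
  expect_equal(class_weights(c(3, 1)), c(4 / 6, 2), tolerance = 1e-12)
  # scale invariance
  expect_equal(class_weights(c(30, 10)), class_weights(c(3, 1)))
  # zero-count classes get the max finite weight; cap at 10x median
  w <- class_weights(c(100, 1, 0))
  expect_equal(w[3], w[2])
  expect_true(all(w <= 10 * median(w) + 1e-12))
  expect_error(class_weights(c(0, 0)), "zero")
})

test_that("weighted cross-entropy matches hand evaluation", {
  expect_equal(weighted_ce(c(1, 0), 1, c(1, 1)), 0)
  expect_equal(weighted_ce(c(0.5, 0.5), 1, c(2, 1)), -2 * log(0.5),
               tolerance = 1e-12)
  # omega == 1 reduces to the standard cross-entropy
  set.seed(2)
  p <- runif(5); p <- p / sum(p)
  expect_equal(weighted_ce(p, 3, rep(1, 5)), -log(p[3]), tolerance = 1e-12)
  expect_warning(weighted_ce(c(0, 1), 1, c(1, 1)), "clamped")
})

test_that("GIoU matches hand geometry and the rasterization oracle", {
  expect_equal(giou_box(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  # corner case: IoU = 1/7, hull 9, union 7 -> GIoU = 1/7 - 2/9
  g <- giou_box(c(0, 0, 2, 2), c(1, 1, 3, 3))
  expect_equal(g, 1 / 7 - 2 / 9, tolerance = 1e-12)
  expect_lt(abs(g - (-0.0794)), 1e-4)
  # monotone approach to -1 under separation
  gs <- vapply(c(5, 20, 100, 1000), function(d) {
    giou_box(c(0, 0, 1, 1), c(d, 0, d + 1, 1))
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
  expect_lt(gs[4], -0.99)
  # rasterization oracle on integer-corner boxes
  set.seed(3)
  for (i in 1:60) {
    a <- c(sort(sample(0:9, 2)), 0, 0); a[3:4] <- sort(sample(0:9, 2))
    a <- c(a[1], a[3], a[2], a[4])
    b <- c(sort(sample(0:9, 2)), sort(sample(0:9, 2)))[c(1, 3, 2, 4)]
    if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) next
    ref <- raster_iou_giou(a, b, scale = 20L)
    expect_lt(abs(box_iou(a, b) - ref$iou), 2 / 20)
    expect_lt(abs(box_iou(a, b) - ref$iou), 1e-9)  # aligned grid is exact
    expect_lt(abs(giou_box(a, b) - ref$giou), 1e-9)
  }
})

test_that("contrastive loss separates groups and is rotation invariant", {
  set.seed(4)
  # identical same-group embeddings: analytic minimum is log(M - 1)
  M <- 5
  emb <- matrix(rep(rnorm(4), each = M), M, 4)
  l_id <- ag_val(contrastive_loss(emb, rep("pest", M), tau = 0.1))
  expect_equal(l_id, log(M - 1), tolerance = 1e-9)
  # orthogonal clusters by group beat shuffled labels
  e2 <- rbind(matrix(rep(c(1, 0, 0, 0), 3), 3, 4, byrow = TRUE),
              matrix(rep(c(0, 1, 0, 0), 3), 3, 4, byrow = TRUE)) +
    rand_mat(6, 4, sd = 0.01)
  grp <- rep(c("pest", "predator"), each = 3)
  l_good <- ag_val(contrastive_loss(e2, grp, tau = 0.1))
  l_bad <- ag_val(contrastive_loss(e2, grp[c(1, 4, 2, 5, 3, 6)], tau = 0.1))
  expect_lt(l_good, l_bad)
  expect_gte(l_good, 0)
  # invariance under a global rotation
  th <- 0.7
  R <- diag(4); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(ag_val(contrastive_loss(e2 %*% R, grp, tau = 0.1)), l_good,
               tolerance = 1e-9)
  # single embedding contributes nothing
  expect_equal(ag_val(contrastive_loss(matrix(rnorm(4), 1), "pest")), 0)
})

test_that("transformer encoder layer matches a brute-force attention loop", {
  set.seed(5)
  d <- 4L
  at <- mha_new(d, 1L)
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    x <- rand_mat(n, d)
    out <- ag_val(mha_apply(at, x, x))
    # brute force with the layer's own projection weights
    lin <- function(l, z) sweep(z %*% l$W$value, 2, -l$b$value, "-")
    Q <- lin(at$Wq, x); K <- lin(at$Wk, x); V <- lin(at$Wv, x)
    ref <- matrix(0, n, d)
    for (i in seq_len(n)) {
      s <- sapply(seq_len(n), function(j) sum(Q[i, ] * K[j, ]) / sqrt(d))
      a <- exp(s - max(s)); a <- a / sum(a)
      for (j in seq_len(n)) ref[i, ] <- ref[i, ] + a[j] * V[j, ]
    }
    ref <- lin(at$Wo, ref)
    expect_equal(out, ref, tolerance = 1e-6)
  }
  # full encoder: token count preserved, joint permutation equivariance
  set.seed(6)
  cfg <- tiny_cfg()
  head <- head_new(cfg)
  fm <- feature_map(rand_mat(16 * 16, 8, seed = 7), 16, 16, "fused")
  ag_no_grad({
    mem <- transformer_encode(head, fm)
    expect_equal(dim(ag_val(mem)), c(256L, 64L))
  })
})

test_that("prediction outputs satisfy their range contracts", {
  set.seed(8)
  cfg <- tiny_cfg()
  head <- head_new(cfg)
  ag_no_grad({
    emb <- rand_mat(12, 64, seed = 9)
    det <- head_predict(head, emb, "pest")
    bx <- ag_val(det$boxes); pr <- ag_val(det$class_probs)
    expect_true(all(bx >= 0 & bx <= 1))
    expect_equal(dim(pr), c(12L, 9L))
    expect_equal(rowSums(pr), rep(1, 12), tolerance = 1e-6)
    # identical embeddings give identical predictions
    det2 <- head_predict(head, emb, "pest")
    expect_identical(ag_val(det2$boxes), bx)
    # decoder shape contract and branch independence
    mem <- rand_mat(256, 64, seed = 10)
    ep <- ag_val(transformer_decode(head, mem, "pest"))
    expect_equal(dim(ep), c(12L, 64L))
    expect_error(transformer_decode(head, mem, "bees"), "unknown branch")
  })
})

test_that("match cost combines its three terms as specified", {
  lw <- list(lambda_cls = 1, lambda_bbox = 5, lambda_giou = 2)
  # perfect prediction: zero cost
  probs <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 1, 9)
  gtb <- matrix(c(0.5, 0.5, 0.2, 0.2), 1, 4)
  cost <- match_cost(probs, gtb, gtb, 0L, lw)
  expect_equal(cost[1, 1], 0, tolerance = 1e-12)
  # monotone in L1 distance, other terms fixed
  b1 <- matrix(c(0.52, 0.5, 0.2, 0.2), 1, 4)
  b2 <- matrix(c(0.58, 0.5, 0.2, 0.2), 1, 4)
  expect_lt(match_cost(probs, b1, gtb, 0L, lw)[1, 1],
            match_cost(probs, b2, gtb, 0L, lw)[1, 1])
  # 2x2 hand case, term by term
  p2 <- rbind(c(0.7, 0.2, rep(0.1 / 7, 7)), c(0.1, 0.8, rep(0.1 / 7, 7)))
  bx <- rbind(c(0.3, 0.3, 0.2, 0.2), c(0.7, 0.7, 0.2, 0.2))
  gt <- rbind(c(0.32, 0.3, 0.2, 0.2), c(0.7, 0.68, 0.2, 0.2))
  cost <- match_cost(p2, bx, gt, c(0L, 1L), lw)
  for (q in 1:2) for (t in 1:2) {
    l1 <- sum(abs(bx[q, ] - gt[t, ]))
    gi <- giou_box(cxcywh_to_corners(bx[q, , drop = FALSE], 1)[1, ],
                   cxcywh_to_corners(gt[t, , drop = FALSE], 1)[1, ])
    expect_equal(cost[q, t],
                 1 * (1 - p2[q, t]) + 5 * l1 + 2 * (1 - gi),
                 tolerance = 1e-12)
  }
})

test_that("detection loss is permutation invariant and linear in its weights", {
  set.seed(11)
  cfg <- tiny_cfg()
  head <- head_new(cfg)
  omega <- c(rep(1, 8), 0.1)
  lw <- cfg$loss
  emb <- rand_mat(12, 64, seed = 12)
  gtb <- rbind(c(0.3, 0.3, 0.25, 0.25), c(0.7, 0.6, 0.3, 0.3))
  gtl <- c(2L, 5L)
  ag_no_grad({
    det <- head_predict(head, emb, "pest")
    l1 <- detection_loss(det, gtb, gtl, omega, lw)
    l2 <- detection_loss(det, gtb[2:1, ], gtl[2:1], omega, lw)
    tot <- function(l, lw) {
      lw$lambda_cls * ag_val(l$L_cls) + lw$lambda_bbox * ag_val(l$L_bbox) +
        lw$lambda_giou * ag_val(l$L_giou)
    }
    expect_equal(tot(l1, lw), tot(l2, lw), tolerance = 1e-9)
    # doubling lambda_bbox doubles its contribution on a fixed batch; use
    # ground truth equal to two predicted boxes so the assignment cannot flip
    pv <- ag_val(det$boxes)
    gtb0 <- pv[c(3, 7), , drop = FALSE]
    gtl0 <- max.col(ag_val(det$class_probs)[c(3, 7), 1:8]) - 1L
    lw2 <- lw; lw2$lambda_bbox <- 2 * lw$lambda_bbox
    la <- detection_loss(det, gtb0, gtl0, omega, lw)
    lb <- detection_loss(det, gtb0, gtl0, omega, lw2)
    expect_equal(la$assignment, lb$assignment)
    expect_equal(lw2$lambda_bbox * ag_val(lb$L_bbox),
                 2 * lw$lambda_bbox * ag_val(la$L_bbox), tolerance = 1e-9)
    # empty ground truth: box losses vanish, classification remains
    l0 <- detection_loss(det, matrix(numeric(0), 0, 4), integer(0), omega, lw)
    expect_equal(ag_val(l0$L_bbox), 0)
    expect_equal(ag_val(l0$L_giou), 0)
    expect_gt(ag_val(l0$L_cls), 0)
  })
})

test_that("pest-branch loss has zero gradient on predator-head parameters", {
  set.seed(13)
  cfg <- tiny_cfg()
  model <- pf_model_new(cfg)
  scenes <- tiny_scenes(1, seed = 2)
  # force a pest-only scene (class 0-5 guaranteed by default distribution draw)
  smp <- tiny_samples(scenes)
  omega <- c(rep(1, 8), 0.1)
  ag_tape_reset()
  fw <- model_forward(model, smp[[1]])
  tg <- pestfuse:::scene_targets(scenes[[1]], TRUE)
  dl <- detection_loss(fw$dets$pest, tg$pest$boxes, tg$pest$labels, omega,
                       cfg$loss)
  loss <- ag_add(ag_add(dl$L_cls, dl$L_bbox), dl$L_giou)
  ag_backward(loss)
  pred_params <- collect_params(model$head$branches$predator)
  grads <- vapply(pred_params, function(p) {
    if (is.null(p$grad)) 0 else max(abs(p$grad))
  }, numeric(1))
  expect_true(all(grads == 0))
  pest_params <- collect_params(model$head$branches$pest)
  pg <- vapply(pest_params, function(p) {
    if (is.null(p$grad)) 0 else max(abs(p$grad))
  }, numeric(1))
  expect_gt(max(pg), 0)
})
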