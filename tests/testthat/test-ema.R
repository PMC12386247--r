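# Environment-guided modality attention: SS1D recurrence, gate construction
# and the gated fusion equation.

test_that("SS1D matches the hand-unrolled scalar recurrence", {
  # A = 0.5, B = C = 1, x = (1, 0, 0): h = y = (1, 0.5, 0.25)
  y <- ag_val(ss1d_scan(matrix(c(1, 0, 0), 3, 1), 0.5,
                        matrix(1), matrix(1), raw = FALSE))
  expect_equal(as.vector(y), c(1, 0.5, 0.25), tolerance = 1e-12)
  # A = 0 is memoryless: y_t = C B x_t
  x <- matrix(c(2, -1, 3), 3, 1)
  y0 <- ag_val(ss1d_scan(x, 0, matrix(1.5), matrix(2), raw = FALSE))
  expect_equal(as.vector(y0), 3 * as.vector(x), tolerance = 1e-12)
  # zero input gives zero output (h_0 = 0, linear recurrence)
  yz <- ag_val(ss1d_scan(matrix(0, 4, 2), c(0.3, 0.8),
                         rand_mat(2, 2, seed = 1), rand_mat(2, 3, seed = 2),
                         raw = FALSE))
  expect_true(all(yz == 0))
  expect_error(ss1d_scan(matrix(numeric(0), 0, 1), 0.5, matrix(1), matrix(1)),
               "empty")
})

test_that("SS1D equals its closed-form convolution on short sequences", {
  # y_t = sum_{k <= t} C A^{t-k} B x_k, brute-forced for lengths <= 6
  set.seed(3)
  for (trial in 1:100) {
    Tn <- sample(1:6, 1)
    d_in <- sample(1:3, 1); d_st <- sample(1:3, 1); d_out <- sample(1:3, 1)
    a <- runif(d_st, 0.05, 0.95)
    B <- rand_mat(d_in, d_st)
    C_out <- rand_mat(d_st, d_out)
    x <- rand_mat(Tn, d_in)
    y <- ag_val(ss1d_scan(x, a, B, C_out, raw = FALSE))
    A <- diag(a, d_st)
    ref <- matrix(0, Tn, d_out)
    for (t in seq_len(Tn)) {
      for (k in seq_len(t)) {
        Apow <- diag(d_st)
        if (t - k > 0) for (j in seq_len(t - k)) Apow <- Apow %*% A
        ref[t, ] <- ref[t, ] + x[k, , drop = FALSE] %*% B %*% Apow %*% C_out
      }
    }
    expect_equal(y, ref, tolerance = 1e-9)
  }
})

test_that("gate construction yields an open-unit-interval tensor of declared shape", {
  set.seed(4)
  cfg <- tiny_cfg()
  ema <- ema_new(cfg)
  ag_no_grad({
    gb <- build_gate(ema, matrix(runif(8 * 3), 8, 3))
    expect_equal(dim(gb$g), c(16L * 16L, 8L))
    expect_true(all(gb$g > 0 & gb$g < 1))
    # distinct environments produce distinct gates for generic weights
    g2 <- build_gate(ema, matrix(runif(8 * 3), 8, 3))$g
    expect_gt(max(abs(gb$g - g2)), 0)
    # single-vector history degenerates gracefully
    g1 <- build_gate(ema, c(0.5, 0.5, 0.5))$g
    expect_equal(dim(g1), c(256L, 8L))
  })
  expect_error(ag_no_grad(build_gate(ema, c(1, 2))), "ncol")
})

test_that("gate gradients reach the environment encoder weights", {
  set.seed(5)
  cfg <- tiny_cfg()
  cfg$ema$depth <- 2L
  ema <- ema_new(cfg)
  hist <- matrix(runif(4 * 3), 4, 3)
  W <- ema$env_enc$lin$W
  w0 <- as.vector(W$value)[1:6]
  loss_of <- function(v) {
    old <- W$value
    W$value[seq_along(v)] <- v
    out <- ag_no_grad({ ag_tape_reset(); ag_val(ag_sum(build_gate(ema, hist)$g)) })
    W$value <- old
    out
  }
  ag_tape_reset()
  loss <- ag_sum(build_gate(ema, hist)$g)
  ag_backward(loss)
  g_an <- as.vector(W$grad)[1:6]
  g_num <- ag_numgrad(loss_of, w0)
  expect_lt(max(abs(g_an - g_num)), 1e-5)
})

test_that("gated fusion evaluates the mixing equation exactly", {
  F_rgb <- rand_mat(12, 4, seed = 6)
  F_ir <- rand_mat(12, 4, seed = 7)
  # g == 1 limits
  expect_equal(ag_val(fuse_gate(F_rgb, F_ir, 1, 1)), F_rgb, tolerance = 1e-15)
  expect_equal(ag_val(fuse_gate(F_rgb, F_ir, 1, 0)), F_ir, tolerance = 1e-15)
  # hand case: g = 0.5, alpha = 0.5, F_RGB = 2, F_IR = 4 -> 1.5 everywhere
  out <- ag_val(fuse_gate(matrix(2, 3, 3), matrix(4, 3, 3),
                          matrix(0.5, 3, 3), 0.5))
  expect_true(all(abs(out - 1.5) < 1e-15))
  # convex-combination bounds for g == 1
  for (i in 1:20) {
    a <- runif(1)
    fo <- ag_val(fuse_gate(F_rgb, F_ir, 1, a))
    expect_true(all(fo >= pmin(F_rgb, F_ir) - 1e-12))
    expect_true(all(fo <= pmax(F_rgb, F_ir) + 1e-12))
  }
  # 0 < g < 1 only attenuates
  g <- matrix(runif(48), 12, 4)
  fo <- ag_val(fuse_gate(F_rgb, F_ir, g, 0.3))
  mix <- 0.3 * F_rgb + 0.7 * F_ir
  expect_true(all(abs(fo) <= abs(mix) + 1e-12))
  expect_error(fuse_gate(F_rgb, F_ir, 1, 1.2))
})

test_that("alpha remains in [0,1] under arbitrary gradient steps", {
  set.seed(8)
  cfg <- tiny_cfg()
  ema <- ema_new(cfg)
  # sigmoid parameterization: any raw value keeps alpha inside the interval
  for (v in c(-1e6, -3, 0, 3, 1e6)) {
    ema$alpha_raw$value <- v
    a <- ag_val(ag_sigmoid(ema$alpha_raw))
    expect_gte(a, 0)
    expect_lte(a, 1)
  }
})
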