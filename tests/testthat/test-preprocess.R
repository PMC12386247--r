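# Preprocessing: occlusion, brightness perturbation, temporal interpolation,
# min-max normalization and sample assembly.

test_that("occlusion zeroes exactly the region and is idempotent", {
  img <- matrix(1, 64, 64)
  out <- apply_occlusion(img, occlusion_region(5, 11, 10, 10))
  expect_equal(sum(out == 0), 100)
  expect_equal(sum(out), 64 * 64 - 100)
  # idempotent
  expect_identical(apply_occlusion(out, occlusion_region(5, 11, 10, 10)), out)
  # total mask
  expect_true(all(apply_occlusion(img, occlusion_region(1, 1, 64, 64)) == 0))
  # fully outside is an error, not a no-op
  expect_error(apply_occlusion(img, occlusion_region(100, 100, 5, 5)),
               "outside")
  # multi-channel arrays behave identically
  arr <- array(1, c(32, 32, 3))
  out3 <- apply_occlusion(arr, occlusion_region(1, 1, 4, 4))
  expect_equal(sum(out3 == 0), 4 * 4 * 3)
})

test_that("brightness perturbation is unbiased, clipped and deterministic", {
  img <- array(0.5, c(100, 100, 3))  # far from clip boundaries
  expect_identical(perturb_brightness(img, 0), img)
  a <- perturb_brightness(img, 0.1, seed = 2)
  b <- perturb_brightness(img, 0.1, seed = 2)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # law of large numbers: sample mean of the added noise ~ N(0, sigma^2/n)
  n <- 1e6
  img_big <- array(0.5, c(1000, 1000))
  d <- perturb_brightness(img_big, 0.1, seed = 7) - img_big
  expect_lt(abs(mean(d)), 3 * 0.1 / sqrt(n))
  expect_error(perturb_brightness(img, -0.1), "nonnegative")
})

test_that("sensor interpolation is exact on affine signals and refuses extrapolation", {
  expect_equal(interpolate_sensor(c(0, 2), c(10, 20), 1), 15)
  expect_equal(interpolate_sensor(c(0, 2, 5), c(10, 20, 50), 0), 10)   # left endpoint
  # linearity closure: s(t) = 2t + 1 sampled at integers
  t <- 0:10
  s <- 2 * t + 1
  for (tp in c(0, 0.25, 3.7, 9.999)) {
    expect_equal(interpolate_sensor(t, s, tp), 2 * tp + 1, tolerance = 1e-12)
  }
  # dense-resampling oracle: value within bracketing endpoints of a monotone segment
  set.seed(4)
  tt <- cumsum(runif(20, 0.5, 2))
  vv <- cumsum(runif(20))
  for (tp in runif(50, tt[1], tt[20] - 1e-9)) {
    v <- interpolate_sensor(tt, vv, tp)
    k <- findInterval(tp, tt)
    expect_gte(v, vv[k] - 1e-12)
    expect_lte(v, vv[k + 1] + 1e-12)
  }
  expect_error(interpolate_sensor(c(0, 2), c(1, 2), 2), "extrapolate")
  expect_error(interpolate_sensor(c(0, 2), c(1, 2), -0.1), "extrapolate")
})

test_that("min-max normalization maps extrema to {0,1} and inverts exactly", {
  st <- c(10, 30)
  expect_equal(normalize_minmax(10, st), 0)
  expect_equal(normalize_minmax(30, st), 1)
  expect_equal(normalize_minmax(20, st), 0.5)
  expect_equal(normalize_minmax(95, st), 1)   # clipped
  expect_equal(normalize_minmax(-5, st), 0)
  for (s in runif(20, 10, 30)) {
    expect_equal(denormalize_minmax(normalize_minmax(s, st), st), s,
                 tolerance = 1e-12)
  }
  expect_error(normalize_minmax(1, c(5, 5)), "degenerate")
  expect_error(norm_stats(tibble::tibble(temperature = c(1, 1),
                                         humidity = c(0, 1),
                                         light = c(0, 1))), "degenerate")
})

test_that("sample assembly composes interpolation and normalization", {
  env <- generate_env_series(20, "noon", "sunny", seed = 1, t0 = 990)
  stats <- norm_stats(env)
  rgb <- array(0.5, c(8, 8, 3)); th <- matrix(0.5, 8, 8)
  smp <- assemble_sample(rgb, th, env, 1000.4, stats, history = 4L)
  expect_equal(dim(smp$env_history), c(4, 3))
  expect_true(all(smp$env_history >= 0 & smp$env_history <= 1))
  # compositional oracle: each channel equals normalize(interpolate(.))
  for (ch in c("temperature", "humidity", "light")) {
    expect_equal(unname(smp$env_norm[ch]),
                 normalize_minmax(
                   interpolate_sensor(env$timestamp, env[[ch]], 1000.4),
                   stats[[ch]]),
                 tolerance = 1e-12)
  }
  # frame exactly on a sensor timestamp introduces no error
  smp2 <- assemble_sample(rgb, th, env, 1000, stats, history = 2L)
  k <- which(env$timestamp == 1000)
  expect_equal(unname(smp2$env_norm["temperature"]),
               normalize_minmax(env$temperature[k], stats$temperature),
               tolerance = 1e-12)
  expect_identical(smp$rgb, rgb)
})
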