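# Preprocessing: occlusion simulation, brightness perturbation, sensor-to-frame
# temporal interpolation, min-max normalization, and assembly of one aligned
# multimodal sample.

#' Rectangular occlusion region
#'
#' @param x,y Top-left pixel (1-based).
#' @param w,h Extent in pixels (>= 1).
#' @return A `pf_region` list.
#' @export
occlusion_region <- function(x, y, w, h) {
  stopifnot(w >= 1, h >= 1)
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "pf_region")
}

#' Sample a random occlusion region for augmentation
#'
#' Area uniform in 2-20 % of the frame, aspect ratio in `[0.3, 3]`.
#' @param H,W Image extent.
#' @return A [occlusion_region()].
#' @export
sample_occlusion_region <- function(H, W) {
  area <- stats::runif(1, 0.02, 0.20) * H * W
  aspect <- stats::runif(1, 0.3, 3)
  w <- max(1L, min(W, round(sqrt(area * aspect))))
  h <- max(1L, min(H, round(sqrt(area / aspect))))
  occlusion_region(sample.int(W - w + 1L, 1L), sample.int(H - h + 1L, 1L), w, h)
}

#' Zero out a rectangular region of an image
#'
#' Pixels inside the region are set exactly to 0; everything else is
#' untouched. A region that does not intersect the image domain is an error,
#' not a no-op.
#' @param image `H x W` matrix or `H x W x C` array.
#' @param region A [occlusion_region()].
#' @return Image of the same shape.
#' @export
apply_occlusion <- function(image, region) {
  stopifnot(inherits(region, "pf_region"), length(image) > 0)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  y1 <- max(1L, region$y); y2 <- min(H, region$y + region$h - 1L)
  x1 <- max(1L, region$x); x2 <- min(W, region$x + region$w - 1L)
  if (y1 > y2 || x1 > x2) {
    stop("occlusion region lies entirely outside the image domain")
  }
  if (length(d) == 2L) {
    image[y1:y2, x1:x2] <- 0
  } else {
    image[y1:y2, x1:x2, ] <- 0
  }
  image
}

#' Add zero-mean Gaussian brightness noise
#'
#' `I'' = I + N(0, sigma^2)`, clipped afterwards to `[0, 1]` (images are stored
#' on normalized intensities, and downstream encoders assume bounded input).
#' `sigma = 0` is an exact identity.
#' @param image Numeric array in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0). Default 0.05 on unit-range
#'   intensities.
#' @param seed RNG seed for deterministic augmentation.
#' @return Perturbed image, same shape.
#' @export
perturb_brightness <- function(image, sigma = 0.05, seed = 0L) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(image)
  set.seed(seed)
  out <- image + stats::rnorm(length(image), sd = sigma)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Linearly interpolate a sensor series at a frame timestamp
#'
#' Evaluates `s_hat = s_k + (s_{k+1} - s_k) / (t_{k+1} - t_k) * (t' - t_k)` on
#' the bracketing pair `t_k <= t' < t_{k+1}`. Extrapolation is forbidden: `t'`
#' outside `[t_1, t_n)` is an error (the generator guarantees bracketing).
#' @param times Strictly increasing sample times (seconds).
#' @param values Sensor readings at `times`.
#' @param t_prime Target timestamp(s).
#' @return Interpolated value(s).
#' @export
#' @examples
#' interpolate_sensor(c(0, 2), c(10, 20), 1) # 15
interpolate_sensor <- function(times, values, t_prime) {
  stopifnot(length(times) >= 2L, length(times) == length(values),
            all(diff(times) > 0), all(is.finite(values)))
  if (any(t_prime < times[1] | t_prime >= times[length(times)])) {
    stop("t_prime outside [t_first, t_last): refusing to extrapolate")
  }
  k <- findInterval(t_prime, times)
  values[k] + (values[k + 1L] - values[k]) / (times[k + 1L] - times[k]) *
    (t_prime - times[k])
}

#' Training-set min-max normalization statistics
#'
#' @param env Tibble with `temperature`, `humidity`, `light` columns pooled
#'   over the training split.
#' @return A `pf_norm_stats` list of `c(min, max)` per channel.
#' @export
norm_stats <- function(env) {
  chans <- c("temperature", "humidity", "light")
  stopifnot(all(chans %in% names(env)))
  st <- lapply(chans, function(ch) range(env[[ch]]))
  names(st) <- chans
  for (ch in chans) {
    if (st[[ch]][2] <= st[[ch]][1]) {
      stop(sprintf("degenerate channel '%s': max equals min in the training set", ch))
    }
  }
  structure(st, class = "pf_norm_stats")
}

#' Min-max normalize / denormalize a sensor value
#'
#' `(s - s_min) / (s_max - s_min)`; values beyond the training extrema are
#' clipped into `[0, 1]`. `denormalize_minmax()` inverts the map for in-range
#' values.
#' @param value Numeric value(s).
#' @param stats Length-2 `c(min, max)` vector (one channel of
#'   [norm_stats()]).
#' @return Normalized value(s) in `[0, 1]` (or raw units for denormalize).
#' @export
normalize_minmax <- function(value, stats) {
  s_min <- stats[1]; s_max <- stats[2]
  if (s_max <= s_min) stop("degenerate channel: s_max must exceed s_min")
  pmin(pmax((value - s_min) / (s_max - s_min), 0), 1)
}

#' @rdname normalize_minmax
#' @export
denormalize_minmax <- function(value, stats) {
  stats[1] + value * (stats[2] - stats[1])
}

#' Assemble one temporally aligned multimodal sample
#'
#' Interpolates the three sensor channels at the frame timestamp (and at 1 Hz
#' steps before it for the environment history consumed by the state-space
#' gate), then min-max normalizes with training-set statistics. Images pass
#' through untouched.
#'
#' @param rgb,thermal Image arrays in `[0, 1]`.
#' @param env Tibble `timestamp`, `temperature`, `humidity`, `light`.
#' @param t_frame Frame timestamp (seconds); must be bracketed by `env`.
#' @param stats A [norm_stats()].
#' @param history Number of 1 Hz steps of environment history (>= 1).
#' @return A `pf_sample` list: `rgb`, `thermal`, `env_norm` (named length-3
#'   vector in `[0,1]`), `env_history` (`history x 3` matrix, oldest first),
#'   `t_frame`.
#' @export
assemble_sample <- function(rgb, thermal, env, t_frame, stats, history = 8L) {
  stopifnot(inherits(stats, "pf_norm_stats"), history >= 1L)
  chans <- c("temperature", "humidity", "light")
  hist_t <- t_frame - rev(seq_len(history) - 1L)
  hist_t <- pmax(hist_t, env$timestamp[1])  # clamp history start into coverage
  hmat <- vapply(chans, function(ch) {
    normalize_minmax(interpolate_sensor(env$timestamp, env[[ch]], hist_t),
                     stats[[ch]])
  }, numeric(history))
  hmat <- matrix(hmat, nrow = history, ncol = 3,
                 dimnames = list(NULL, chans))
  structure(list(rgb = rgb, thermal = thermal,
                 env_norm = hmat[history, ],
                 env_history = hmat, t_frame = t_frame),
            class = "pf_sample")
}
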