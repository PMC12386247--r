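# Run configuration. All architectural constants default to the published
# model (64-channel 64x64 encoder maps, C' = 32 fusion channels, a 32x32x64
# modulation gate, d_model = 256 with 8 heads and 6+6 transformer layers, 100
# queries per branch); the "tiny" preset shrinks every dimension so a full
# train/eval round trip runs in minutes on one CPU core.

#' Build a run configuration
#'
#' @param preset `"paper"` for published dimensions, `"tiny"` for the reduced
#'   test-scale model (16-channel 16x16 maps, d_model 64, 12 queries).
#' @param ... Named overrides replacing nested fields, e.g.
#'   `train = list(steps = 100)` merges into the `train` block.
#' @return A `pf_config` nested list.
#' @export
#' @examples
#' cfg <- pf_config("tiny")
#' cfg$head$d_model
pf_config <- function(preset = c("paper", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 0L,
    data = list(image_size = 256L, n_targets = 3L, n_train = 64L, n_val = 16L,
                min_box = 20L, max_overlap_iou = 0.3, env_history = 8L),
    encoder = list(channels = 64L, spatial = 64L, depth = 3L),
    cma = list(cprime = 32L, bins = 16L, tau = 1.0, grid = 8L,
               spatial_kernel = 7L, dilated_branch = TRUE),
    ema = list(depth = 3L, width = 64L, state = 16L, history = 8L,
               gate_h = 32L, gate_w = 32L, gate_c = 64L),
    head = list(d_model = 256L, heads = 8L, n_enc = 6L, n_dec = 6L,
                ffn = 1024L, n_queries = 100L, n_classes = 8L),
    loss = list(lambda_cls = 1, lambda_bbox = 5, lambda_giou = 2,
                mu_contrastive = 0.5, tau_c = 0.1, noobj_weight = 0.1),
    train = list(lr = 1e-4, weight_decay = 1e-4, clip = 1, batch_size = 4L,
                 steps = 500L, warmup = 20L, lr_schedule = "cosine",
                 lr_floor_frac = 0.05, sigma_brightness = 0.05,
                 augment = TRUE),
    flags = list(use_cma = TRUE, use_ema = TRUE, use_reweighting = TRUE,
                 decoupled_head = TRUE),
    modalities = c("rgb", "thermal", "sensor"),
    norm_stats = NULL
  )
  if (preset == "tiny") {
    cfg$data <- utils::modifyList(cfg$data, list(
      image_size = 64L, n_targets = 2L, n_train = 32L, n_val = 8L))
    cfg$encoder <- utils::modifyList(cfg$encoder, list(
      channels = 16L, spatial = 16L))
    cfg$cma <- utils::modifyList(cfg$cma, list(
      cprime = 8L, bins = 8L, grid = 4L))
    # at tiny scale the gate shares the feature geometry, so no adapter
    cfg$ema <- utils::modifyList(cfg$ema, list(
      state = 8L, gate_h = 16L, gate_w = 16L, gate_c = 8L))
    cfg$head <- utils::modifyList(cfg$head, list(
      d_model = 64L, heads = 2L, n_enc = 1L, n_dec = 2L,
      ffn = 128L, n_queries = 12L))
    cfg$train <- utils::modifyList(cfg$train, list(lr = 1e-3, batch_size = 4L,
                                                   augment = FALSE))
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if (!"rgb" %in% cfg$modalities) {
    stop("the RGB modality is always retained; modality subsets must include 'rgb'")
  }
  class(cfg) <- "pf_config"
  cfg
}

#' Write / read a configuration as YAML
#'
#' The YAML round trip is lossless (normalization statistics included), so a
#' training run's config file fully determines evaluation-time preprocessing.
#' @param cfg A `pf_config`.
#' @param path File path.
#' @return `read_config()` returns a `pf_config`; `write_config()` its path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$norm_stats)) x$norm_stats <- unclass(x$norm_stats)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pf_config(x$preset)
  for (nm in setdiff(names(x), "preset")) {
    if (is.list(x[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], x[[nm]])
    } else {
      cfg[[nm]] <- x[[nm]]
    }
  }
  if (!is.null(cfg$norm_stats)) {
    cfg$norm_stats <- structure(lapply(cfg$norm_stats, as.numeric),
                                class = "pf_norm_stats")
  }
  cfg$modalities <- as.character(cfg$modalities)
  class(cfg) <- "pf_config"
  cfg
}

#' Hash a configuration for run logs
#' @param cfg A `pf_config`.
#' @return A short character hash.
#' @keywords internal
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}
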