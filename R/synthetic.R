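# Synthetic multimodal scene generator.
#
# Emulates the statistical structure of a field acquisition rig: paired RGB and
# thermal frames (pre-registered, same size), sprite-like insect targets of six
# pest and two predator classes, per-scene 1 Hz environmental series bracketing
# the frame timestamp, and COCO-style annotations. Everything is deterministic
# given the scene seed, so scenes double as reproducible test fixtures.

#' Class inventory: six pests and two predators
#'
#' Class indices 0-5 are pests, 6 (lady beetle) and 7 (lacewing) are predators.
#' Pest species are generic (the class structure, not the taxonomy, is what the
#' detector consumes); each class carries a distinct sprite colour and ellipse
#' aspect so an 8-way classifier is learnable from the rendered scenes.
#'
#' @return A tibble with columns `class_id`, `name`, `group`, `r`, `g`, `b`,
#'   `aspect`.
#' @export
#' @examples
#' pf_classes()
pf_classes <- function() {
  tibble::tibble(
    class_id = 0:7,
    name = c("pest_aphid", "pest_planthopper", "pest_armyworm", "pest_whitefly",
             "pest_stinkbug", "pest_noctuid", "lady_beetle", "lacewing"),
    group = c(rep("pest", 6), rep("predator", 2)),
    # saturated, mutually distant sprite colours: channel differences survive
    # the evening/fog brightness and contrast compression linearly, keeping
    # the 8 classes spectrally separable under every condition
    r = c(0.85, 0.90, 0.15, 0.85, 0.15, 0.10, 0.95, 0.92),
    g = c(0.15, 0.85, 0.25, 0.15, 0.80, 0.08, 0.45, 0.95),
    b = c(0.12, 0.15, 0.85, 0.80, 0.85, 0.06, 0.08, 0.90),
    aspect = c(0.8, 1.4, 2.2, 1.0, 0.7, 1.2, 1.0, 1.8)
  )
}

#' Pest/predator group of a class index
#' @param class_id Integer vector of class indices 0-7.
#' @return Character vector, `"pest"` or `"predator"`.
#' @export
class_group <- function(class_id) {
  stopifnot(all(class_id %in% 0:7))
  ifelse(class_id <= 5, "pest", "predator")
}

#' Default class mixture
#'
#' Pests are common, predators rare, mirroring field prevalence.
#' @return Probability vector of length 8 summing to 1.
#' @export
default_class_distribution <- function() {
  c(rep(0.84 / 6, 6), rep(0.16 / 2, 2))
}

#' Specification of one synthetic scene
#'
#' @param image_size Side of the square frame in pixels (>= 64).
#' @param n_targets Number of insect targets to place (>= 0).
#' @param class_distribution Probability vector over the 8 classes.
#' @param time_of_day One of `"morning"`, `"noon"`, `"evening"`.
#' @param weather One of `"sunny"`, `"cloudy"`, `"foggy"`.
#' @param seed Integer RNG seed; identical specs render bit-identical scenes.
#' @param max_overlap_iou Maximum pairwise IoU allowed between placed boxes.
#' @param min_box,max_box_frac Target box side range: at least `min_box` px
#'   (annotation floor 20 px) and at most `max_box_frac * image_size`.
#' @return A `pf_scene_spec` list.
#' @export
#' @examples
#' spec <- scene_spec(n_targets = 3, seed = 7)
#' sc <- generate_scene(spec)
#' sc$boxes
scene_spec <- function(image_size = 256L, n_targets = 3L,
                       class_distribution = default_class_distribution(),
                       time_of_day = c("morning", "noon", "evening"),
                       weather = c("sunny", "cloudy", "foggy"),
                       seed = 0L, max_overlap_iou = 0.3,
                       min_box = 20L, max_box_frac = 0.35) {
  time_of_day <- match.arg(time_of_day)
  weather <- match.arg(weather)
  stopifnot(image_size >= 64L, n_targets >= 0L,
            length(class_distribution) == 8L,
            all(class_distribution >= 0),
            abs(sum(class_distribution) - 1) < 1e-9)
  structure(list(image_size = as.integer(image_size),
                 n_targets = as.integer(n_targets),
                 class_distribution = class_distribution,
                 time_of_day = time_of_day, weather = weather,
                 seed = as.integer(seed),
                 max_overlap_iou = max_overlap_iou,
                 min_box = as.integer(min_box), max_box_frac = max_box_frac),
            class = "pf_scene_spec")
}

# smooth low-frequency noise field via coarse grid + block upsampling
smooth_noise <- function(H, W, coarse = 8L, sd = 1) {
  g <- matrix(stats::rnorm(coarse * coarse, sd = sd), coarse, coarse)
  up <- g[rep(seq_len(coarse), each = ceiling(H / coarse))[seq_len(H)],
          rep(seq_len(coarse), each = ceiling(W / coarse))[seq_len(W)]]
  up
}

condition_light_level <- function(time_of_day, weather) {
  tod <- c(morning = 0.55, noon = 0.85, evening = 0.15)[[time_of_day]]
  wx <- c(sunny = 1.0, cloudy = 0.6, foggy = 0.35)[[weather]]
  tod * wx
}

#' Render one synthetic multimodal scene
#'
#' Targets are textured ellipses with class-specific colour and aspect on a
#' vegetated background; the thermal channel shows each target as a warm blob
#' on a cool background, so mean thermal intensity inside boxes always exceeds
#' the outside mean. The condition knobs modulate the RGB frame only (evening
#' darkens, fog halves contrast and adds haze); thermal contrast is preserved,
#' which is exactly the complementarity the fusion model exploits.
#'
#' @param spec A [scene_spec()].
#' @return A `pf_scene` list: `rgb` (`H x W x 3` array in `[0,1]`), `thermal`
#'   (`H x W` matrix in `[0,1]`), `boxes` (tibble `class_id`, `group`, `xmin`,
#'   `ymin`, `xmax`, `ymax` in pixels, corner convention), `timestamp`
#'   (seconds), `time_of_day`, `weather`, `image_size`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "pf_scene_spec"))
  set.seed(spec$seed)
  S <- spec$image_size
  cls <- pf_classes()

  # --- target placement with overlap control -----------------------------
  max_box <- max(spec$min_box + 2L, floor(spec$max_box_frac * S))
  boxes <- matrix(numeric(0), ncol = 4)
  labels <- integer(0)
  for (i in seq_len(spec$n_targets)) {
    placed <- FALSE
    for (try in seq_len(250L)) {
      ci <- sample.int(8L, 1L, prob = spec$class_distribution) - 1L
      w0 <- stats::runif(1, spec$min_box, max_box)
      h0 <- min(max(w0 / cls$aspect[ci + 1L], spec$min_box), max_box)
      x0 <- stats::runif(1, 0, S - w0)
      y0 <- stats::runif(1, 0, S - h0)
      cand <- c(x0, y0, x0 + w0, y0 + h0)
      ok <- TRUE
      if (nrow(boxes) > 0) {
        ious <- box_iou_one_many(cand, boxes)
        ok <- all(ious <= spec$max_overlap_iou)
      }
      if (ok) {
        boxes <- rbind(boxes, cand)
        labels <- c(labels, ci)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(structure(class = c("pf_capacity_error", "error", "condition"),
                     list(message = sprintf(
                       "cannot place %d non-overlapping targets >= %d px in a %d px frame",
                       spec$n_targets, spec$min_box, S),
                       call = sys.call(-1))))
    }
  }

  # --- background ---------------------------------------------------------
  base <- c(0.27, 0.44, 0.20)
  tex <- smooth_noise(S, S, coarse = 8L, sd = 0.05) +
    matrix(stats::rnorm(S * S, sd = 0.015), S, S)
  rgb <- array(0, c(S, S, 3))
  for (ch in 1:3) rgb[, , ch] <- base[ch] + tex
  thermal <- 0.18 + smooth_noise(S, S, coarse = 8L, sd = 0.02) +
    matrix(stats::rnorm(S * S, sd = 0.01), S, S)

  # --- sprites ------------------------------------------------------------
  ys <- matrix(seq_len(S) - 0.5, S, S)        # pixel-centre y per [row,col]
  xs <- t(ys)                                  # pixel-centre x
  if (length(labels) > 0) {
    for (i in seq_along(labels)) {
      b <- boxes[i, ]
      ci <- labels[i] + 1L
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      a <- (b[3] - b[1]) / 2 * 0.92; bb <- (b[4] - b[2]) / 2 * 0.92
      x1 <- max(1L, floor(b[1])); x2 <- min(S, ceiling(b[3]))
      y1 <- max(1L, floor(b[2])); y2 <- min(S, ceiling(b[4]))
      yy <- ys[y1:y2, x1:x2, drop = FALSE]
      xx <- xs[y1:y2, x1:x2, drop = FALSE]
      d2 <- ((xx - cx) / a)^2 + ((yy - cy) / bb)^2
      mask <- d2 <= 1
      jitter <- stats::rnorm(3, sd = 0.04)
      spot <- (sin(xx * 1.7 + stats::runif(1, 0, 6)) *
                 sin(yy * 1.7 + stats::runif(1, 0, 6))) > 0.55
      for (ch in 1:3) {
        col <- min(max(cls[[c("r", "g", "b")[ch]]][ci] + jitter[ch], 0.02), 0.98)
        plane <- rgb[y1:y2, x1:x2, ch]
        px <- col * (1 - 0.25 * spot[mask])
        plane[mask] <- px
        rgb[y1:y2, x1:x2, ch] <- plane
      }
      amp <- 0.45 + 0.2 * stats::runif(1)
      blob <- exp(-d2 * 2.2) * amp
      thermal[y1:y2, x1:x2] <- thermal[y1:y2, x1:x2] + blob
    }
  }

  # --- condition effects on the RGB frame ----------------------------------
  bright <- c(morning = 0.75, noon = 1.0, evening = 0.4)[[spec$time_of_day]]
  rgb <- rgb * bright
  if (spec$weather == "cloudy") {
    rgb <- (rgb - 0.5) * 0.8 + 0.5 * bright
  } else if (spec$weather == "foggy") {
    rgb <- (rgb - 0.5) * 0.5 + 0.5 * bright + 0.10
  }
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  thermal[thermal < 0] <- 0; thermal[thermal > 1] <- 1

  boxes_tbl <- tibble::tibble(
    class_id = labels,
    group = class_group(labels),
    xmin = if (length(labels)) unname(boxes[, 1]) else numeric(0),
    ymin = if (length(labels)) unname(boxes[, 2]) else numeric(0),
    xmax = if (length(labels)) unname(boxes[, 3]) else numeric(0),
    ymax = if (length(labels)) unname(boxes[, 4]) else numeric(0))

  structure(list(rgb = rgb, thermal = thermal, boxes = boxes_tbl,
                 timestamp = 1000 + spec$seed %% 1000,
                 time_of_day = spec$time_of_day, weather = spec$weather,
                 image_size = S),
            class = "pf_scene")
}

#' Check the annotation invariants of a scene
#'
#' Asserts in-bounds boxes, the 20 px minimum extent, label/group consistency
#' and the warm-target thermal contrast.
#' @param scene A `pf_scene`.
#' @param min_box Minimum box side in pixels.
#' @return `TRUE` invisibly; errors describe any violated invariant.
#' @export
validate_scene <- function(scene, min_box = 20) {
  b <- scene$boxes
  S <- scene$image_size
  if (nrow(b) > 0) {
    stopifnot(all(b$xmin >= 0), all(b$ymin >= 0),
              all(b$xmax <= S), all(b$ymax <= S),
              all(b$xmax - b$xmin >= min_box - 1e-9),
              all(b$ymax - b$ymin >= min_box - 1e-9),
              identical(b$group, class_group(b$class_id)))
    inside <- matrix(FALSE, S, S)
    for (i in seq_len(nrow(b))) {
      inside[max(1, ceiling(b$ymin[i])):min(S, floor(b$ymax[i])),
             max(1, ceiling(b$xmin[i])):min(S, floor(b$xmax[i]))] <- TRUE
    }
    stopifnot(mean(scene$thermal[inside]) > mean(scene$thermal[!inside]))
  }
  invisible(TRUE)
}

#' Generate a 1 Hz environmental sensor series
#'
#' Temperature follows a time-of-day baseline with AR(1) fluctuation, humidity
#' is anti-correlated with temperature (fog pushes it up), and light reflects
#' the time-of-day x weather illumination level. All channels are clipped to
#' physical ranges (temperature -10..50 degC, humidity 0..100 % RH, light 0..1
#' normalized LDR units).
#'
#' @param duration Series length in seconds (>= 2).
#' @param time_of_day,weather Condition facets as in [scene_spec()].
#' @param seed RNG seed.
#' @param t0 Timestamp of the first sample (seconds).
#' @return Tibble `timestamp`, `temperature`, `humidity`, `light` with
#'   `duration + 1` rows at 1 Hz.
#' @export
#' @examples
#' es <- generate_env_series(10, "noon", "sunny", seed = 1)
#' nrow(es)
generate_env_series <- function(duration, time_of_day = "noon",
                                weather = "sunny", seed = 0L, t0 = 0) {
  if (duration < 2) stop("duration must be at least 2 seconds")
  time_of_day <- match.arg(time_of_day, c("morning", "noon", "evening"))
  weather <- match.arg(weather, c("sunny", "cloudy", "foggy"))
  set.seed(seed)
  n <- as.integer(floor(duration)) + 1L
  ts <- t0 + seq_len(n) - 1
  ar1 <- function(n, sd) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, sd = sd)
    for (i in seq_len(n - 1L)) x[i + 1L] <- 0.95 * x[i] + stats::rnorm(1, sd = sd * 0.3)
    x
  }
  temp_base <- c(morning = 18, noon = 28, evening = 15)[[time_of_day]] +
    c(sunny = 2, cloudy = 0, foggy = -2)[[weather]]
  temperature <- pmin(pmax(temp_base + ar1(n, 1.2), -10), 50)
  hum_base <- 90 - 1.5 * (temp_base - 10) +
    c(sunny = -8, cloudy = 0, foggy = 12)[[weather]]
  humidity <- pmin(pmax(hum_base + ar1(n, 3), 0), 100)
  light <- pmin(pmax(condition_light_level(time_of_day, weather) +
                       ar1(n, 0.02), 0), 1)
  tibble::tibble(timestamp = ts, temperature = temperature,
                 humidity = humidity, light = light)
}

#' Sample a dataset of scenes in memory
#'
#' The in-memory counterpart of [generate_dataset()]: identical seeding and
#' condition sampling, but scenes (with their env series attached) are
#' returned directly instead of written to disk.
#' @param n_scenes Number of scenes.
#' @param spec_template A [scene_spec()] supplying everything but the
#'   per-scene seed and condition.
#' @param seed Dataset-level seed; scene `i` uses `seed * 10000 + i`.
#' @param env_halfwidth Seconds of sensor data on each side of the frame.
#' @return List of `pf_scene` objects with `env` tibble and `scene_id`.
#' @export
sample_dataset <- function(n_scenes, spec_template = scene_spec(), seed = 0L,
                           env_halfwidth = 10L) {
  combos <- expand.grid(time_of_day = c("morning", "noon", "evening"),
                        weather = c("sunny", "cloudy", "foggy"),
                        stringsAsFactors = FALSE)
  set.seed(seed)
  combo_idx <- sample.int(nrow(combos), n_scenes, replace = TRUE)
  lapply(seq_len(n_scenes), function(i) {
    sp <- spec_template
    sp$seed <- as.integer((seed * 10000 + i) %% .Machine$integer.max)
    sp$time_of_day <- combos$time_of_day[combo_idx[i]]
    sp$weather <- combos$weather[combo_idx[i]]
    sc <- generate_scene(sp)
    sc$env <- generate_env_series(2L * env_halfwidth, sp$time_of_day,
                                  sp$weather, seed = sp$seed + 1L,
                                  t0 = sc$timestamp - env_halfwidth)
    sc$scene_id <- i
    sc
  })
}

#' Generate a dataset of scenes on disk
#'
#' Writes per-scene RGB and thermal PNGs, a 1 Hz env CSV bracketing each frame
#' timestamp, and a single COCO-style annotation JSON (categories 1-8, pixel
#' `[x, y, w, h]` boxes). Conditions are sampled uniformly over the nine
#' time-of-day x weather combinations.
#'
#' @param n_scenes Number of scenes.
#' @param spec_template A [scene_spec()] supplying everything but the per-scene
#'   seed and condition.
#' @param out_dir Output directory (created if missing).
#' @param seed Dataset-level seed; scene `i` uses `seed * 10000 + i`.
#' @param split Split tag recorded in the manifest.
#' @param env_halfwidth Seconds of sensor data on each side of the frame.
#' @return A `pf_manifest`: tibble of scene files plus `annotations_path`,
#'   `split`, `dir` attributes.
#' @export
generate_dataset <- function(n_scenes, spec_template = scene_spec(),
                             out_dir, seed = 0L, split = "train",
                             env_halfwidth = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenes <- sample_dataset(n_scenes, spec_template, seed, env_halfwidth)
  rows <- vector("list", n_scenes)
  images <- vector("list", n_scenes)
  anns <- list()
  ann_id <- 0L
  for (i in seq_len(n_scenes)) {
    sc <- scenes[[i]]
    es <- sc$env
    tf <- sc$timestamp
    sp <- list(image_size = sc$image_size, time_of_day = sc$time_of_day,
               weather = sc$weather)
    rgb_f <- sprintf("rgb_%04d.png", i)
    th_f <- sprintf("thermal_%04d.png", i)
    env_f <- sprintf("env_%04d.csv", i)
    png::writePNG(sc$rgb, file.path(out_dir, rgb_f))
    png::writePNG(sc$thermal, file.path(out_dir, th_f))
    utils::write.csv(es, file.path(out_dir, env_f), row.names = FALSE)
    images[[i]] <- list(id = i, file_name = rgb_f, width = sp$image_size,
                        height = sp$image_size, thermal_file_name = th_f,
                        env_file_name = env_f, timestamp = tf,
                        time_of_day = sp$time_of_day, weather = sp$weather)
    if (nrow(sc$boxes) > 0) {
      for (j in seq_len(nrow(sc$boxes))) {
        ann_id <- ann_id + 1L
        b <- sc$boxes[j, ]
        anns[[ann_id]] <- list(
          id = ann_id, image_id = i, category_id = b$class_id + 1L,
          bbox = c(b$xmin, b$ymin, b$xmax - b$xmin, b$ymax - b$ymin),
          area = (b$xmax - b$xmin) * (b$ymax - b$ymin), iscrowd = 0L)
      }
    }
    rows[[i]] <- tibble::tibble(
      scene_id = i, rgb = rgb_f, thermal = th_f, env = env_f,
      timestamp = tf, time_of_day = sp$time_of_day, weather = sp$weather)
  }
  cls <- pf_classes()
  categories <- lapply(seq_len(8), function(k) {
    list(id = k, name = cls$name[k], supercategory = cls$group[k])
  })
  ann_path <- file.path(out_dir, "annotations.json")
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = categories),
                       ann_path, auto_unbox = TRUE, digits = NA)
  manifest <- dplyr::bind_rows(rows)
  attr(manifest, "annotations_path") <- ann_path
  attr(manifest, "split") <- split
  attr(manifest, "dir") <- out_dir
  class(manifest) <- c("pf_manifest", class(manifest))
  manifest
}

#' Load a generated dataset back into memory
#'
#' Round-trips [generate_dataset()] output: reads the COCO JSON, per-scene
#' PNGs and env CSVs.
#' @param dir Dataset directory.
#' @return List with `manifest` (tibble), `scenes` (list of `pf_scene` with an
#'   `env` tibble attached) and `annotations` (tibble of all boxes).
#' @export
read_dataset <- function(dir) {
  ann_path <- file.path(dir, "annotations.json")
  stopifnot(file.exists(ann_path))
  coco <- jsonlite::read_json(ann_path, simplifyVector = FALSE)
  ann_tbl <- purrr::map_dfr(coco$annotations, function(a) {
    tibble::tibble(image_id = a$image_id,
                   class_id = a$category_id - 1L,
                   xmin = a$bbox[[1]], ymin = a$bbox[[2]],
                   xmax = a$bbox[[1]] + a$bbox[[3]],
                   ymax = a$bbox[[2]] + a$bbox[[4]])
  })
  if (nrow(ann_tbl)) ann_tbl$group <- class_group(ann_tbl$class_id)
  scenes <- lapply(coco$images, function(im) {
    rgb <- png::readPNG(file.path(dir, im$file_name))
    thermal <- png::readPNG(file.path(dir, im$thermal_file_name))
    if (length(dim(thermal)) == 3L) thermal <- thermal[, , 1]
    boxes <- ann_tbl[ann_tbl$image_id == im$id,
                     c("class_id", "group", "xmin", "ymin", "xmax", "ymax")]
    env <- tibble::as_tibble(utils::read.csv(file.path(dir, im$env_file_name)))
    structure(list(rgb = rgb, thermal = thermal, boxes = boxes,
                   timestamp = im$timestamp, time_of_day = im$time_of_day,
                   weather = im$weather, image_size = im$width,
                   env = env, scene_id = im$id),
              class = "pf_scene")
  })
  manifest <- purrr::map_dfr(coco$images, function(im) {
    tibble::tibble(scene_id = im$id, rgb = im$file_name,
                   thermal = im$thermal_file_name, env = im$env_file_name,
                   timestamp = im$timestamp, time_of_day = im$time_of_day,
                   weather = im$weather)
  })
  list(manifest = manifest, scenes = scenes, annotations = ann_tbl)
}
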