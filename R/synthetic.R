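#' Synthetic underwater scene configuration
#'
#' Describes a ground-truthed image sequence emulating the acquisition
#' conditions of a fixed shallow-water observatory camera: a static textured
#' background, fish-shaped moving foreground ellipses whose per-frame counts
#' follow a photoperiod-dependent Poisson law, slowly growing near-lens
#' bio-fouling patches, turbidity-dependent blur and contrast loss, day
#' (broad illumination) versus night (vignetted artificial light) regimes,
#' occasional fish schools with overlapping bodies, and occasional corrupted
#' frames.
#'
#' Turbidity score s maps to a Gaussian blur of sigma `1.0 * s` px and a
#' contrast scale `1 - 0.15 * s`; fouling score s maps to `c(0, 3, 6, 10)[s+1]`
#' static dark patches whose radii grow every `growth_every` frames.
#'
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param n_frames number of frames.
#' @param day_mean,night_mean Poisson means of the per-frame fish count in
#'   each photoperiod (night abundance is typically much lower).
#' @param fish_axes_a,fish_axes_b semi-axis ranges of the fish ellipses (px).
#' @param fish_contrast range of the fish/background intensity contrast.
#' @param turbidity,fouling condition scores in 0..3.
#' @param school_prob probability that a frame contains a school.
#' @param school_size_mean Poisson mean of the school size.
#' @param error_prob probability a frame is a corrupted (noise) frame.
#' @param wrong_ptz_prob probability a frame views the wrong scene
#'   (flagged `ptz_ok = FALSE`).
#' @param growth_every fouling growth period (frames).
#' @param noise_sd per-frame sensor noise standard deviation.
#' @param start_time timestamp of the first frame (UTC).
#' @param interval_min acquisition interval in minutes.
#' @param fixed_count if not `NULL`, every non-error frame contains exactly
#'   this many fish (overrides the Poisson law; used for controlled tests).
#' @param force_photoperiod `NULL`, `"day"` or `"night"`: override the
#'   irradiance-driven photoperiod.
#' @param seed integer RNG seed; the sequence is bit-reproducible from it.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(frame_shape = c(240, 320), n_frames = 100,
                         day_mean = 3, night_mean = 1,
                         fish_axes_a = c(10, 18), fish_axes_b = c(5, 9),
                         fish_contrast = c(40, 90),
                         turbidity = 0, fouling = 0,
                         school_prob = 0.05, school_size_mean = 6,
                         error_prob = 0.02, wrong_ptz_prob = 0,
                         growth_every = 50, noise_sd = 2,
                         start_time = as.POSIXct("2013-03-01 00:00:00",
                                                 tz = "UTC"),
                         interval_min = 30, fixed_count = NULL,
                         force_photoperiod = NULL, seed = 1L) {
  if (!(turbidity %in% 0:3) || !(fouling %in% 0:3))
    stop_config("turbidity and fouling scores must be integers in 0..3")
  if (day_mean < 0 || night_mean < 0 || school_prob < 0 || error_prob < 0 ||
      noise_sd < 0)
    stop_config("rates and noise levels must be >= 0")
  if (2 * max(fish_axes_a) >= min(frame_shape))
    stop_config("fish larger than frame")
  if (!is.null(force_photoperiod) &&
      !force_photoperiod %in% c("day", "night"))
    stop_config("force_photoperiod must be NULL, 'day' or 'night'")
  structure(as.list(environment()), class = "scene_config")
}

# Rasterize a rotated ellipse; returns logical mask and its outline polygon
# (0-based row/col, 24-gon) for ground truth.
ellipse_mask <- function(shape, cy, cx, a, b, angle) {
  rr <- seq_len(shape[1]) - 1; cc <- seq_len(shape[2]) - 1
  dy <- matrix(rr - cy, shape[1], shape[2])
  dx <- matrix(cc - cx, shape[1], shape[2], byrow = TRUE)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  poly <- cbind(row = cy + a * cos(th) * sin(angle) + b * sin(th) * cos(angle),
                col = cx + a * cos(th) * cos(angle) - b * sin(th) * sin(angle))
  list(mask = mask, poly = poly)
}

make_background <- function(shape) {
  rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
  base <- 70 + 25 * outer(sin(2 * pi * rr / shape[1]),
                          cos(2 * pi * cc / shape[2]), "+") / 2
  rough <- matrix(runif(prod(shape), -1, 1), shape[1], shape[2])
  texture <- EBImage::filter2(rough, EBImage::makeBrush(15, "gaussian",
                                                        sigma = 4),
                              boundary = "replicate")
  base + 60 * texture
}

make_fouling <- function(shape, score, seed) {
  n_patch <- c(0L, 4L, 7L, 10L)[score + 1]
  if (n_patch == 0)
    return(list(base = matrix(FALSE, shape[1], shape[2]), patches = NULL))
  r0 <- min(shape) * c(0, 0.10, 0.13, 0.17)[score + 1]
  withr::with_seed(seed, {
    patches <- lapply(seq_len(n_patch), function(i) {
      # anchored near the frame border (fouling grows on the housing rim)
      side <- sample(4, 1)
      cy <- switch(side, runif(1, 0, 0.15), runif(1, 0.85, 1),
                   runif(1, 0, 1), runif(1, 0, 1)) * (shape[1] - 1)
      cx <- switch(side, runif(1, 0, 1), runif(1, 0, 1),
                   runif(1, 0, 0.15), runif(1, 0.85, 1)) * (shape[2] - 1)
      list(cy = cy, cx = cx, r = r0 * runif(1, 0.7, 1.3),
           lobes = matrix(runif(8, -0.6, 0.6), 4, 2))
    })
    list(base = NULL, patches = patches)
  })
}

fouling_mask_at <- function(fz, shape, growth_steps) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (is.null(fz$patches)) return(mask)
  scale <- 1 + 0.12 * growth_steps
  for (p in fz$patches) {
    r <- p$r * scale
    for (l in seq_len(nrow(p$lobes))) {
      em <- ellipse_mask(shape, p$cy + p$lobes[l, 1] * r,
                         p$cx + p$lobes[l, 2] * r,
                         r * 0.8, r * 0.6, l * pi / 4)
      mask <- mask | em$mask
    }
  }
  mask
}

solar_irradiance <- function(timestamp) {
  h <- as.numeric(format(timestamp, "%H", tz = "UTC")) +
    as.numeric(format(timestamp, "%M", tz = "UTC")) / 60
  800 * pmax(0, sin(pi * (h - 6) / 12))
}

#' Generate a ground-truthed synthetic image sequence
#'
#' Renders the scene described by a [scene_config()]: static background plus
#' contrast-marked fish ellipses (each displaced by at least one body length
#' between frames), fouling patches identical between consecutive frames
#' except at growth steps, whole-frame turbidity blur and contrast
#' compression, a radial vignette at night, sensor noise, and occasional
#' corrupted frames. Annotations carry the visually countable fish number as
#' `observed_count` (a fish at least 20% visible through the fouling is
#' counted, as a human scorer would) together with the configured condition
#' scores.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (a [frame_sequence]), `annotations`
#'   (manifest-style data.frame) and `truth` (per frame: `count`, placed
#'   fish polygons/parameters, visible fractions, error flag; plus the
#'   shared fouling description).
#' @export
generate_sequence <- function(config) {
  shp <- config$frame_shape
  n <- config$n_frames
  ts <- config$start_time + (seq_len(n) - 1) * config$interval_min * 60
  irr <- solar_irradiance(ts)
  photoperiod <- if (!is.null(config$force_photoperiod))
    rep(config$force_photoperiod, n) else ifelse(irr > 5, "day", "night")
  if (!is.null(config$force_photoperiod))
    irr <- if (config$force_photoperiod == "day") rep(800, n) else rep(0, n)
  fz <- make_fouling(shp, config$fouling, seed = config$seed + 7919L)
  withr::with_seed(config$seed, {
    bg <- make_background(shp)
    vignette <- {
      rr <- seq_len(shp[1]) - (shp[1] + 1) / 2
      cc <- seq_len(shp[2]) - (shp[2] + 1) / 2
      d2 <- outer(rr^2, cc^2, "+")
      0.25 + 0.75 * exp(-d2 / (0.18 * sum(shp^2) / 2))
    }
    frames <- vector("list", n)
    truth <- vector("list", n)
    prev_centers <- NULL
    margin_a <- max(config$fish_axes_a)
    for (t in seq_len(n)) {
      is_error <- runif(1) < config$error_prob
      is_wrong_ptz <- !is_error && runif(1) < config$wrong_ptz_prob
      growth_steps <- (t - 1) %/% config$growth_every
      fmask <- fouling_mask_at(fz, shp, growth_steps)
      if (is_error) {
        frames[[t]] <- matrix(runif(prod(shp), 0, 255), shp[1], shp[2])
        truth[[t]] <- list(count = 0L, fish = list(), visible = numeric(0),
                           error = TRUE, ptz_ok = TRUE)
        prev_centers <- NULL
        next
      }
      img <- if (is_wrong_ptz) bg[rev(seq_len(shp[1])), ] + 15 else bg
      ph <- photoperiod[t]
      n_fish <- if (!is.null(config$fixed_count)) config$fixed_count
      else rpois(1, if (ph == "day") config$day_mean else config$night_mean)
      if (is.null(config$fixed_count) && runif(1) < config$school_prob)
        n_fish <- n_fish + rpois(1, config$school_size_mean)
      fish <- list()
      centers <- NULL
      school_anchor <- c(runif(1, 0.3, 0.7) * shp[1],
                         runif(1, 0.3, 0.7) * shp[2])
      for (i in seq_len(n_fish)) {
        a <- runif(1, config$fish_axes_a[1], config$fish_axes_a[2])
        b <- runif(1, config$fish_axes_b[1], config$fish_axes_b[2])
        for (attempt in 1:15) {
          if (i > 6) { # school members cluster around a shared anchor
            cy <- clamp(school_anchor[1] + rnorm(1, 0, 3 * a),
                        margin_a, shp[1] - 1 - margin_a)
            cx <- clamp(school_anchor[2] + rnorm(1, 0, 3 * a),
                        margin_a, shp[2] - 1 - margin_a)
          } else {
            cy <- runif(1, margin_a, shp[1] - 1 - margin_a)
            cx <- runif(1, margin_a, shp[2] - 1 - margin_a)
          }
          # displacement contract: land at least one body length (2a) away
          # from every fish of the previous frame
          if (is.null(prev_centers) ||
              all(sqrt((prev_centers[, 1] - cy)^2 +
                       (prev_centers[, 2] - cx)^2) >= 2 * a)) break
        }
        angle <- runif(1, 0, pi)
        em <- ellipse_mask(shp, cy, cx, a, b, angle)
        contrast <- runif(1, config$fish_contrast[1], config$fish_contrast[2])
        body <- img[em$mask] + contrast +
          rnorm(sum(em$mask), 0, 8)   # mild body texture
        img[em$mask] <- body
        fish[[i]] <- list(cy = cy, cx = cx, a = a, b = b, angle = angle,
                          poly = em$poly, mask_area = sum(em$mask))
        centers <- rbind(centers, c(cy, cx))
      }
      visible <- vapply(fish, function(f) {
        em <- ellipse_mask(shp, f$cy, f$cx, f$a, f$b, f$angle)
        if (f$mask_area == 0) return(0)
        sum(em$mask & !fmask) / f$mask_area
      }, numeric(1))
      # fouling occludes: dark, nearly opaque overlay close to the lens
      img[fmask] <- img[fmask] * 0.12 + 8
      s <- config$turbidity
      if (s > 0) {
        img <- EBImage::filter2(img, EBImage::makeBrush(
          2 * ceiling(2 * s) + 1, "gaussian", sigma = 1.0 * s),
          boundary = "replicate")
        img <- mean(img) + (img - mean(img)) * (1 - 0.15 * s)
      }
      if (ph == "night") img <- img * vignette * 0.85
      img <- img + rnorm(prod(shp), 0, config$noise_sd)
      frames[[t]] <- clamp(img, 0, 255)
      truth[[t]] <- list(count = sum(visible >= 0.2), fish = fish,
                         visible = visible, error = FALSE,
                         ptz_ok = !is_wrong_ptz)
      prev_centers <- centers
    }
  })
  frame_id <- sprintf("f%05d", seq_len(n))
  ann <- data.frame(
    frame_id = frame_id, timestamp = ts,
    observed_count = vapply(truth, function(x) as.numeric(x$count),
                            numeric(1)),
    turbidity = config$turbidity, fouling = config$fouling,
    irradiance = irr, photoperiod = photoperiod,
    ptz_ok = vapply(truth, `[[`, logical(1), "ptz_ok"),
    error_frame = vapply(truth, `[[`, logical(1), "error"),
    stringsAsFactors = FALSE)
  names(truth) <- frame_id
  list(frames = frame_sequence(frame_id, ts, frames,
                               nominal_interval = config$interval_min),
       annotations = ann,
       truth = list(frames = truth, fouling = fz, config_seed = config$seed))
}

#' Write a synthetic dataset to the standard on-disk layout
#'
#' Produces the layout consumed by [load_sequence()]: an `images/` directory
#' of per-frame PNGs, a `manifest.csv` and a `truth.json` with the per-frame
#' ground-truth counts and fish polygons.
#'
#' @param dataset as returned by [generate_sequence()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$frames$frame_id)) {
    png::writePNG(dataset$frames$pixels[[i]] / 255,
                  file.path(img_dir,
                            paste0(dataset$frames$frame_id[i], ".png")))
  }
  ann <- dataset$annotations
  man <- data.frame(
    frame_id = ann$frame_id,
    timestamp_iso8601 = format(ann$timestamp, "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC"),
    observed_count = ann$observed_count, turbidity = ann$turbidity,
    fouling = ann$fouling, irradiance = ann$irradiance,
    photoperiod = ann$photoperiod, ptz_ok = ann$ptz_ok,
    error_frame = ann$error_frame)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth_json <- lapply(dataset$truth$frames, function(fr) {
    list(count = fr$count, error = fr$error,
         visible = fr$visible,
         fish = lapply(fr$fish, function(f)
           list(cy = f$cy, cx = f$cx, a = f$a, b = f$b, angle = f$angle)))
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read ground truth written by [write_dataset()]
#' @param path `truth.json` file path.
#' @return named list (by frame_id) of per-frame truth records.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Generate a labeled feature-space dataset
#'
#' Two multivariate Gaussian classes in the 22-dimensional reference feature
#' space, with class means `separation` pooled standard deviations apart on
#' a random subset of informative features. Exercises the learner in
#' isolation from the imaging pipeline: separation 0 gives Bayes accuracy
#' 0.5, large separations give (near) linearly separable classes.
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param separation class-mean separation in pooled-sigma units.
#' @param seed integer RNG seed.
#' @param n_informative number of informative features.
#' @return list with `X` (feature matrix, schema column names), `y` (0/1
#'   labels) and `informative` (indices of the informative features).
#' @export
generate_feature_dataset <- function(n_pos, n_neg, separation, seed = 1L,
                                     n_informative = 4) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  schema <- default_feature_schema()
  withr::with_seed(seed, {
    informative <- sample.int(length(schema), n_informative)
    n <- n_pos + n_neg
    X <- matrix(rnorm(n * length(schema)), n, length(schema),
                dimnames = list(NULL, schema))
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    for (j in informative)
      X[, j] <- X[, j] + ifelse(y == 1, separation / 2, -separation / 2)
    ord <- sample.int(n)
    list(X = X[ord, , drop = FALSE], y = y[ord], informative = informative)
  })
}
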