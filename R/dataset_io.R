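#' Frame sequence container
#'
#' A time-ordered sequence of grayscale frames from a fixed camera. Frames are
#' stored as numeric matrices with intensities in \[0, 255\] (row = image row,
#' column = image column) together with their acquisition timestamps.
#'
#' @param frame_id character vector of unique frame identifiers.
#' @param timestamp POSIXct vector, strictly increasing after sorting.
#' @param pixels list of numeric matrices (may contain `NULL` for frames not
#'   yet loaded), all sharing one dimension.
#' @param image_path optional character vector of source files.
#' @param nominal_interval nominal acquisition interval in minutes.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frame_id, timestamp, pixels,
                           image_path = rep(NA_character_, length(frame_id)),
                           nominal_interval = 30) {
  frame_id <- as.character(frame_id)
  if (anyDuplicated(frame_id)) stop_data("duplicate frame_id in sequence")
  if (!inherits(timestamp, "POSIXct")) stop_data("timestamps must be POSIXct")
  if (anyDuplicated(timestamp)) {
    dup <- frame_id[duplicated(timestamp)][1]
    stop_data("duplicate timestamp at frame_id '", dup, "'")
  }
  o <- order(timestamp)
  dims <- unique(lapply(pixels[!vapply(pixels, is.null, TRUE)], dim))
  if (length(dims) > 1) stop_data("all frames in a sequence must share dimensions")
  structure(list(frame_id = frame_id[o], timestamp = timestamp[o],
                 pixels = pixels[o], image_path = image_path[o],
                 nominal_interval = nominal_interval),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frame_id)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat(sprintf("<frame_sequence> %d frames, %s .. %s, %s px\n",
              length(x), format(min(x$timestamp)), format(max(x$timestamp)),
              if (is.null(d)) "?" else paste(d, collapse = "x")))
  invisible(x)
}

#' Fetch one frame's pixel matrix, loading it from disk if needed
#' @param seq a `frame_sequence`.
#' @param index frame position.
#' @return numeric matrix, intensities in \[0, 255\].
#' @export
get_frame <- function(seq, index) {
  px <- seq$pixels[[index]]
  if (is.null(px)) px <- read_frame_image(seq$image_path[[index]])
  px
}

#' Read an image file as a grayscale intensity matrix
#'
#' PNG and JPEG are supported. Colour images are converted to grayscale with
#' the classic luma weighting 0.299 R + 0.587 G + 0.114 B.
#'
#' @param path image file path.
#' @return numeric matrix, intensities in \[0, 255\].
#' @export
read_frame_image <- function(path) {
  if (!file.exists(path)) stop_data("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_data("jpeg support not available for: ", path)
    jpeg::readJPEG(path)
  } else stop_data("unsupported image format: ", path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img <- img[, , 1]
  }
  img * 255
}

MANIFEST_COLUMNS <- c("frame_id", "timestamp_iso8601", "observed_count",
                      "turbidity", "fouling", "irradiance", "photoperiod",
                      "ptz_ok", "error_frame")

parse_manifest_timestamp <- function(x) {
  ts <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop_data("unparseable timestamp(s): ",
                           paste(utils::head(x[is.na(ts)], 3), collapse = ", "))
  ts
}

check_score <- function(x, name, ids) {
  bad <- !is.na(x) & !(x %in% 0:3)
  if (any(bad)) stop_data("invalid ", name, " score (must be 0-3) at frame_id '",
                          ids[bad][1], "'")
  as.integer(x)
}

#' Load an image sequence and its annotation manifest
#'
#' Reads a directory of time-stamped frames and a CSV manifest with columns
#' `frame_id, timestamp_iso8601, observed_count, turbidity, fouling,
#' irradiance, photoperiod, ptz_ok, error_frame` (empty cells = missing), and
#' returns the time-sorted sequence joined 1:1 with its annotations.
#'
#' @param image_dir directory containing the image files (`<frame_id>.png` or
#'   an explicit relative path in the manifest's frame_id column).
#' @param manifest path to the manifest CSV.
#' @param lazy if `TRUE` pixel data are loaded on demand by [get_frame()].
#' @return list with `frames` (a [frame_sequence]) and `annotations`
#'   (a data.frame, one row per frame, sorted like the sequence).
#' @export
load_sequence <- function(image_dir, manifest, lazy = FALSE) {
  if (!file.exists(manifest)) stop_data("manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing_cols))
    stop_data("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$frame_id))
    stop_data("duplicate frame_id in manifest: ",
              man$frame_id[duplicated(man$frame_id)][1])
  ts <- parse_manifest_timestamp(man$timestamp_iso8601)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  lgl <- function(x) ifelse(x == "", NA, toupper(x) %in% c("TRUE", "T", "1"))
  ann <- data.frame(
    frame_id = man$frame_id,
    timestamp = ts,
    observed_count = num(man$observed_count),
    turbidity = check_score(num(man$turbidity), "turbidity", man$frame_id),
    fouling = check_score(num(man$fouling), "fouling", man$frame_id),
    irradiance = num(man$irradiance),
    photoperiod = ifelse(man$photoperiod == "", NA, man$photoperiod),
    ptz_ok = lgl(man$ptz_ok),
    error_frame = lgl(man$error_frame),
    stringsAsFactors = FALSE)
  bad_ph <- !is.na(ann$photoperiod) & !(ann$photoperiod %in% c("day", "night"))
  if (any(bad_ph)) stop_data("invalid photoperiod label at frame_id '",
                             ann$frame_id[bad_ph][1], "'")
  if (any(!is.na(ann$observed_count) & ann$observed_count < 0))
    stop_data("negative observed_count in manifest")
  paths <- file.path(image_dir, paste0(man$frame_id, ".png"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop_data("image file missing for frame_id '", man$frame_id[missing][1], "'")
  pixels <- if (lazy) vector("list", nrow(man)) else lapply(paths, read_frame_image)
  frames <- frame_sequence(man$frame_id, ts, pixels, paths)
  ann <- ann[match(frames$frame_id, ann$frame_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(frames = frames, annotations = ann)
}

#' Assign day/night photoperiod labels from solar irradiance
#'
#' A frame is `day` when its global solar irradiance exceeds `threshold`
#' (W m^-2); pre-set photoperiod labels pass through unchanged. Applied
#' vectorised over the annotation table.
#'
#' @param annotations annotation data.frame as returned by [load_sequence()].
#' @param threshold irradiance threshold in W m^-2 separating day from night.
#' @return the annotation data.frame with a complete `photoperiod` column.
#' @export
classify_photoperiod <- function(annotations, threshold = 5) {
  ph <- annotations$photoperiod
  need <- is.na(ph)
  irr <- annotations$irradiance
  if (any(need & is.na(irr)))
    stop_data("frame_id '", annotations$frame_id[need & is.na(irr)][1],
              "' has neither irradiance nor a photoperiod label")
  ph[need] <- ifelse(irr[need] > threshold, "day", "night")
  annotations$photoperiod <- ph
  annotations
}

#' Stratified uniform sampling of training frames
#'
#' Draws `floor(fraction * stratum size)` frames uniformly without replacement
#' within each photoperiod stratum (day and night sampled separately so both
#' illumination regimes are represented).
#'
#' @param annotations annotation data.frame with complete `photoperiod`.
#' @param fraction sampling fraction in (0, 1\].
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#' @return character vector of sampled frame_ids (day stratum first).
#' @export
sample_training_frames <- function(annotations, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1)) stop_config("fraction must be in (0, 1]")
  if (anyNA(annotations$photoperiod))
    stop_data("photoperiod labels required; run classify_photoperiod() first")
  withr::with_seed(seed, {
    unlist(lapply(c("day", "night"), function(ph) {
      ids <- annotations$frame_id[annotations$photoperiod == ph]
      n <- floor(fraction * length(ids))
      if (length(ids) == 0) {
        warning("empty ", ph, " stratum skipped")
        return(character(0))
      }
      ids[sample.int(length(ids), n)]
    }), use.names = FALSE)
  })
}
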