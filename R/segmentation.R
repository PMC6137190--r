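#' Segmentation parameters
#'
#' Parameters of the difference-image segmentation: Gaussian pre-blur,
#' locally adaptive Gaussian-weighted threshold, elliptical morphological
#' opening/closing, and the minimum blob area retained as a region of
#' interest. Defaults target small moving subjects (fish-sized blobs) against
#' a static background.
#'
#' @param k_blur odd Gaussian blur kernel size (px).
#' @param sigma_blur blur standard deviation (px).
#' @param block odd window size of the local Gaussian-weighted mean used as
#'   adaptive threshold surface (px).
#' @param offset additive offset c: a pixel is foreground when its blurred
#'   difference exceeds the local weighted mean by more than `offset`
#'   (intensity units, 0-255 scale).
#' @param k_morph odd diameter of the elliptical (disc) structuring element
#'   for opening-then-closing (px).
#' @param min_blob_area minimum connected-component area kept (px).
#' @return validated list of class `seg_params`.
#' @export
seg_params <- function(k_blur = 5, sigma_blur = 1.5, block = 51, offset = 7,
                       k_morph = 5, min_blob_area = 100) {
  odd <- function(x) x >= 1 && x %% 2 == 1
  if (!odd(k_blur) || !odd(block) || !odd(k_morph))
    stop_config("k_blur, block and k_morph must be odd positive integers")
  if (sigma_blur <= 0 || offset < 0 || min_blob_area < 1)
    stop_config("sigma_blur must be > 0, offset >= 0, min_blob_area >= 1")
  structure(list(k_blur = as.integer(k_blur), sigma_blur = sigma_blur,
                 block = as.integer(block), offset = offset,
                 k_morph = as.integer(k_morph),
                 min_blob_area = as.integer(min_blob_area)),
            class = "seg_params")
}

#' Absolute difference of two consecutive frames
#'
#' Static content (background, bio-fouling) cancels; regions that changed
#' between acquisitions — the candidate moving subjects — survive. The
#' absolute value makes both the arrival and the departure position of a
#' subject visible.
#'
#' @param current,previous grayscale matrices of identical dimension.
#' @return non-negative numeric matrix `abs(current - previous)`.
#' @export
difference_image <- function(current, previous) {
  if (!identical(dim(current), dim(previous)))
    stop_data("frame dimensions differ: ",
              paste(dim(current), collapse = "x"), " vs ",
              paste(dim(previous), collapse = "x"))
  abs(current - previous)
}

#' Blur, adaptively threshold and morphologically clean a difference image
#'
#' Gaussian blur, then a locally adaptive threshold against the
#' Gaussian-weighted neighbourhood mean (window `block`, offset `offset`),
#' then morphological opening (removes speckle) followed by closing (fills
#' small holes) with an elliptical kernel.
#'
#' @param diff non-negative difference image.
#' @param params a [seg_params()] object.
#' @return binary 0/1 matrix of the same dimension.
#' @export
threshold_and_clean <- function(diff, params = seg_params()) {
  if (min(diff) < 0) stop_data("difference image must be non-negative")
  gb <- EBImage::makeBrush(params$k_blur, "gaussian", sigma = params$sigma_blur)
  blurred <- EBImage::filter2(diff, gb, boundary = "replicate")
  wb <- EBImage::makeBrush(params$block, "gaussian", sigma = params$block / 6)
  local_mean <- EBImage::filter2(blurred, wb, boundary = "replicate")
  mask <- (blurred > local_mean + params$offset) * 1
  disc <- EBImage::makeBrush(params$k_morph, "disc")
  mask <- EBImage::closing(EBImage::opening(mask, disc), disc)
  storage.mode(mask) <- "integer"
  unclass(mask)
}

#' Extract convex-hull regions of interest from a binary mask
#'
#' Each connected component with area at least `min_blob_area` becomes one
#' RoI: the component contour is characterised by its convex hull (which
#' smooths the jagged silhouettes produced by uneven light on fish bodies),
#' and the hull's bounding box is mapped back onto the original frame to crop
#' the grayscale patch. Components touching the image border are kept.
#'
#' @param mask binary 0/1 matrix.
#' @param original the original grayscale frame the mask was derived from.
#' @param min_blob_area minimum component pixel count.
#' @param frame_id identifier attributed to the RoIs.
#' @return list of `roi` objects with fields `frame_id`, `hull` (matrix of
#'   0-based (row, col) vertices), `bbox` (`c(r0, c0, r1, c1)`, 0-based,
#'   half-open), `area_px`, `patch` (grayscale crop of `original`) and
#'   `mask` (component mask cropped to the bbox).
#' @export
extract_rois <- function(mask, original, min_blob_area = 100,
                         frame_id = NA_character_) {
  if (!identical(dim(mask), dim(original)))
    stop_data("mask and original frame dimensions differ")
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  if (n_comp == 0) return(list())
  idx <- which(lab > 0)
  comp <- lab[idx]
  sizes <- tabulate(comp, n_comp)
  keep <- which(sizes >= min_blob_area)
  if (!length(keep)) return(list())
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    sel <- comp == k
    r <- rows[sel]; cl <- cols[sel]
    h <- grDevices::chull(cl, r)
    hull <- cbind(row = r[h], col = cl[h]) - 1L
    r0 <- min(r); r1 <- max(r); c0 <- min(cl); c1 <- max(cl)
    cmask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    cmask[cbind(r - r0 + 1L, cl - c0 + 1L)] <- TRUE
    out[[i]] <- structure(list(
      frame_id = frame_id,
      hull = hull,
      bbox = c(r0 - 1L, c0 - 1L, r1, c1),
      area_px = sizes[k],
      patch = original[r0:r1, c0:c1, drop = FALSE],
      mask = cmask), class = "roi")
  }
  out
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> frame %s, bbox [%d,%d)x[%d,%d), area %d px, hull %d vtx\n",
              x$frame_id, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$area_px, nrow(x$hull)))
  invisible(x)
}

#' Segment one frame of a sequence against its predecessor
#'
#' Composition of [difference_image()], [threshold_and_clean()] and
#' [extract_rois()]; the RoIs are attributed to the current frame. Relies on
#' the working assumption of fixed-camera monitoring: relevant subjects
#' (fish) change between consecutive acquisitions faster than irrelevant
#' regions (background, fouling).
#'
#' @param seq a [frame_sequence].
#' @param index frame position, must be at least 2 (the first frame has no
#'   predecessor).
#' @param params a [seg_params()] object.
#' @return list of RoIs (possibly empty).
#' @export
segment_frame <- function(seq, index, params = seg_params()) {
  if (index < 2 || index > length(seq))
    stop_data("index must be in 2..", length(seq), " (no predecessor frame)")
  d <- difference_image(get_frame(seq, index), get_frame(seq, index - 1))
  mask <- threshold_and_clean(d, params)
  extract_rois(mask, get_frame(seq, index), params$min_blob_area,
               frame_id = seq$frame_id[index])
}

#' Segment every frame of a sequence
#' @param seq a [frame_sequence].
#' @param params a [seg_params()] object.
#' @return named list (by frame_id) of RoI lists for frames 2..n.
#' @export
segment_sequence <- function(seq, params = seg_params()) {
  n <- length(seq)
  if (n < 2) stop_data("need at least 2 frames")
  out <- lapply(2:n, function(i) segment_frame(seq, i, params))
  names(out) <- seq$frame_id[2:n]
  out
}

#' Write RoIs to a CSV table
#'
#' One row per RoI: frame_id, bbox, area and the hull vertex list as
#' semicolon-separated `row,col` pairs.
#' @param rois list of RoIs (or list of lists as from [segment_sequence()]).
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  if (length(rois) && is.list(rois[[1]]) && !inherits(rois[[1]], "roi"))
    rois <- unlist(rois, recursive = FALSE)
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(frame_id = r$frame_id, r0 = r$bbox[1], c0 = r$bbox[2],
               r1 = r$bbox[3], c1 = r$bbox[4], area_px = r$area_px,
               hull = paste(r$hull[, 1], r$hull[, 2], sep = ",",
                            collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(frame_id = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
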