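#' Build paired observed/recognized abundance series from a sequence
#'
#' Runs the segmentation and the classifier over every frame that has both a
#' manual count and a predecessor frame (the first frame of a sequence has no
#' difference image and is excluded), and returns one timestamp-aligned row
#' per evaluated frame carrying both counts and the annotation strata.
#'
#' @param seq a [frame_sequence].
#' @param annotations annotation data.frame (sorted like the sequence) with
#'   `observed_count`; strata columns are carried through.
#' @param classifier a `gp_ensemble`, or a function `function(rois, frame_id)`
#'   returning a count (useful as an oracle stub in tests).
#' @param params a [seg_params()].
#' @param extractors feature extractor registry.
#' @return data.frame of class `count_series`: `frame_id, timestamp,
#'   observed, recognized, turbidity, fouling, photoperiod, ptz_ok,
#'   error_frame`.
#' @export
build_series <- function(seq, annotations, classifier,
                         params = seg_params(),
                         extractors = default_feature_extractors()) {
  stopifnot(identical(annotations$frame_id, seq$frame_id))
  eval_idx <- which(!is.na(annotations$observed_count))
  eval_idx <- eval_idx[eval_idx >= 2]
  if (!length(eval_idx)) stop_data("no evaluable frames (need observed counts)")
  counter <- if (is.function(classifier)) classifier
  else function(rois, frame_id) predict_count(classifier, rois, extractors)
  recognized <- vapply(eval_idx, function(i) {
    rois <- segment_frame(seq, i, params)
    as.numeric(counter(rois, seq$frame_id[i]))
  }, numeric(1))
  out <- data.frame(
    frame_id = seq$frame_id[eval_idx],
    timestamp = seq$timestamp[eval_idx],
    observed = annotations$observed_count[eval_idx],
    recognized = recognized,
    turbidity = annotations$turbidity[eval_idx],
    fouling = annotations$fouling[eval_idx],
    photoperiod = annotations$photoperiod[eval_idx],
    ptz_ok = annotations$ptz_ok[eval_idx],
    error_frame = annotations$error_frame[eval_idx],
    stringsAsFactors = FALSE)
  class(out) <- c("count_series", "data.frame")
  out
}

as_count_series <- function(df) {
  class(df) <- c("count_series", "data.frame")
  df
}

#' Reduce a series to well-acquired frames
#'
#' Drops entries whose PTZ camera was mis-positioned (`ptz_ok = FALSE`) or
#' that were acquisition/transmission errors (`error_frame = TRUE`); both the
#' observed and the recognized column are filtered identically because they
#' live on the same rows. Optionally also drops extremely crowded frames
#' (observed count above `max_count`).
#'
#' @param series a `count_series`.
#' @param max_count crowding cutoff; `Inf` (default) disables it.
#' @return the filtered `count_series`.
#' @export
filter_reduced <- function(series, max_count = Inf) {
  keep <- (is.na(series$ptz_ok) | series$ptz_ok) &
    (is.na(series$error_frame) | !series$error_frame) &
    series$observed <= max_count
  as_count_series(series[keep, , drop = FALSE])
}

#' Keep entries whose turbidity/fouling scores fall in the given subsets
#'
#' @param series a `count_series`.
#' @param turbidity,fouling integer subsets of \{0, 1, 2, 3\}.
#' @return the stratified `count_series` (possibly empty).
#' @export
stratify <- function(series, turbidity = 0:3, fouling = 0:3) {
  keep <- series$turbidity %in% turbidity & series$fouling %in% fouling
  as_count_series(series[keep, , drop = FALSE])
}

#' Aggregate a paired series to a coarser temporal scale
#'
#' `raw_30min` is the identity; `day_night` averages the observed and
#' recognized counts per (calendar day, photoperiod); `monthly` averages per
#' calendar month. Calendar boundaries use the civil time zone `tz` (the
#' observatory's clock).
#'
#' @param series a `count_series`.
#' @param scale one of `"raw_30min"`, `"day_night"`, `"monthly"`.
#' @param tz time zone for the calendar grouping.
#' @return for `raw_30min` the input; otherwise a data.frame with the group
#'   keys, mean `observed`, mean `recognized` and group size `n`, in
#'   chronological order.
#' @export
aggregate_series <- function(series, scale = c("raw_30min", "day_night",
                                               "monthly"), tz = "CET") {
  scale <- match.arg(scale)
  if (scale == "raw_30min") return(series)
  if (scale == "day_night") {
    if (anyNA(series$photoperiod))
      stop_data("day/night aggregation needs photoperiod labels")
    date <- format(as.Date(series$timestamp, tz = tz))
    keys <- paste(date, series$photoperiod)
  } else {
    keys <- format(series$timestamp, "%Y-%m", tz = tz)
  }
  sp <- split(seq_along(keys), keys)   # key order is chronological
  agg <- data.frame(
    observed = vapply(sp, function(i) mean(series$observed[i]), numeric(1)),
    recognized = vapply(sp, function(i) mean(series$recognized[i]),
                        numeric(1)),
    n = lengths(sp))
  if (scale == "day_night") {
    agg <- cbind(date = as.Date(sub(" .*", "", names(sp))),
                 photoperiod = sub(".* ", "", names(sp)), agg)
  } else {
    agg <- cbind(month = names(sp), agg)
  }
  rownames(agg) <- NULL
  agg
}

#' Pearson correlation between two aligned count vectors
#'
#' Product-moment r with the two-sided p-value from the t transform on n - 2
#' degrees of freedom. Undefined cases (either vector constant, n < 3) are
#' flagged rather than reported as 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return list of class `correlation_result`: `r`, `p`, `n`, `defined`.
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) stop_data("series lengths differ")
  n <- length(a)
  if (n < 3 || sd(a) == 0 || sd(b) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          defined = FALSE), class = "correlation_result"))
  ct <- stats::cor.test(a, b, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 defined = TRUE), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<correlation> r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  else cat(sprintf("<correlation> undefined (n = %d)\n", x$n))
  invisible(x)
}

#' Pearson correlation of two count series on aligned timestamps
#'
#' @param a,b `count_series` objects covering identical timestamps, or a
#'   single paired series (`b` missing) whose `observed` and `recognized`
#'   columns are correlated.
#' @return a `correlation_result`.
#' @export
series_pearson <- function(a, b = NULL) {
  if (is.null(b)) return(pearson_cor(a$observed, a$recognized))
  if (!identical(a$timestamp, b$timestamp))
    stop_data("misaligned timestamps between series")
  pearson_cor(a$observed, b$observed)
}

#' Correlation grid over turbidity and fouling strata
#'
#' The stratified evaluation table: for every (turbidity, fouling) score pair
#' the paired series is restricted to that stratum, aggregated to `scale`,
#' and correlated. Undefined correlations (constant series or fewer than 3
#' aggregated entries) are reported as missing.
#'
#' @param series a `count_series`.
#' @param scale aggregation scale, see [aggregate_series()].
#' @param reduced if `TRUE`, apply [filter_reduced()] first.
#' @param max_count crowding cutoff passed to [filter_reduced()].
#' @param tz calendar time zone.
#' @return data.frame with columns `turbidity, fouling, r, p, n` (16 rows).
#' @export
correlation_grid <- function(series, scale = "raw_30min", reduced = FALSE,
                             max_count = Inf, tz = "CET") {
  if (reduced) series <- filter_reduced(series, max_count)
  grid <- expand.grid(turbidity = 0:3, fouling = 0:3)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- stratify(series, grid$turbidity[i], grid$fouling[i])
    if (!nrow(s)) return(list(r = NA_real_, p = NA_real_, n = 0L))
    ag <- aggregate_series(s, scale, tz)
    cr <- pearson_cor(ag$observed, ag$recognized)
    list(r = cr$r, p = cr$p, n = cr$n)
  })
  data.frame(grid,
             r = vapply(res, `[[`, numeric(1), "r"),
             p = vapply(res, `[[`, numeric(1), "p"),
             n = vapply(res, `[[`, integer(1), "n"))
}
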