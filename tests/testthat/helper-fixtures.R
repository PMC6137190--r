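# Small fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures on disk.

# A frame_sequence from a list of matrices, 30 min apart.
make_seq <- function(mats, start = as.POSIXct("2013-06-01 10:00:00",
                                              tz = "UTC")) {
  n <- length(mats)
  frame_sequence(sprintf("t%03d", seq_len(n)), start + (seq_len(n) - 1) * 1800,
                 mats)
}

# Minimal annotation table matching a sequence.
make_ann <- function(seq, observed, turbidity = 0L, fouling = 0L,
                     photoperiod = "day", ptz_ok = TRUE, error_frame = FALSE,
                     irradiance = 500) {
  n <- length(seq)
  data.frame(frame_id = seq$frame_id, timestamp = seq$timestamp,
             observed_count = observed,
             turbidity = rep_len(turbidity, n), fouling = rep_len(fouling, n),
             irradiance = rep_len(irradiance, n),
             photoperiod = rep_len(photoperiod, n),
             ptz_ok = rep_len(ptz_ok, n),
             error_frame = rep_len(error_frame, n),
             stringsAsFactors = FALSE)
}

# A count_series directly from vectors (no imaging), for the pure
# time-series / statistics tests.
make_series <- function(observed, recognized = observed,
                        start = as.POSIXct("2013-01-01 00:00:00", tz = "UTC"),
                        step_min = 30, turbidity = 0L, fouling = 0L,
                        photoperiod = "day", ptz_ok = TRUE,
                        error_frame = FALSE) {
  n <- length(observed)
  df <- data.frame(
    frame_id = sprintf("s%04d", seq_len(n)),
    timestamp = start + (seq_len(n) - 1) * step_min * 60,
    observed = observed, recognized = recognized,
    turbidity = rep_len(turbidity, n), fouling = rep_len(fouling, n),
    photoperiod = rep_len(photoperiod, n), ptz_ok = rep_len(ptz_ok, n),
    error_frame = rep_len(error_frame, n), stringsAsFactors = FALSE)
  class(df) <- c("count_series", "data.frame")
  df
}

# A RoI built from an explicit component mask placed on a background frame.
make_roi <- function(comp_mask, frame = NULL, frame_dim = c(80, 100),
                     offset = c(10, 10), patch_value = 128) {
  fr <- frame
  if (is.null(fr)) fr <- matrix(40, frame_dim[1], frame_dim[2])
  full <- matrix(0L, nrow(fr), ncol(fr))
  rr <- offset[1] + seq_len(nrow(comp_mask)) - 1
  cc <- offset[2] + seq_len(ncol(comp_mask)) - 1
  full[rr, cc] <- comp_mask * 1L
  sub <- fr[rr, cc, drop = FALSE]
  sub[comp_mask > 0] <- patch_value
  fr[rr, cc] <- sub
  rois <- extract_rois(full, fr, min_blob_area = 1, frame_id = "fix")
  stopifnot(length(rois) == 1)
  rois[[1]]
}

# Trivial one-tree ensembles: always-positive / always-negative voters.
make_const_ensemble <- function(value, n_features = 22) {
  tree <- list(const = value)
  ind <- structure(list(tree = tree, fitness = NA_real_, size = 1L,
                        depth = 1L), class = "gp_individual")
  structure(list(individuals = list(ind),
                 feature_names = default_feature_schema(),
                 ranges = list(min = rep(0, n_features),
                               max = rep(1, n_features)),
                 theta = 0.5, k = 1, repeats = 1,
                 config = gp_config(), seed = 1L),
            class = "gp_ensemble")
}

# Brute-force symmetric GLCM statistics: the independent oracle for the
# vectorized implementation.
brute_glcm <- function(patch, levels = 32) {
  q <- pmin(floor(patch / 256 * levels), levels - 1)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  lev <- 0:(levels - 1)
  out <- matrix(0, 4, 4)
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    P <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        a <- q[i, j] + 1; b <- q[i2, j2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    P <- P / sum(P)
    pi_ <- rowSums(P)
    mu <- sum(lev * pi_); s2 <- sum((lev - mu)^2 * pi_)
    dm <- outer(lev, lev, "-")
    out[k, ] <- c(sum(P * dm^2),
                  if (s2 > 0) sum(P * outer(lev - mu, lev - mu)) / s2 else 0,
                  sum(P^2), sum(P / (1 + abs(dm))))
  }
  colMeans(out)
}
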