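#' Names of the reference 22-feature schema
#'
#' Nine texture descriptors computed on the grayscale patch (first-order
#' intensity statistics plus gray-level co-occurrence statistics averaged
#' over the four distance-1 offsets) followed by thirteen shape descriptors
#' of the convex hull and component mask (six hull/mask geometry measures
#' plus the seven Hu invariants). The learner performs implicit
#' feature selection, so the schema is a superset that can be swapped via the
#' `extractors` argument of [extract_features()] without touching the
#' classifier.
#'
#' @return character vector of length 22.
#' @export
default_feature_schema <- function() {
  c("int_mean", "int_std", "int_skewness", "int_kurtosis", "int_entropy",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "hull_area", "hull_perimeter", "circularity", "aspect_ratio",
    "solidity", "eccentricity",
    paste0("hu", 1:7))
}

#' Gray-level co-occurrence statistics
#'
#' The patch is quantized to `levels` gray levels; symmetric co-occurrence
#' matrices are accumulated at distance 1 for the four offsets (0, 45, 90,
#' 135 degrees) and the four Haralick-style statistics are averaged over
#' offsets. On a constant patch correlation is defined as 0.
#'
#' @param patch grayscale matrix, intensities in \[0, 255\].
#' @param levels number of quantization levels.
#' @return named vector: contrast, correlation, energy, homogeneity.
#' @keywords internal
glcm_stats <- function(patch, levels = 32) {
  q <- pmin(floor(patch / 256 * levels), levels - 1)
  nr <- nrow(q); nc <- ncol(q)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  lev <- 0:(levels - 1)
  stats <- matrix(0, 4, 4)
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- tabulate(a * levels + b + 1, levels * levels)
    P <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + t(P)                       # symmetric GLCM
    P <- P / sum(P)
    pi_ <- rowSums(P)
    mu <- sum(lev * pi_)
    s2 <- sum((lev - mu)^2 * pi_)
    dmat <- outer(lev, lev, "-")
    contrast <- sum(P * dmat^2)
    correlation <- if (s2 > 0)
      sum(P * outer(lev - mu, lev - mu)) / s2 else 0
    energy <- sum(P^2)
    homogeneity <- sum(P / (1 + abs(dmat)))
    stats[k, ] <- c(contrast, correlation, energy, homogeneity)
  }
  colMeans(stats)
}

#' Texture features of a RoI patch
#'
#' First-order statistics of the intensity distribution (mean, population
#' standard deviation, skewness, kurtosis, Shannon entropy of the 256-bin
#' histogram in bits) and the four averaged co-occurrence statistics. Moments
#' of a constant patch degenerate gracefully (skewness, kurtosis and
#' correlation are defined as 0; entropy is 0; energy is 1).
#'
#' @param patch non-empty grayscale matrix, intensities in \[0, 255\].
#' @return named numeric vector of length 9.
#' @export
texture_features <- function(patch) {
  if (length(patch) == 0) stop_data("empty patch")
  v <- as.numeric(patch)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  s <- sqrt(s2)
  skw <- if (s > 0) mean((v - m)^3) / s^3 else 0
  kur <- if (s > 0) mean((v - m)^4) / s2^2 else 0
  bins <- tabulate(clamp(floor(v), 0, 255) + 1, 256)
  p <- bins[bins > 0] / length(v)
  entropy <- -sum(p * log2(p))
  g <- glcm_stats(patch)
  c(int_mean = m, int_std = s, int_skewness = skw, int_kurtosis = kur,
    int_entropy = entropy,
    glcm_contrast = g[1], glcm_correlation = g[2], glcm_energy = g[3],
    glcm_homogeneity = g[4])
}

#' Seven Hu moment invariants, log-scaled
#'
#' Computed from the normalized central moments of a binary mask and
#' log-scaled as `-sign(h) * log10(|h|)` to compress their dynamic range;
#' an exactly zero invariant maps to 0.
#'
#' @param mask logical or 0/1 matrix.
#' @return numeric vector of length 7.
#' @keywords internal
hu_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  m00 <- length(x)
  if (m00 == 0) return(rep(0, 7))
  xb <- mean(x); yb <- mean(y)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- numeric(7)
  h[1] <- n20 + n02
  h[2] <- (n20 - n02)^2 + 4 * n11^2
  h[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h[4] <- (n30 + n12)^2 + (n21 + n03)^2
  h[5] <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h[7] <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  ifelse(h == 0, 0, -sign(h) * log10(abs(h) + 1e-300))
}

#' Shape features of a RoI
#'
#' Hull geometry (pixel-accurate hull area, hull perimeter, circularity
#' 4*pi*A/P^2, bounding-box aspect ratio), the solidity of the component
#' within its hull, the eccentricity of the best-fit ellipse of the
#' component mask, and the seven log-scaled Hu moment invariants of the
#' mask. The hull pixel area is the shoelace area of the pixel-centre
#' polygon plus perimeter/2 plus 1, so a square component that is its own
#' hull has solidity exactly 1.
#'
#' @param roi a `roi` object with at least 3 non-collinear hull vertices.
#' @return named numeric vector of length 13.
#' @export
shape_features <- function(roi) {
  hull <- roi$hull
  if (nrow(hull) < 3) stop_data("degenerate hull (fewer than 3 vertices)")
  geom <- polygon_geometry(hull)
  if (geom$area <= 0) stop_data("degenerate (collinear) hull")
  hull_area <- geom$area + geom$perimeter / 2 + 1   # pixel-accurate area
  hull_per <- geom$perimeter
  circ <- 4 * pi * hull_area / hull_per^2
  bb_h <- roi$bbox[3] - roi$bbox[1]
  bb_w <- roi$bbox[4] - roi$bbox[2]
  aspect <- bb_w / bb_h
  solidity <- roi$area_px / hull_area
  idx <- which(roi$mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- mean((x - mean(x))^2); mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  dd <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
  ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
  c(hull_area = hull_area, hull_perimeter = hull_per, circularity = circ,
    aspect_ratio = aspect, solidity = solidity, eccentricity = ecc,
    setNames(hu_moments(roi$mask), paste0("hu", 1:7)))
}

#' Default feature extractor blocks
#'
#' A pluggable registry: a named list of functions, each mapping a RoI to a
#' named numeric vector. Replacing or extending the list changes the feature
#' schema without touching the learner.
#' @return named list of extractor functions.
#' @export
default_feature_extractors <- function() {
  list(texture = function(roi) texture_features(roi$patch),
       shape = function(roi) shape_features(roi))
}

#' Full feature vector of a RoI
#'
#' Concatenates the extractor blocks (by default texture then shape, the
#' 22-name schema of [default_feature_schema()]). All values are finite.
#'
#' @param roi a `roi` object.
#' @param extractors extractor registry, see [default_feature_extractors()].
#' @return named numeric vector.
#' @export
extract_features <- function(roi, extractors = default_feature_extractors()) {
  v <- unlist(lapply(extractors, function(f) f(roi)), use.names = TRUE)
  names(v) <- sub("^[^.]+\\.", "", names(v))
  if (any(!is.finite(v)))
    stop_data("non-finite feature value(s): ",
              paste(names(v)[!is.finite(v)], collapse = ", "))
  v
}

#' Feature matrix for a list of RoIs
#' @param rois list of RoIs.
#' @param extractors extractor registry.
#' @return numeric matrix, one row per RoI, columns named by the schema.
#' @export
feature_matrix <- function(rois, extractors = default_feature_extractors()) {
  if (!length(rois))
    return(matrix(numeric(0), 0, length(default_feature_schema()),
                  dimnames = list(NULL, default_feature_schema())))
  t(vapply(rois, extract_features, extract_features(rois[[1]],
                                                    extractors = extractors),
           extractors = extractors))
}

#' Min-max normalization ranges from a training feature matrix
#' @param X numeric training matrix (rows = examples).
#' @return list with vectors `min` and `max` (per column).
#' @export
feature_ranges <- function(X) {
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}

#' Apply stored min-max normalization, clipping to \[0, 1\]
#'
#' Features are scaled with the training-set ranges stored alongside the
#' model; values outside the training range are clipped. A constant training
#' column maps to 0.
#'
#' @param X numeric matrix.
#' @param ranges as returned by [feature_ranges()].
#' @return matrix of the same dimension with values in \[0, 1\].
#' @export
apply_normalization <- function(X, ranges) {
  span <- ranges$max - ranges$min
  span[span == 0] <- 1
  X01 <- sweep(sweep(X, 2, ranges$min), 2, span, "/")
  clamp(X01, 0, 1)
}
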