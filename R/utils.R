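`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Error conditions with CLI-relevant classes
#'
#' `stop_config()` signals a configuration/validation error (CLI exit code 2),
#' `stop_data()` a data error (CLI exit code 3).
#' @param ... message parts passed to [sprintf()]-free paste.
#' @keywords internal
#' @name fishcam-conditions
NULL

stop_config <- function(...) {
  stop(structure(class = c("fishcam_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("fishcam_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Shoelace area and perimeter of a pixel-centre polygon
#'
#' @param poly numeric matrix with columns (row, col), vertices in order.
#' @return list with `area` (unsigned shoelace area) and `perimeter`.
#' @keywords internal
polygon_geometry <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  if (n < 3) return(list(area = 0, perimeter = 0))
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area, perimeter = per)
}

#' Rasterize a convex polygon to a logical pixel mask
#'
#' Pixel centres at integer 0-based (row, col) coordinates; a pixel is in the
#' mask when its centre lies inside or on the polygon boundary.
#'
#' @param poly matrix, columns (row, col), 0-based, vertices in hull order.
#' @param nrow,ncol mask dimensions.
#' @return logical matrix of dim `c(nrow, ncol)`.
#' @keywords internal
convex_polygon_mask <- function(poly, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  if (is.null(dim(poly)) || nrow(poly) < 1) return(mask)
  if (nrow(poly) <= 2) { # point or segment: mark covered pixels
    r <- round(poly[, 1]) + 1L; c <- round(poly[, 2]) + 1L
    ok <- r >= 1 & r <= nrow & c >= 1 & c <= ncol
    mask[cbind(r[ok], c[ok])] <- TRUE
    return(mask)
  }
  y <- poly[, 1]; x <- poly[, 2]
  # ensure counter-clockwise orientation in (x, y)
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) { x <- rev(x); y <- rev(y) }
  r0 <- max(0L, floor(min(y))); r1 <- min(nrow - 1L, ceiling(max(y)))
  c0 <- max(0L, floor(min(x))); c1 <- min(ncol - 1L, ceiling(max(x)))
  if (r1 < r0 || c1 < c0) return(mask)
  rr <- r0:r1; cc <- c0:c1
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inside <- matrix(TRUE, length(rr), length(cc))
  n <- length(x)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cross <- (x[k2] - x[k]) * (py - y[k]) - (y[k2] - y[k]) * (px - x[k])
    inside <- inside & (cross >= -1e-9)
  }
  sub <- mask[rr + 1L, cc + 1L, drop = FALSE]
  sub[inside] <- TRUE
  mask[rr + 1L, cc + 1L] <- sub
  mask
}

#' Intersection-over-union of two logical masks
#' @param a,b logical matrices of identical dimension.
#' @return IoU in \[0, 1\]; 0 when the union is empty.
#' @keywords internal
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Classification metrics from a confusion configuration
#'
#' Accuracy, true positive rate and false positive rate:
#' ACC = (TP+TN)/(TP+FP+FN+TN), TPR = TP/(TP+FN), FPR = FP/(FP+TN).
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts.
#' @return named numeric vector `c(acc, tpr, fpr)`; a rate with an empty
#'   denominator is `NaN`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  c(acc = (tp + tn) / (tp + fp + fn + tn),
    tpr = tp / (tp + fn),
    fpr = fp / (fp + tn))
}
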