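# Contour agreement metrics (mean absolute distance, Dice similarity
# coefficient on rasterized interiors) and confusion-matrix rates.

#' Mean absolute distance between two contours
#'
#' Symmetric average of the two directed mean nearest-point distances.
#' Both contours are densely resampled (default 1 px arc step) before
#' distance evaluation, so the result approximates the continuous
#' point-to-curve distance rather than a control-point distance.
#'
#' @param a,b contours or n x 2 polyline matrices.
#' @param step resampling arc step in pixels.
#' @param closed treat the inputs as closed polygons.
#' @return distance in pixels.
#' @export
contour_mad <- function(a, b, step = 1, closed = TRUE) {
  pa <- dense_resample(as.matrix(a), step = step, closed = closed)
  pb <- dense_resample(as.matrix(b), step = step, closed = closed)
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("empty contour")
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Dice similarity coefficient of two contour interiors
#'
#' Rasterizes both simple polygons on the native pixel grid (a pixel
#' belongs to a region iff its centre lies inside the polygon, even-odd
#' rule) and returns `2 |A and B| / (|A| + |B|)`. Contours are deemed
#' similar when the DSC exceeds 0.75.
#'
#' @param a,b contours or n x 2 polygon matrices.
#' @return DSC in `[0, 1]`.
#' @export
contour_dsc <- function(a, b) {
  pa <- as.matrix(a); pb <- as.matrix(b)
  xr <- range(c(pa[, 1], pb[, 1])); yr <- range(c(pa[, 2], pb[, 2]))
  xs <- seq(floor(xr[1]), ceiling(xr[2]))
  ys <- seq(floor(yr[1]), ceiling(yr[2]))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- points_in_polygon(gx, gy, pa)
  in_b <- points_in_polygon(gx, gy, pb)
  total <- sum(in_a) + sum(in_b)
  if (total == 0L) stop("zero total area after rasterization")
  2 * sum(in_a & in_b) / total
}

#' Confusion matrix constructor
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return list of class `atasm_confusion`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "atasm_confusion")
}

#' Classification accuracy in percent
#'
#' `(TP + TN) / (TP + TN + FP + FN) * 100`.
#'
#' @param cm an [confusion_matrix()].
#' @return percentage.
#' @export
classification_accuracy <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total <= 0) stop("empty confusion matrix")
  100 * (cm$tp + cm$tn) / total
}

#' Classification precision in percent
#'
#' `TP / (TP + FP) * 100`; undefined (error) when no positive
#' predictions exist.
#'
#' @param cm an [confusion_matrix()].
#' @return percentage.
#' @export
classification_precision <- function(cm) {
  denom <- cm$tp + cm$fp
  if (denom <= 0) stop("precision undefined: no positive predictions")
  100 * cm$tp / denom
}
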