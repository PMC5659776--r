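# Contours: ordered closed polylines of 20 control points in image pixel
# coordinates. The canonical ordering starts at the topmost point
# (smallest y) and has positive shoelace signed area in (x, y).

ATASM_N_POINTS <- 20L

#' Construct a contour object
#'
#' A contour is an n x 2 numeric matrix (columns `x`, `y`) with class
#' `atasm_contour`. Control-point contours produced by
#' [resample_contour()] always have exactly 20 rows.
#'
#' @param points n x 2 numeric matrix or data frame of (x, y) coordinates.
#' @param closed logical; tendon and sheath contours are closed.
#' @param pixel_spacing_mm physical pixel edge length (default 0.075 mm,
#'   the transverse A1-pulley scan resolution the package assumes).
#' @return an `atasm_contour` matrix.
#' @export
as_contour <- function(points, closed = TRUE, pixel_spacing_mm = 0.075) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("contour points must have two columns (x, y)")
  storage.mode(p) <- "double"
  if (anyNA(p) || any(!is.finite(p))) stop("contour contains non-finite coordinates")
  colnames(p) <- c("x", "y")
  structure(p, closed = closed, pixel_spacing_mm = pixel_spacing_mm,
            class = c("atasm_contour", "matrix", "array"))
}

contour_points <- function(contour) {
  p <- unclass(contour)
  attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
  dim(p) <- dim(contour)
  p
}

#' Resample a closed polygon to 20 canonical control points
#'
#' Picks the four extremal anchors (topmost, bottommost, leftmost,
#' rightmost vertices) and places four arc-length-equidistant points
#' between each adjacent anchor pair, giving 20 control points ordered
#' from the top anchor with positive signed area.
#'
#' @param raw_points m x 2 matrix (m >= 8) of ordered vertices of a simple
#'   closed polygon.
#' @param pixel_spacing_mm carried through to the result.
#' @return an `atasm_contour` with 20 control points.
#' @export
resample_contour <- function(raw_points, pixel_spacing_mm = 0.075) {
  p <- as.matrix(raw_points)
  storage.mode(p) <- "double"
  if (nrow(p) >= 2L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 8L) stop("need at least 8 polygon vertices")
  area <- polygon_signed_area(p)
  if (abs(area) < 1e-9) stop("degenerate polygon: zero area")
  if (area < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]

  pick <- function(ord) order(ord[, 1], ord[, 2])[1]
  i_top    <- pick(cbind(p[, 2],  p[, 1]))
  i_bottom <- pick(cbind(-p[, 2], -p[, 1]))
  i_left   <- pick(cbind(p[, 1],  p[, 2]))
  i_right  <- pick(cbind(-p[, 1], -p[, 2]))
  anchors <- c(i_top, i_bottom, i_left, i_right)
  if (anyDuplicated(anchors)) stop("degenerate polygon: coincident extremal anchors")

  s <- arc_lengths(p, closed = TRUE)
  total <- s[length(s)]
  # anchors ordered by traversal position starting at the top anchor,
  # unwrapped so positions increase monotonically along the polygon
  a_pos <- s[anchors]
  a_pos <- a_pos[1] + sort((a_pos - a_pos[1]) %% total)
  out <- matrix(NA_real_, ATASM_N_POINTS, 2L)
  for (k in 1:4) {
    s0 <- a_pos[k]
    s1 <- if (k < 4) a_pos[k + 1] else a_pos[1] + total
    at <- s0 + (0:4) / 5 * (s1 - s0)
    out[(k - 1L) * 5L + 1:5, ] <- point_at_arc(p, at)
  }
  ctr <- as_contour(out, pixel_spacing_mm = pixel_spacing_mm)
  if (!polygon_is_simple(out)) stop("resampled contour self-intersects")
  ctr
}

#' Read a contour from a plain-text coordinate file
#'
#' Accepts one point per row in any of the dialects `X,Y`, `(X,Y)` or
#' whitespace-separated `X Y`; floating point values allowed.
#'
#' @param path file path.
#' @return an `atasm_contour` (not resampled; row count as in the file).
#' @export
read_contour <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) < 3L) stop("contour file has fewer than 3 points: ", path)
  ln_no <- which(keep)
  pts <- matrix(NA_real_, length(lines), 2L)
  for (i in seq_along(lines)) {
    ln <- gsub("[()]", "", lines[i])
    parts <- strsplit(ln, "[,[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals))
      stop("malformed contour row at line ", ln_no[i], " of ", path, ": '", lines[i], "'")
    pts[i, ] <- vals
  }
  as_contour(pts)
}

#' Write a contour as `X,Y` rows
#'
#' @param contour an `atasm_contour` or n x 2 matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  p <- as.matrix(contour)
  writeLines(sprintf("%.6f,%.6f", p[, 1], p[, 2]), path)
  invisible(path)
}

#' Outward unit normals at contour control points
#'
#' The normal at point i is the unit perpendicular of the central
#' difference c(i+1) - c(i-1), with its sign chosen to point away from
#' the contour centroid.
#'
#' @param contour closed contour (n x 2).
#' @return n x 2 matrix of unit normals.
#' @export
contour_normals <- function(contour) {
  p <- as.matrix(contour)
  n <- nrow(p)
  ip1 <- c(2:n, 1L); im1 <- c(n, 1:(n - 1L))
  tg <- p[ip1, , drop = FALSE] - p[im1, , drop = FALSE]
  nrm <- cbind(tg[, 2], -tg[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  ctr <- colMeans(p)
  flip <- rowSums(nrm * sweep(p, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

# Centroid of a contour's control points.
contour_centroid <- function(contour) colMeans(as.matrix(contour))
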