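# Shared numeric helpers: interpolation, convolution, similarity fits,
# polygon geometry. Coordinates are 1-based pixel centers, x = column,
# y = row (row index increases downward). Images are numeric matrices
# with intensities nominally in [0, 255].

#' Bilinear interpolation of an image at sub-pixel positions
#'
#' Positions outside the image are clamped to the border (nearest-border
#' value), matching the sampling policy used throughout the package.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param x,y numeric vectors of equal length, 1-based coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(nr >= 2L, nc >= 2L)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- y0 + (x0 - 1) * nr
  v00 <- img[i00]
  v10 <- img[i00 + nr]
  v01 <- img[i00 + 1]
  v11 <- img[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# TRUE if any of (x, y) falls outside the image extent.
out_of_image <- function(img, x, y) {
  any(x < 1 | x > ncol(img) | y < 1 | y > nrow(img))
}

#' 2-D convolution with reflected borders
#'
#' Pads the image by edge reflection, convolves with `kernel` (true
#' convolution, FFT-based), and crops back to the input extent.
#'
#' @param img numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @return numeric matrix, same dimensions as `img`.
#' @keywords internal
convolve2_reflect <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  py <- (kr - 1L) %/% 2L
  px <- (kc - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(nr > py, nc > px)
  ridx <- c(rev(seq_len(py) + 1L), seq_len(nr), nr - seq_len(py))
  cidx <- c(rev(seq_len(px) + 1L), seq_len(nc), nc - seq_len(px))
  padded <- img[ridx, cidx, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[py + seq_len(nr), px + seq_len(nc), drop = FALSE]
}

#' Least-squares similarity transform between point sets
#'
#' Finds scale `s`, rotation `R` (no reflection) and translation `t`
#' minimizing sum ||s R x_i + t - y_i||^2 over corresponding rows.
#'
#' @param src,dst n x 2 matrices of corresponding points.
#' @return list with `scale`, `rotation` (2 x 2), `translation` (length 2)
#'   and `apply`, a function mapping an n x 2 matrix through the transform.
#' @keywords internal
fit_similarity <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 2L, ncol(dst) == 2L)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  xc <- sweep(src, 2, mu_s); yc <- sweep(dst, 2, mu_d)
  a <- crossprod(yc, xc)                       # sum y_c x_c^T
  sv <- svd(a)
  d <- sign(det(sv$u) * det(sv$v))
  s_mat <- diag(c(1, d))
  rot <- sv$u %*% s_mat %*% t(sv$v)
  denom <- sum(xc^2)
  if (denom < .Machine$double.eps) stop("degenerate (coincident) source points")
  scl <- sum(sv$d * diag(s_mat)) / denom
  trans <- mu_d - scl * as.vector(rot %*% mu_s)
  list(
    scale = scl, rotation = rot, translation = trans,
    apply = function(p) sweep(scl * p %*% t(rot), 2, trans, `+`)
  )
}

# Apply pose (tx, ty, scale, rotation in radians) to an n x 2 point matrix.
apply_pose <- function(points, pose) {
  ct <- cos(pose$rotation); st <- sin(pose$rotation)
  rot <- matrix(c(ct, st, -st, ct), 2, 2)
  sweep(pose$scale * points %*% t(rot), 2, c(pose$tx, pose$ty), `+`)
}

# Shoelace signed area (positive for the package's canonical ordering).
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Cumulative arc length of a polyline (closed repeats the first vertex).
arc_lengths <- function(p, closed = TRUE) {
  q <- if (closed) rbind(p, p[1, , drop = FALSE]) else p
  seg <- sqrt(rowSums(diff(q)^2))
  c(0, cumsum(seg))
}

#' Resample a polyline at fixed arc-length steps
#'
#' @param p n x 2 matrix of vertices.
#' @param step arc-length step in pixels.
#' @param closed treat `p` as a closed polygon (the duplicate endpoint is
#'   not emitted).
#' @return m x 2 matrix of points spaced `step` apart along the polyline.
#' @keywords internal
dense_resample <- function(p, step = 1, closed = TRUE) {
  q <- if (closed) rbind(p, p[1, , drop = FALSE]) else p
  s <- arc_lengths(p, closed = closed)
  total <- s[length(s)]
  if (total <= 0) stop("zero-length polyline")
  at <- seq(0, total, by = step)
  if (closed && abs(at[length(at)] - total) < 1e-12) at <- at[-length(at)]
  cbind(
    stats::approx(s, q[, 1], xout = at, rule = 2)$y,
    stats::approx(s, q[, 2], xout = at, rule = 2)$y
  )
}

# Point at a given arc-length position along a closed polygon.
point_at_arc <- function(p, at) {
  q <- rbind(p, p[1, , drop = FALSE])
  s <- arc_lengths(p, closed = TRUE)
  at <- at %% s[length(s)]
  cbind(
    stats::approx(s, q[, 1], xout = at, rule = 2)$y,
    stats::approx(s, q[, 2], xout = at, rule = 2)$y
  )
}

#' Even-odd point-in-polygon test
#'
#' @param px,py coordinates of query points.
#' @param poly n x 2 polygon vertex matrix (closed implicitly).
#' @return logical vector, TRUE for points inside.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Proper-intersection test between segment sets; used for polygon
# simplicity checks on control-point contours (O(n^2), n ~ 20-400).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || idx(j + 1L) == i || idx(i + 1L) == j) next
      if (segments_intersect(p[i, ], p[idx(i + 1L), ], p[j, ], p[idx(j + 1L), ]))
        return(FALSE)
    }
  }
  TRUE
}

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed below 2^31.
child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629
}
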