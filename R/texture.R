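# Gabor and Laws texture images and 100-element texture profiles sampled
# along contour normals (20 control points x 5 samples at offsets
# -4, -2, 0, +2, +4 px; negative offsets are inside the contour).

PROFILE_OFFSETS <- c(-4, -2, 0, 2, 4)

#' Gabor filter kernels
#'
#' Real and imaginary Gabor kernels evaluated on an integer grid centred
#' at the origin:
#' `G(x, y) = 1/(2 pi sigma^2) exp(-(x^2+y^2)/(2 sigma^2)) {cos|sin}(2 pi phi (x cos theta + y sin theta))`.
#'
#' @param sigma Gaussian envelope width in pixels (default 4).
#' @param phi spatial frequency in cycles/pixel (default 0.1).
#' @param theta orientation in radians (default 0).
#' @param size odd kernel edge length (default 25).
#' @return list with `real` and `imag` square matrices; rows index y,
#'   columns index x.
#' @export
gabor_kernel <- function(sigma = 4, phi = 0.1, theta = 0, size = 25L) {
  if (size %% 2L == 0L) stop("kernel size must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  half <- (size - 1L) %/% 2L
  g <- seq(-half, half)
  xx <- matrix(g, size, size, byrow = TRUE)   # x varies along columns
  yy <- matrix(g, size, size)                 # y varies along rows
  envelope <- exp(-(xx^2 + yy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  phase <- 2 * pi * phi * (xx * cos(theta) + yy * sin(theta))
  list(real = envelope * cos(phase), imag = envelope * sin(phase))
}

#' Gabor texture image (imaginary component)
#'
#' Convolves the image with the imaginary Gabor kernel at the requested
#' orientation (reflected border). The 0 degree response is the texture
#' feature used by the segmentation energy; other angles are available
#' for inspection.
#'
#' @param image numeric matrix.
#' @param theta_deg orientation in degrees (0, 30, 60 or 90).
#' @param sigma,phi,size kernel parameters, see [gabor_kernel()].
#' @return numeric matrix, same extent as `image`.
#' @export
gabor_texture_image <- function(image, theta_deg = 0, sigma = 4, phi = 0.1,
                                size = 25L) {
  k <- gabor_kernel(sigma = sigma, phi = phi, theta = theta_deg * pi / 180,
                    size = size)
  convolve2_reflect(image, k$imag)
}

#' Laws level-edge (E5L5) kernel
#'
#' Outer product of the edge vector E5 = (-1, -2, 0, 2, 1) with the
#' level vector L5 = (1, 4, 6, 4, 1); entries sum to zero.
#'
#' @return 5 x 5 numeric matrix.
#' @export
laws_kernel <- function() {
  outer(c(-1, -2, 0, 2, 1), c(1, 4, 6, 4, 1))
}

#' Laws texture energy image
#'
#' Convolution of the image with the E5L5 level-edge kernel (reflected
#' border); the Laws feature used by the segmentation energy.
#'
#' @param image numeric matrix.
#' @return numeric matrix, same extent as `image`.
#' @export
laws_texture_image <- function(image) {
  convolve2_reflect(image, laws_kernel())
}

#' Sample a texture profile along contour normals
#'
#' For each of the 20 control points, five bilinear samples are taken at
#' offsets -4, -2, 0, +2, +4 px along the outward normal (negative =
#' inside); the samples are concatenated point-major into a 100-vector.
#' Samples falling outside the image use the nearest border value and a
#' warning is raised.
#'
#' @param texture_image numeric matrix (e.g. from
#'   [gabor_texture_image()] or [laws_texture_image()]).
#' @param contour a 20-point contour.
#' @param offsets sample offsets along the normal.
#' @return numeric vector of length 5 x n points.
#' @export
sample_profile <- function(texture_image, contour, offsets = PROFILE_OFFSETS) {
  p <- as.matrix(contour)
  nrm <- contour_normals(p)
  xs <- as.vector(t(outer(nrm[, 1], offsets) + p[, 1]))
  ys <- as.vector(t(outer(nrm[, 2], offsets) + p[, 2]))
  if (out_of_image(texture_image, xs, ys))
    warning("profile samples outside image; nearest-border values used")
  bilinear_sample(texture_image, xs, ys)
}

# Hot-path profile sampler: no class dispatch, no warnings.
sample_profile_fast <- function(texture_image, p, nrm, offsets = PROFILE_OFFSETS) {
  xs <- as.vector(t(outer(nrm[, 1], offsets) + p[, 1]))
  ys <- as.vector(t(outer(nrm[, 2], offsets) + p[, 2]))
  bilinear_sample(texture_image, xs, ys)
}

#' Build the texture profile model from training data
#'
#' Computes the Gabor (0 degree imaginary) and Laws (E5L5) texture
#' images of every training image, samples the 100-element profile on
#' the training contour, and averages element-wise across images.
#'
#' @param images list of numeric matrices.
#' @param contours list of 20-point contours, parallel to `images`.
#' @param gabor_sigma,gabor_phi,gabor_size Gabor kernel parameters.
#' @return an `atasm_texture_model`: list with `gabor` and `laws`
#'   100-vectors and `n_training`.
#' @export
build_texture_model <- function(images, contours, gabor_sigma = 4,
                                gabor_phi = 0.1, gabor_size = 25L) {
  if (length(images) < 1L || length(images) != length(contours))
    stop("need parallel non-empty lists of images and contours")
  profs_g <- NULL; profs_l <- NULL
  for (i in seq_along(images)) {
    gi <- gabor_texture_image(images[[i]], 0, gabor_sigma, gabor_phi, gabor_size)
    li <- laws_texture_image(images[[i]])
    pg <- sample_profile(gi, contours[[i]])
    pl <- sample_profile(li, contours[[i]])
    if (is.null(profs_g)) {
      profs_g <- matrix(0, length(images), length(pg))
      profs_l <- matrix(0, length(images), length(pl))
    }
    if (length(pg) != ncol(profs_g)) stop("mixed profile lengths across training shapes")
    profs_g[i, ] <- pg
    profs_l[i, ] <- pl
  }
  structure(list(
    gabor = colMeans(profs_g),
    laws = colMeans(profs_l),
    n_training = length(images),
    gabor_sigma = gabor_sigma, gabor_phi = gabor_phi, gabor_size = gabor_size
  ), class = "atasm_texture_model")
}
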