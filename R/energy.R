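# Segmentation energy: five terms per control point (curvature, area
# gradient, line gradient, Gabor texture, Laws texture), the adaptive
# per-point weights learned from training data, and the weighted total
# that the optimizer maximizes. Sheath segmentation flips the sign of
# both gradient terms (dark interior, bright exterior).

ENERGY_TERMS <- c("curvature", "area_grad", "line_grad", "gabor", "laws")

# --- vectorized per-term internals -----------------------------------------

curvature_all <- function(p) {
  n <- nrow(p)
  ip1 <- c(2:n, 1L); im1 <- c(n, 1:(n - 1L))
  v1 <- p[ip1, , drop = FALSE] - p
  v2 <- p[im1, , drop = FALSE] - p
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  bad <- n1 == 0 | n2 == 0
  n1[bad] <- 1; n2[bad] <- 1
  ca <- rowSums(v1 * v2) / (n1 * n2)
  ang <- acos(pmin(pmax(ca, -1), 1))
  ang[bad] <- pi
  ang
}

# mean intensity of a 3x3 unit-spaced window centred (sub-pixel) at each row
# of `centers`, sampled bilinearly.
window_mean3 <- function(image, centers) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  acc <- numeric(nrow(centers))
  for (k in seq_len(nrow(off)))
    acc <- acc + bilinear_sample(image, centers[, 1] + off[k, 1], centers[, 2] + off[k, 2])
  acc / nrow(off)
}

area_grad_all <- function(image, p, nrm, sign_flip = FALSE, offset = 2) {
  inner <- window_mean3(image, p - offset * nrm)
  outer_ <- window_mean3(image, p + offset * nrm)
  v <- inner - outer_
  if (sign_flip) -v else v
}

line_grad_all <- function(image, p, nrm, sign_flip = FALSE, len = 5L) {
  inner <- numeric(nrow(p)); outer_ <- numeric(nrow(p))
  for (k in seq_len(len)) {
    inner <- inner + bilinear_sample(image, p[, 1] - k * nrm[, 1], p[, 2] - k * nrm[, 2])
    outer_ <- outer_ + bilinear_sample(image, p[, 1] + k * nrm[, 1], p[, 2] + k * nrm[, 2])
  }
  v <- (inner - outer_) / len
  if (sign_flip) -v else v
}

# per-point texture partial: -(sum over the point's 5 samples of squared
# model/test profile differences). Summing over points gives the global
# texture energy.
texture_partials <- function(model_profile, test_profile) {
  d2 <- (model_profile - test_profile)^2
  -colSums(matrix(d2, nrow = 5L))
}

# --- exported single-term operations ---------------------------------------

#' Curvature energy at one control point
#'
#' Angle (radians, in `[0, pi]`) at point `i` between the vectors to its
#' two neighbours on the closed contour; larger means straighter, which
#' the maximization prefers.
#'
#' @param contour closed contour.
#' @param i control point index (1-based).
#' @return angle in radians.
#' @export
curvature_term <- function(contour, i) {
  p <- as.matrix(contour)
  n <- nrow(p)
  v1 <- p[if (i == n) 1L else i + 1L, ] - p[i, ]
  v2 <- p[if (i == 1L) n else i - 1L, ] - p[i, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    warning("coincident neighbour points at control point ", i)
    return(pi)
  }
  acos(min(max(sum(v1 * v2) / (n1 * n2), -1), 1))
}

#' Area-gradient energy at one control point
#'
#' Mean of a 3x3 window centred 2 px inside the contour along the normal
#' minus the mean of the mirrored outside window; the sign is flipped for
#' the sheath target (dark interior).
#'
#' @param image numeric matrix.
#' @param contour closed contour.
#' @param i control point index.
#' @param target `"tendon"` (bright interior) or `"sheath"`.
#' @return intensity difference.
#' @export
area_gradient_term <- function(image, contour, i, target = c("tendon", "sheath")) {
  target <- match.arg(target)
  p <- as.matrix(contour)
  nrm <- contour_normals(p)
  as.numeric(area_grad_all(image, p[i, , drop = FALSE], nrm[i, , drop = FALSE],
                           sign_flip = target == "sheath"))
}

#' Line-gradient energy at one control point
#'
#' Mean over a 5-sample line segment along the inward normal minus the
#' mirrored outward segment (5x1 mask, unit spacing); sign flipped for
#' the sheath target.
#'
#' @inheritParams area_gradient_term
#' @return intensity difference.
#' @export
line_gradient_term <- function(image, contour, i, target = c("tendon", "sheath")) {
  target <- match.arg(target)
  p <- as.matrix(contour)
  nrm <- contour_normals(p)
  as.numeric(line_grad_all(image, p[i, , drop = FALSE], nrm[i, , drop = FALSE],
                           sign_flip = target == "sheath"))
}

#' Gabor texture energy of a contour
#'
#' Negative sum of squared differences between the trained mean Gabor
#' profile and the profile sampled on the contour. The per-point
#' contributions (each point's 5-sample partial sum) are attached as the
#' `"partials"` attribute for per-point weighting.
#'
#' @param texture_model an `atasm_texture_model`.
#' @param contour a 20-point contour.
#' @param gabor_image precomputed 0-degree imaginary Gabor texture image.
#' @return scalar energy (<= 0, 0 iff the profiles agree exactly).
#' @export
gabor_energy <- function(texture_model, contour, gabor_image) {
  prof <- sample_profile(gabor_image, contour)
  partials <- texture_partials(texture_model$gabor, prof)
  structure(sum(partials), partials = partials)
}

#' Laws texture energy of a contour
#'
#' As [gabor_energy()], with the Laws E5L5 feature.
#'
#' @param texture_model an `atasm_texture_model`.
#' @param contour a 20-point contour.
#' @param laws_image precomputed Laws texture image.
#' @return scalar energy with `"partials"` attribute.
#' @export
laws_energy <- function(texture_model, contour, laws_image) {
  prof <- sample_profile(laws_image, contour)
  partials <- texture_partials(texture_model$laws, prof)
  structure(sum(partials), partials = partials)
}

# --- full energy vector and total ------------------------------------------

# Precompute per-image quantities shared by all energy evaluations.
energy_context <- function(image, texture_model, target = "tendon") {
  list(
    image = image,
    gabor_image = gabor_texture_image(image, 0, texture_model$gabor_sigma,
                                      texture_model$gabor_phi, texture_model$gabor_size),
    laws_image = laws_texture_image(image),
    texture_model = texture_model,
    target = target
  )
}

#' Evaluate all five energy terms at every control point
#'
#' @param ctx an energy context (internal; see [segment_tendon()]) or a
#'   list with `image`, `gabor_image`, `laws_image`, `texture_model`,
#'   `target`.
#' @param contour a 20-point contour.
#' @return 5 x 20 matrix with rows `curvature`, `area_grad`,
#'   `line_grad`, `gabor`, `laws`.
#' @export
energy_vector <- function(ctx, contour) {
  energy_terms_fast(ctx, as.matrix(contour))
}

# Fast energy evaluation: normals without class dispatch, all raw-image
# samples gathered into a single bilinear lookup (hot path of the GA).
energy_terms_fast <- function(ctx, p) {
  n <- nrow(p)
  ip1 <- c(2:n, 1L); im1 <- c(n, 1:(n - 1L))
  tg <- p[ip1, , drop = FALSE] - p[im1, , drop = FALSE]
  nrm <- cbind(tg[, 2], -tg[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  ctr <- colMeans(p)
  flip_n <- rowSums(nrm * sweep(p, 2, ctr)) < 0
  nrm[flip_n, ] <- -nrm[flip_n, ]

  # curvature
  v1 <- p[ip1, , drop = FALSE] - p
  v2 <- p[im1, , drop = FALSE] - p
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  bad <- n1 == 0 | n2 == 0
  n1[bad] <- 1; n2[bad] <- 1
  curv <- acos(pmin(pmax(rowSums(v1 * v2) / (n1 * n2), -1), 1))
  curv[bad] <- pi

  # all raw-image samples in one lookup:
  # 9-point windows at +/-2 px and 5-point lines at -1..-5 / +1..+5
  offg <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  ia_x <- rep(p[, 1] - 2 * nrm[, 1], each = 9L) + offg[, 1]
  ia_y <- rep(p[, 2] - 2 * nrm[, 2], each = 9L) + offg[, 2]
  oa_x <- rep(p[, 1] + 2 * nrm[, 1], each = 9L) + offg[, 1]
  oa_y <- rep(p[, 2] + 2 * nrm[, 2], each = 9L) + offg[, 2]
  ks <- 1:5
  il_x <- rep(p[, 1], each = 5L) - ks * rep(nrm[, 1], each = 5L)
  il_y <- rep(p[, 2], each = 5L) - ks * rep(nrm[, 2], each = 5L)
  ol_x <- rep(p[, 1], each = 5L) + ks * rep(nrm[, 1], each = 5L)
  ol_y <- rep(p[, 2], each = 5L) + ks * rep(nrm[, 2], each = 5L)
  vals <- bilinear_sample(ctx$image,
                          c(ia_x, oa_x, il_x, ol_x),
                          c(ia_y, oa_y, il_y, ol_y))
  n9 <- 9L * n; n5 <- 5L * n
  ia <- colMeans(matrix(vals[seq_len(n9)], 9L))
  oa <- colMeans(matrix(vals[n9 + seq_len(n9)], 9L))
  il <- colMeans(matrix(vals[2L * n9 + seq_len(n5)], 5L))
  ol <- colMeans(matrix(vals[2L * n9 + n5 + seq_len(n5)], 5L))
  sgn <- if (identical(ctx$target, "sheath")) -1 else 1

  rbind(
    curvature = curv,
    area_grad = sgn * (ia - oa),
    line_grad = sgn * (il - ol),
    gabor = texture_partials(ctx$texture_model$gabor,
                             sample_profile_fast(ctx$gabor_image, p, nrm)),
    laws = texture_partials(ctx$texture_model$laws,
                            sample_profile_fast(ctx$laws_image, p, nrm))
  )
}

#' Weighted total energy
#'
#' The objective the optimizer maximizes: the double sum over terms and
#' control points of `w[k, i] * F[k, i]`.
#'
#' @param energy 5 x n matrix of term values.
#' @param weights 5 x n matrix of non-negative weights.
#' @return scalar.
#' @export
total_energy <- function(energy, weights) {
  if (!all(dim(energy) == dim(weights)))
    stop("energy and weight matrices must have identical dimensions")
  sum(weights * energy)
}

# --- adaptive weight training ----------------------------------------------

#' Train the adaptive per-point energy weights
#'
#' For every term k and control point i, each term is evaluated at 21
#' positions on the search line through the true boundary point (+/- 10
#' px along the outward normal, unit steps, other points held at truth).
#' With F the value at the true position, F~ the line maximum and sigma
#' the standard deviation over the line, the weight is the training-set
#' mean of `sigma * F / F~` after shifting each line by its minimum so
#' the ratio lies in `[0, 1]` (1 exactly when the true boundary is the
#' line maximum). Constant lines contribute 0.
#'
#' @param images list of training images.
#' @param contours list of ground-truth 20-point contours.
#' @param texture_model an `atasm_texture_model` built from the same
#'   training set.
#' @param target `"tendon"` or `"sheath"` (gradient sign convention).
#' @param half_range search-line half extent in pixels (default 10).
#' @param step search-line step in pixels (default 1).
#' @return an `atasm_energy_weights` object: 5 x 20 non-negative matrix
#'   with a `target` attribute.
#' @export
train_weights <- function(images, contours, texture_model,
                          target = c("tendon", "sheath"),
                          half_range = 10, step = 1) {
  target <- match.arg(target)
  if (length(images) < 1L || length(images) != length(contours))
    stop("need parallel non-empty lists of images and contours")
  offsets <- seq(-half_range, half_range, by = step)
  zero_at <- which(offsets == 0)[1]
  if (is.na(zero_at)) stop("search line must include offset 0")
  n_pts <- nrow(as.matrix(contours[[1]]))
  acc <- matrix(0, length(ENERGY_TERMS), n_pts,
                dimnames = list(ENERGY_TERMS, NULL))
  flip <- target == "sheath"
  for (t in seq_along(images)) {
    img <- images[[t]]
    gimg <- gabor_texture_image(img, 0, texture_model$gabor_sigma,
                                texture_model$gabor_phi, texture_model$gabor_size)
    limg <- laws_texture_image(img)
    p <- as.matrix(contours[[t]])
    nrm <- contour_normals(p)
    n <- nrow(p)
    ip1 <- c(2:n, 1L); im1 <- c(n, 1:(n - 1L))
    for (i in seq_len(n)) {
      disp <- cbind(p[i, 1] + offsets * nrm[i, 1],
                    p[i, 2] + offsets * nrm[i, 2])
      nrep <- matrix(nrm[i, ], nrow(disp), 2, byrow = TRUE)
      # curvature with neighbours fixed
      v1 <- sweep(-disp, 2, p[ip1[i], ], `+`)
      v2 <- sweep(-disp, 2, p[im1[i], ], `+`)
      n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
      n1[n1 == 0] <- 1; n2[n2 == 0] <- 1
      line_vals <- matrix(0, length(ENERGY_TERMS), nrow(disp),
                          dimnames = list(ENERGY_TERMS, NULL))
      line_vals["curvature", ] <- acos(pmin(pmax(rowSums(v1 * v2) / (n1 * n2), -1), 1))
      line_vals["area_grad", ] <- area_grad_all(img, disp, nrep, flip)
      line_vals["line_grad", ] <- line_grad_all(img, disp, nrep, flip)
      mg <- texture_model$gabor[(i - 1L) * 5L + 1:5]
      ml <- texture_model$laws[(i - 1L) * 5L + 1:5]
      for (j in seq_len(nrow(disp))) {
        sx <- disp[j, 1] + PROFILE_OFFSETS * nrm[i, 1]
        sy <- disp[j, 2] + PROFILE_OFFSETS * nrm[i, 2]
        line_vals["gabor", j] <- -sum((mg - bilinear_sample(gimg, sx, sy))^2)
        line_vals["laws", j] <- -sum((ml - bilinear_sample(limg, sx, sy))^2)
      }
      for (k in seq_len(nrow(line_vals))) {
        vals <- line_vals[k, ]
        s <- stats::sd(vals)
        lo <- min(vals); hi <- max(vals)
        if (!is.finite(s) || hi - lo <= 0) next   # constant line: weight 0
        ratio <- (vals[zero_at] - lo) / (hi - lo)
        acc[k, i] <- acc[k, i] + max(0, s * ratio)
      }
    }
  }
  w <- acc / length(images)
  structure(w, target = target, class = c("atasm_energy_weights", class(w)))
}
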