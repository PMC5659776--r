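# Point distribution model: generalized Procrustes alignment, PCA over
# aligned 40-vectors (x, y interleaved), shape synthesis X = Xbar + P b
# followed by a similarity pose, and +/- 3 sqrt(lambda) parameter clamps.

shape_to_vec <- function(p) as.vector(t(as.matrix(p)))
vec_to_shape <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

normalize_shape <- function(p) {
  p <- sweep(p, 2, colMeans(p))
  rms <- sqrt(mean(rowSums(p^2)))
  if (rms < .Machine$double.eps) stop("degenerate shape: all points coincident")
  p / rms
}

#' Generalized Procrustes alignment of corresponding shapes
#'
#' Iteratively similarity-aligns every shape (translation, scale,
#' rotation) to the re-estimated mean, which is normalized to centroid
#' zero and unit RMS scale.
#'
#' @param shapes list of n x 2 matrices with corresponding rows.
#' @param max_iter iteration cap (default 10).
#' @param tol RMS change of the mean shape for convergence (default 1e-7).
#' @return list with `aligned` (list of n x 2 matrices), `mean_shape`
#'   (n x 2, centroid 0, unit RMS), `scale_hint` (mean centred RMS size of
#'   the input shapes, used to place a model-space shape back at image
#'   scale), and `iterations`.
#' @export
procrustes_align <- function(shapes, max_iter = 10L, tol = 1e-7) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  shapes <- lapply(shapes, as.matrix)
  n <- nrow(shapes[[1]])
  if (any(vapply(shapes, nrow, 1L) != n)) stop("shapes must have equal point counts")
  sizes <- vapply(shapes, function(p) {
    pc <- sweep(p, 2, colMeans(p))
    sqrt(mean(rowSums(pc^2)))
  }, 1.0)
  if (any(sizes < .Machine$double.eps)) stop("degenerate shape: all points coincident")
  aligned <- lapply(shapes, normalize_shape)
  mean_shape <- aligned[[1]]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    aligned <- lapply(aligned, function(p) fit_similarity(p, mean_shape)$apply(p))
    new_mean <- normalize_shape(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean(rowSums((new_mean - mean_shape)^2)))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  list(aligned = aligned, mean_shape = mean_shape,
       scale_hint = mean(sizes), iterations = iterations)
}

#' Fit the PCA point distribution model
#'
#' Eigendecomposition of the covariance of aligned shape vectors; the
#' retained modes cover `var_retain` of total variance, capped at
#' (number of shapes - 1).
#'
#' @param aligned list of aligned n x 2 shapes (e.g. from
#'   [procrustes_align()]).
#' @param var_retain fraction of variance to retain (default 0.98).
#' @param scale_hint optional image-scale hint stored on the model.
#' @return an object of class `atasm_shape_model` with elements
#'   `mean_shape` (2n vector, x/y interleaved), `modes` (2n x m),
#'   `eigenvalues` (length m, non-increasing), `n_training`, `var_retain`.
#' @export
fit_pca <- function(aligned, var_retain = 0.98, scale_hint = NULL) {
  if (length(aligned) < 2L) stop("need at least 2 aligned shapes")
  x <- t(vapply(aligned, shape_to_vec, numeric(2L * nrow(aligned[[1]]))))
  mu <- colMeans(x)
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total <- sum(lambda)
  cap <- nrow(x) - 1L
  if (total <= 1e-12 * max(1, ncol(x))) {
    m <- 0L
  } else {
    m <- which(cumsum(lambda) / total >= var_retain)[1]
    m <- min(m, cap)
  }
  modes <- eg$vectors[, seq_len(m), drop = FALSE]
  structure(list(
    mean_shape = mu,
    modes = modes,
    eigenvalues = lambda[seq_len(m)],
    all_eigenvalues = lambda,
    n_training = nrow(x),
    var_retain = var_retain,
    scale_hint = scale_hint
  ), class = "atasm_shape_model")
}

#' @export
print.atasm_shape_model <- function(x, ...) {
  cat("Point distribution model:", length(x$mean_shape) / 2, "landmarks,",
      length(x$eigenvalues), "modes from", x$n_training, "training shapes\n")
  invisible(x)
}

#' Default (identity) pose
#'
#' @param tx,ty translation in pixels.
#' @param scale isotropic scale.
#' @param rotation rotation in radians.
#' @export
shape_pose <- function(tx = 0, ty = 0, scale = 1, rotation = 0) {
  list(tx = tx, ty = ty, scale = scale, rotation = rotation)
}

#' Clamp shape parameters to the model's deformation bounds
#'
#' Each mode weight b_i is clipped into +/- 3 sqrt(lambda_i) (three
#' standard deviations of the training distribution). Modes with zero
#' eigenvalue force b_i = 0.
#'
#' @param b numeric vector of mode weights.
#' @param model an `atasm_shape_model`.
#' @param sqrt_lambda if FALSE, use the bound 3 lambda_i instead of
#'   3 sqrt(lambda_i) (strict-print mode; not recommended).
#' @return clamped copy of `b`.
#' @export
clamp_shape_params <- function(b, model, sqrt_lambda = TRUE) {
  lim <- shape_param_bounds(model, sqrt_lambda)
  pmin(pmax(b, -lim), lim)
}

#' Deformation bounds of a shape model
#'
#' @param model an `atasm_shape_model`.
#' @param sqrt_lambda use 3 sqrt(lambda) bounds (default) or 3 lambda.
#' @return vector of non-negative per-mode bounds.
#' @export
shape_param_bounds <- function(model, sqrt_lambda = TRUE) {
  if (sqrt_lambda) 3 * sqrt(model$eigenvalues) else 3 * model$eigenvalues
}

#' Synthesize a contour from shape parameters and pose
#'
#' Computes X = Xbar + P b in model space, then applies the similarity
#' pose (scale, rotation, translation). Out-of-bound mode weights are
#' clamped first, so synthesized shapes always stay inside the model.
#'
#' @param model an `atasm_shape_model`.
#' @param b mode weights (length = retained modes; may be empty).
#' @param pose a pose from [shape_pose()].
#' @return an `atasm_contour`.
#' @export
synthesize_shape <- function(model, b = numeric(length(model$eigenvalues)),
                             pose = shape_pose()) {
  m <- length(model$eigenvalues)
  if (length(b) != m) stop("b must have length ", m)
  b <- clamp_shape_params(b, model)
  v <- model$mean_shape
  if (m > 0L) v <- v + as.vector(model$modes %*% b)
  as_contour(apply_pose(vec_to_shape(v), pose))
}

#' Project a contour into the model (inverse of synthesis)
#'
#' Estimates the similarity pose aligning the model mean to the contour,
#' then the least-squares mode weights of the residual.
#'
#' @param model an `atasm_shape_model`.
#' @param contour n x 2 contour with model-corresponding points.
#' @param clamp clamp the recovered weights to the model bounds.
#' @return list with `b` and `pose`.
#' @export
project_shape <- function(model, contour, clamp = TRUE) {
  p <- as.matrix(contour)
  mu <- vec_to_shape(model$mean_shape)
  tf <- fit_similarity(mu, p)
  ang <- atan2(tf$rotation[2, 1], tf$rotation[1, 1])
  pose <- shape_pose(tf$translation[1], tf$translation[2], tf$scale, ang)
  # pull the contour back into model space
  inv_rot <- t(tf$rotation)
  q <- sweep(p, 2, tf$translation) %*% t(inv_rot) / tf$scale
  resid <- shape_to_vec(q) - model$mean_shape
  b <- as.vector(crossprod(model$modes, resid))
  if (clamp) b <- clamp_shape_params(b, model)
  list(b = b, pose = pose)
}
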