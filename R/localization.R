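# Tendon localization: averaged intensity template trained from aligned
# images, coarse block search by sum of absolute differences (SAD) at
# half resolution, Powell-refined similarity transform at full
# resolution, and a manual ROI override for the special cases where
# template matching is not applicable.

#' Train the averaged intensity template
#'
#' The template crop is the reference tendon's bounding box expanded by
#' `margin` per side. Every other training image is warped by the
#' similarity transform mapping its contour onto the reference contour,
#' and the template is the per-pixel (coverage-weighted) mean of the
#' aligned images.
#'
#' @param images list of training images.
#' @param contours list of 20-point tendon contours, parallel to `images`.
#' @param reference index of the reference training image (default 1).
#' @param margin crop margin as a fraction of the tendon bounding box
#'   per side (default 0.4).
#' @return an `atasm_template`: list with `pixels`, `reference_contour`
#'   (template coordinates), `origin` (crop origin in the reference
#'   image) and `n_training`.
#' @export
train_template <- function(images, contours, reference = 1L, margin = 0.4) {
  if (length(images) < 1L || length(images) != length(contours))
    stop("need parallel non-empty lists of images and contours")
  ref_img <- images[[reference]]
  ref_ct <- as.matrix(contours[[reference]])
  bx <- range(ref_ct[, 1]); by <- range(ref_ct[, 2])
  mx <- margin * diff(bx); my <- margin * diff(by)
  x0 <- max(1L, floor(bx[1] - mx)); x1 <- min(ncol(ref_img), ceiling(bx[2] + mx))
  y0 <- max(1L, floor(by[1] - my)); y1 <- min(nrow(ref_img), ceiling(by[2] + my))
  xs <- x0:x1; ys <- y0:y1
  acc <- matrix(0, length(ys), length(xs))
  cov_n <- matrix(0, length(ys), length(xs))
  grid_x <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  grid_y <- matrix(ys, length(ys), length(xs))
  for (t in seq_along(images)) {
    if (t == reference) {
      acc <- acc + ref_img[ys, xs]
      cov_n <- cov_n + 1
      next
    }
    # transform mapping the training contour onto the reference contour;
    # pull template pixels back through its inverse into the source image
    tf <- fit_similarity(as.matrix(contours[[t]]), ref_ct)
    inv_rot <- t(tf$rotation)
    dx <- as.vector(grid_x) - tf$translation[1]
    dy <- as.vector(grid_y) - tf$translation[2]
    src <- cbind(dx, dy) %*% t(inv_rot) / tf$scale
    img <- images[[t]]
    ok <- src[, 1] >= 1 & src[, 1] <= ncol(img) & src[, 2] >= 1 & src[, 2] <= nrow(img)
    vals <- bilinear_sample(img, src[, 1], src[, 2])
    vals[!ok] <- 0
    acc <- acc + matrix(vals, nrow(acc))
    cov_n <- cov_n + matrix(as.numeric(ok), nrow(acc))
  }
  if (any(cov_n == 0)) warning("template pixels never covered by any training image")
  pixels <- acc / pmax(cov_n, 1)
  structure(list(
    pixels = pixels,
    reference_contour = as_contour(cbind(ref_ct[, 1] - x0 + 1, ref_ct[, 2] - y0 + 1)),
    origin = c(x = x0, y = y0),
    n_training = length(images)
  ), class = "atasm_template")
}

#' Mean absolute intensity difference between two equal-size blocks
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return scalar SAD value (mean over pixels).
#' @export
sad <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("SAD requires equal block dimensions")
  mean(abs(a - b))
}

# 2x2-mean downsampling (odd trailing row/column dropped).
downsample2 <- function(img) {
  nr <- nrow(img) - nrow(img) %% 2L
  nc <- ncol(img) - ncol(img) %% 2L
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  (x[seq(1, nr, 2), seq(1, nc, 2)] + x[seq(2, nr, 2), seq(1, nc, 2)] +
     x[seq(1, nr, 2), seq(2, nc, 2)] + x[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

#' Coarse template localization by block SAD at half resolution
#'
#' Image and template are downsampled by 2x2 means; template-size
#' maximally overlapping blocks (every half-resolution position) are
#' scanned and the origin of the minimum-SAD block (ties: smallest row,
#' then column) is returned at full resolution. The reported stride is
#' the 2 px full-resolution quantization of the half-resolution scan.
#'
#' @param image numeric matrix.
#' @param template an `atasm_template` (or plain matrix).
#' @return list with `origin` (full-resolution c(x, y) of the block's
#'   top-left corner), `sad` (minimum half-resolution SAD) and `stride`
#'   (full-resolution stride used).
#' @export
coarse_locate <- function(image, template) {
  tpl <- if (inherits(template, "atasm_template")) template$pixels else template
  img2 <- downsample2(image)
  tpl2 <- downsample2(tpl)
  h <- nrow(tpl2); w <- ncol(tpl2)
  if (h > nrow(img2) || w > ncol(img2)) stop("template larger than image at half resolution")
  # maximally overlapping blocks: every half-resolution position is
  # evaluated (the SAD valley of a high-contrast averaged template is
  # narrower than any coarse block stride, so subsampled grids can lose
  # the true position to a background block)
  best <- Inf; best_rc <- c(1L, 1L)
  for (r in seq_len(nrow(img2) - h + 1L)) {
    strip <- img2[r:(r + h - 1L), , drop = FALSE]
    for (cc in seq_len(ncol(img2) - w + 1L)) {
      v <- sum(abs(strip[, cc:(cc + w - 1L)] - tpl2))
      if (v < best) { best <- v; best_rc <- c(r, cc) }
    }
  }
  best <- best / (h * w)
  list(origin = c(x = 2L * (best_rc[2] - 1L) + 1L, y = 2L * (best_rc[1] - 1L) + 1L),
       sad = best, stride = c(x = 2L, y = 2L))
}

# Map template coordinates into the image through a similarity transform
# anchored at the template centre placed at `origin`.
template_transform <- function(template, origin, par) {
  ctr <- c((1 + ncol(template$pixels)) / 2, (1 + nrow(template$pixels)) / 2)
  shift <- c(origin[1] - 1, origin[2] - 1)
  function(p) {
    ct <- cos(par[4]); st <- sin(par[4])
    rot <- matrix(c(ct, st, -st, ct), 2, 2)
    q <- sweep(as.matrix(p), 2, ctr) %*% t(rot) * par[3]
    sweep(q, 2, ctr + shift + par[1:2], `+`)
  }
}

#' Fine template localization by Powell-refined similarity matching
#'
#' Starting from the coarse origin (scale 1, rotation 0), minimizes the
#' SAD between the similarity-transformed template and the full
#' resolution image over translation, scale and rotation with Powell's
#' method, and maps the template's reference contour through the result
#' to give the initial segmentation contour.
#'
#' @param image numeric matrix.
#' @param template an `atasm_template`.
#' @param origin coarse block origin, c(x, y) (e.g. from
#'   [coarse_locate()]).
#' @param ftol Powell tolerance (default 1e-4).
#' @return list with `tx`, `ty`, `scale`, `rotation` (translation is the
#'   residual shift relative to `origin`), `sad`, `contour` (the mapped
#'   reference contour), `converged`, and `apply` (the template-to-image
#'   coordinate map).
#' @export
fine_locate <- function(image, template, origin, ftol = 1e-4) {
  tpl <- template$pixels
  grid <- cbind(
    rep(seq_len(ncol(tpl)), each = nrow(tpl)),
    rep(seq_len(nrow(tpl)), times = ncol(tpl))
  )
  tpl_vals <- as.vector(tpl)
  obj <- function(par) {
    if (par[3] <= 0.1) return(Inf)
    tf <- template_transform(template, origin, par)
    q <- tf(grid)
    mean(abs(bilinear_sample(image, q[, 1], q[, 2]) - tpl_vals))
  }
  res <- powell_minimize(obj, c(0, 0, 1, 0), ftol = ftol, maxit = 50L,
                         step = c(2, 2, 0.02, 0.02))
  tf <- template_transform(template, origin, res$par)
  ref <- as.matrix(template$reference_contour)
  list(tx = res$par[1], ty = res$par[2], scale = res$par[3],
       rotation = res$par[4], sad = res$value,
       contour = as_contour(tf(ref)), converged = res$converged, apply = tf)
}

#' Manually supplied region of interest as localization override
#'
#' Maps the template's reference contour affinely onto a user-supplied
#' box, bypassing coarse/fine template matching (used for images with
#' little synovial sheath or multiple tendons).
#'
#' @param template an `atasm_template`.
#' @param box numeric c(x, y, w, h): top-left corner and size in pixels.
#' @return an `atasm_contour`, the reference contour fitted to the box.
#' @export
manual_roi_override <- function(template, box) {
  if (length(box) != 4L || box[3] <= 0 || box[4] <= 0)
    stop("ROI box must be c(x, y, w, h) with positive size")
  ref <- as.matrix(template$reference_contour)
  bx <- range(ref[, 1]); by <- range(ref[, 2])
  if (diff(bx) <= 0 || diff(by) <= 0) stop("degenerate reference contour")
  as_contour(cbind(
    (ref[, 1] - bx[1]) / diff(bx) * box[3] + box[1],
    (ref[, 2] - by[1]) / diff(by) * box[4] + box[2]
  ))
}
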