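# End-to-end segmentation: model training (shape + texture + weights +
# template per target), tendon segmentation (localization, then
# alternating pose refinement and GA shape optimization of the weighted
# energy), synovial sheath segmentation initialized from the tendon, and
# sheath post-processing (lower boundary from the tendon's bottom arc,
# parabolic closure of the invisible sides), plus the clear/fuzzy
# bottom-boundary grouping rule.

#' Train a complete segmentation model
#'
#' Builds, for the tendon (and optionally the sheath), the point
#' distribution model, the Gabor/Laws texture profile model, the
#' adaptive energy weights and — for the tendon — the averaged intensity
#' template used for localization.
#'
#' @param images list of training images.
#' @param tendon_contours list of 20-point ground-truth tendon contours.
#' @param sheath_contours optional list of sheath contours.
#' @param var_retain PCA variance fraction retained.
#' @param reference index of the template reference image.
#' @param gabor_sigma,gabor_phi,gabor_size Gabor kernel parameters.
#' @return an `atasm_model` with elements `tendon` and (optionally)
#'   `sheath`, each holding `shape`, `texture`, `weights` and, for the
#'   tendon, `template`.
#' @export
train_atasm <- function(images, tendon_contours, sheath_contours = NULL,
                        var_retain = 0.98, reference = 1L,
                        gabor_sigma = 4, gabor_phi = 0.1, gabor_size = 25L) {
  train_target <- function(contours, target, with_template) {
    ga <- procrustes_align(lapply(contours, as.matrix))
    shape <- fit_pca(ga$aligned, var_retain = var_retain,
                     scale_hint = ga$scale_hint)
    texture <- build_texture_model(images, contours, gabor_sigma, gabor_phi,
                                   gabor_size)
    weights <- train_weights(images, contours, texture, target = target)
    out <- list(shape = shape, texture = texture, weights = weights)
    if (with_template)
      out$template <- train_template(images, contours, reference = reference)
    out
  }
  model <- list(tendon = train_target(tendon_contours, "tendon", TRUE))
  if (!is.null(sheath_contours))
    model$sheath <- train_target(sheath_contours, "sheath", FALSE)
  structure(model, class = "atasm_model")
}

#' @export
print.atasm_model <- function(x, ...) {
  cat("ATASM model; targets:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# Alternate pose refinement (Powell) and GA shape optimization of the
# weighted energy until the joint energy change is small.
optimize_shape <- function(ctx, shape, weights, pose0, seed = NULL,
                           ga_cfg = ga_config(), max_rounds = 5L,
                           rel_tol = 1e-4) {
  bounds <- shape_param_bounds(shape)
  b <- numeric(length(bounds))
  pose <- pose0
  history <- list()
  mu <- shape$mean_shape
  modes <- shape$modes
  w <- unclass(weights)
  energy_of <- function(b, pose) {
    v <- mu
    if (length(b) > 0L) v <- v + as.vector(modes %*% b)
    p <- apply_pose(vec_to_shape(v), pose)
    sum(w * energy_terms_fast(ctx, p))
  }
  last <- energy_of(b, pose)
  # the localization (or manual ROI) supplies the initial pose step, so
  # each round runs the GA shape search first and then re-refines pose
  run <- function() {
    for (round in seq_len(max_rounds)) {
      if (length(bounds) > 0L) {
        fitness <- function(bb) energy_of(bb, pose)
        ga <- ga_maximize(fitness, -bounds, bounds, ga_cfg)
        b <<- ga$par
        history[[round]] <<- ga$history
      }
      pr <- refine_pose(ctx, shape, weights, b, pose)
      pose <<- pr$pose
      current <- pr$value
      if (abs(current - last) <= rel_tol * (abs(last) + 1e-12)) {
        last <<- current
        break
      }
      last <<- current
    }
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
  list(b = b, pose = pose, energy = last, ga_history = history)
}

#' Segment the flexor tendon
#'
#' Localizes the tendon (coarse block SAD at half resolution, then a
#' Powell-refined similarity transform; or a manual ROI), then
#' alternates pose refinement with GA maximization of the weighted
#' five-term energy over the shape parameters.
#'
#' @param image numeric matrix.
#' @param model an `atasm_model` (with a trained tendon target).
#' @param roi optional manual ROI box c(x, y, w, h) bypassing template
#'   matching.
#' @param seed RNG seed controlling the GA (fixed seed + fixed inputs
#'   give an identical result).
#' @param ga_cfg GA settings ([ga_config()]).
#' @param max_rounds pose/shape alternation cap (default 5).
#' @param sad_ceiling localization SAD above which the result is flagged
#'   low-confidence.
#' @return list with `contour`, `b`, `pose`, `energy`, `localization`,
#'   `low_confidence`, `ga_history`.
#' @export
segment_tendon <- function(image, model, roi = NULL, seed = 1L,
                           ga_cfg = ga_config(), max_rounds = 5L,
                           sad_ceiling = 60) {
  tm <- model$tendon
  ctx <- energy_context(image, tm$texture, "tendon")
  low_conf <- FALSE
  if (is.null(roi)) {
    coarse <- coarse_locate(image, tm$template)
    fine <- fine_locate(image, tm$template, coarse$origin)
    init_contour <- fine$contour
    localization <- list(coarse = coarse, fine = fine)
    if (fine$sad > sad_ceiling) low_conf <- TRUE
  } else {
    init_contour <- manual_roi_override(tm$template, roi)
    localization <- list(manual_roi = roi)
  }
  init <- project_shape(tm$shape, init_contour)
  opt <- optimize_shape(ctx, tm$shape, tm$weights, init$pose, seed = seed,
                        ga_cfg = ga_cfg, max_rounds = max_rounds)
  list(
    contour = synthesize_shape(tm$shape, opt$b, opt$pose),
    b = opt$b, pose = opt$pose, energy = opt$energy,
    localization = localization, low_confidence = low_conf,
    ga_history = opt$ga_history
  )
}

#' Segment the synovial sheath
#'
#' The sheath model is initialized centred on the segmented tendon
#' (their centres nearly coincide anatomically), optimized with the
#' sign-flipped gradient energies, and post-processed: the lower sheath
#' boundary is the tendon's bottom arc (within 30 degrees of the
#' downward vertical) and the invisible sides are closed with two
#' parabolas.
#'
#' @param image numeric matrix.
#' @param tendon_result result of [segment_tendon()] (or a list with a
#'   `contour`).
#' @param model an `atasm_model` with a trained `sheath` target.
#' @param seed,ga_cfg,max_rounds as in [segment_tendon()].
#' @return list with `tendon`, `sheath` (the raw optimized sheath
#'   contour), `sheath_upper`, `sheath_lower` (open polylines),
#'   `sheath_closed` (closed polyline), `group`
#'   (clear/fuzzy bottom-boundary label), `energy`, `b`, `pose`.
#' @export
segment_sheath <- function(image, tendon_result, model, seed = 1L,
                           ga_cfg = ga_config(), max_rounds = 5L) {
  if (is.null(model$sheath)) stop("model has no trained sheath target")
  sm <- model$sheath
  ctx <- energy_context(image, sm$texture, "sheath")
  tendon <- tendon_result$contour
  ctr <- contour_centroid(tendon)
  pose0 <- shape_pose(ctr[1], ctr[2], sm$shape$scale_hint, 0)
  opt <- optimize_shape(ctx, sm$shape, sm$weights, pose0, seed = seed,
                        ga_cfg = ga_cfg, max_rounds = max_rounds)
  sheath <- synthesize_shape(sm$shape, opt$b, opt$pose)
  upper <- upper_arc(as.matrix(sheath))
  lower <- lower_sheath_from_tendon(tendon)
  closed <- close_sheath(upper, lower)
  grp <- classify_boundary_group(image, tendon)
  list(
    tendon = tendon, sheath = sheath,
    sheath_upper = upper, sheath_lower = lower, sheath_closed = closed,
    group = grp$label, window_contrast = grp$window_contrast,
    energy = opt$energy, b = opt$b, pose = opt$pose
  )
}

#' Upper arc of a closed contour
#'
#' Densely resamples the contour, splits it at its leftmost and
#' rightmost points and keeps the arc containing the topmost point;
#' used both to take the upper boundary of the optimized sheath contour
#' and to derive the matching ground-truth arc of a phantom.
#'
#' @param contour closed contour or polygon matrix.
#' @param step dense resampling step in pixels.
#' @return open polyline (m x 2).
#' @export
upper_arc <- function(contour, step = 1) {
  d <- dense_resample(as.matrix(contour), step = step, closed = TRUE)
  i_l <- which.min(d[, 1]); i_r <- which.max(d[, 1])
  n <- nrow(d)
  lo <- min(i_l, i_r); hi <- max(i_l, i_r)
  arc1 <- d[lo:hi, , drop = FALSE]
  arc2 <- d[c(hi:n, 1:lo), , drop = FALSE]
  if (min(arc1[, 2]) <= min(arc2[, 2])) arc1 else arc2
}

#' Lower sheath boundary from the tendon contour
#'
#' The arc of the densely resampled tendon boundary whose direction from
#' the tendon centroid lies strictly within 30 degrees of the downward
#' vertical; anatomically the sheath sits on the volar plate here, so
#' the tendon and sheath boundaries coincide.
#'
#' @param tendon closed tendon contour.
#' @param max_angle_deg half-angle of the arc (default 30).
#' @param step dense resampling step in pixels.
#' @return open polyline (m x 2), ordered by increasing x.
#' @export
lower_sheath_from_tendon <- function(tendon, max_angle_deg = 30, step = 1) {
  d <- dense_resample(as.matrix(tendon), step = step, closed = TRUE)
  ctr <- colMeans(d)
  dx <- d[, 1] - ctr[1]; dy <- d[, 2] - ctr[2]
  ang <- abs(atan2(dx, dy))        # deviation from the +y (downward) axis
  keep <- ang < max_angle_deg * pi / 180
  if (!any(keep)) stop("degenerate tendon: empty lower arc")
  arc <- d[keep, , drop = FALSE]
  arc[order(arc[, 1]), , drop = FALSE]
}

# Parabola x = a y^2 + b y + c through (xu, yu) and (xl, yl) with slope
# dx/dy = s at yu; sampled at 1 px y-steps.
parabola_side <- function(up, low, slope, step = 1) {
  up <- unname(up); low <- unname(low)
  yu <- up[2]; yl <- low[2]
  if (abs(yl - yu) < 1e-9) {
    return(rbind(up, low))
  }
  m <- rbind(c(yu^2, yu, 1), c(yl^2, yl, 1), c(2 * yu, 1, 0))
  coef <- solve(m, c(up[1], low[1], slope))
  ys <- seq(yu, yl, by = if (yl > yu) step else -step)
  if (ys[length(ys)] != yl) ys <- c(ys, yl)
  cbind(coef[1] * ys^2 + coef[2] * ys + coef[3], ys, deparse.level = 0)
}

#' Close the sheath boundary with two parabolas
#'
#' Connects each end of the upper sheath boundary to the matching end of
#' the lower boundary with a second-order curve `x = a y^2 + b y + c`
#' constrained by the two endpoints and tangent continuity with the
#' upper boundary at its endpoint. Falls back to straight segments if
#' the closed polyline self-intersects.
#'
#' @param upper open upper sheath polyline (ordered by increasing x
#'   along the arc ends).
#' @param lower open lower sheath polyline (ordered by increasing x).
#' @param step parabola sampling step in y (default 1 px).
#' @return closed polyline (m x 2 matrix) with attribute `fallback`
#'   (TRUE when straight-line closure was used).
#' @export
close_sheath <- function(upper, lower, step = 1) {
  upper <- as.matrix(upper); lower <- as.matrix(lower)
  if (nrow(upper) < 2L || nrow(lower) < 2L) stop("need >= 2 points per boundary")
  # orient the upper arc left to right
  if (upper[1, 1] > upper[nrow(upper), 1]) upper <- upper[rev(seq_len(nrow(upper))), ]
  if (lower[1, 1] > lower[nrow(lower), 1]) lower <- lower[rev(seq_len(nrow(lower))), ]
  u_l <- upper[1, ]; u_r <- upper[nrow(upper), ]
  l_l <- lower[1, ]; l_r <- lower[nrow(lower), ]
  slope_at <- function(p1, p2) {
    if (abs(p2[2] - p1[2]) < 1e-9) 0 else (p2[1] - p1[1]) / (p2[2] - p1[2])
  }
  s_l <- slope_at(upper[2, ], upper[1, ])
  s_r <- slope_at(upper[nrow(upper) - 1L, ], upper[nrow(upper), ])
  right_par <- parabola_side(u_r, l_r, s_r, step)
  left_par <- parabola_side(u_l, l_l, s_l, step)
  closed <- rbind(
    upper,
    right_par[-1, , drop = FALSE],
    lower[rev(seq_len(nrow(lower)))[-1], , drop = FALSE],
    left_par[rev(seq_len(nrow(left_par)))[-1], , drop = FALSE]
  )
  closed <- closed[-nrow(closed), , drop = FALSE]
  fallback <- FALSE
  if (!polygon_is_simple(closed[seq(1, nrow(closed), by = 4), , drop = FALSE])) {
    fallback <- TRUE
    closed <- rbind(upper, lower[rev(seq_len(nrow(lower))), , drop = FALSE])
  }
  structure(closed, fallback = fallback)
}

#' Clear vs fuzzy bottom-boundary grouping
#'
#' Compares the mean intensities of two 15 x 15 windows centred 8 px
#' above and below the tendon's bottom-most boundary point; the image is
#' labelled `clear` iff the window above is brighter by strictly more
#' than 30 intensity units.
#'
#' @param image numeric matrix.
#' @param tendon tendon contour (the detected one at inference time).
#' @param window window edge length (default 15).
#' @param gap distance from the boundary point to each window centre
#'   (default 8 px).
#' @param threshold intensity difference threshold (default 30).
#' @return list with `label` (`"clear"`/`"fuzzy"`), `window_contrast`
#'   and `bottom_point`.
#' @export
classify_boundary_group <- function(image, tendon, window = 15L, gap = 8,
                                    threshold = 30) {
  d <- dense_resample(as.matrix(tendon), step = 1, closed = TRUE)
  bottom <- d[which.max(d[, 2]), ]
  half <- (window - 1L) %/% 2L
  win_mean <- function(cy) {
    xs <- round(bottom[1]) + (-half:half)
    ys <- round(cy) + (-half:half)
    cl <- xs < 1 | xs > ncol(image)
    rw <- ys < 1 | ys > nrow(image)
    if (any(cl) || any(rw)) warning("grouping window clipped at image border")
    mean(image[ys[!rw], xs[!cl]])
  }
  contrast <- win_mean(bottom[2] - gap) - win_mean(bottom[2] + gap)
  list(label = if (contrast > threshold) "clear" else "fuzzy",
       window_contrast = contrast, bottom_point = bottom)
}
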