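# Seeded synthetic ultrasound phantoms: a hyperechoic elliptical tendon
# with low-order boundary perturbations, a hypoechoic synovial-fluid
# band around it, a bright volar-plate band beneath, multiplicative
# speckle, and a controllable bottom-boundary contrast (clear vs fuzzy).
# Ground-truth tendon/sheath contours are returned with every image, so
# the whole segmentation and classification pipeline can be exercised
# without clinical data.

#' Phantom specification
#'
#' Defaults emulate a transverse A1-pulley scan: image 200 x 160 px,
#' tendon semi-axes 42 x 26 px (a few millimetres at 0.075 mm/px), a
#' 12 px synovial band, and speckle contrast 0.25.
#'
#' @param width,height image size in pixels.
#' @param center tendon centre c(x, y).
#' @param semi_axes tendon ellipse semi-axes c(a, b) in pixels.
#' @param sheath_width synovial band width in pixels.
#' @param tendon_intensity,sheath_intensity,background_intensity,plate_intensity
#'   region intensities in `[0, 255]`.
#' @param plate_offset,plate_thickness volar-plate band placement below
#'   the sheath, in pixels.
#' @param bottom_contrast `"clear"` (tendon/below step > 30) or
#'   `"fuzzy"` (step <= 30 with a smooth blend).
#' @param fuzzy_below_intensity intensity filling the band below the
#'   tendon in fuzzy mode.
#' @param speckle_scale multiplicative speckle contrast (0 disables).
#' @param perturb_sd standard deviation of the two radial
#'   boundary-perturbation mode amplitudes (fraction of the semi-axis).
#' @param perturb_amplitudes fixed mode amplitudes c(a2, a3) used
#'   instead of drawing from `perturb_sd` when non-NULL.
#' @param center_jitter uniform +/- jitter of the tendon centre in px.
#' @param rng_seed seed for speckle, amplitudes and jitter.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width = 200L, height = 160L, center = c(100, 80),
                         semi_axes = c(42, 26), sheath_width = 12,
                         tendon_intensity = 150, sheath_intensity = 60,
                         background_intensity = 100, plate_intensity = 200,
                         plate_offset = 2, plate_thickness = 12,
                         bottom_contrast = c("clear", "fuzzy"),
                         fuzzy_below_intensity = 135,
                         speckle_scale = 0.25, perturb_sd = 0.05,
                         perturb_amplitudes = NULL, center_jitter = 0,
                         rng_seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               center = center, semi_axes = semi_axes,
               sheath_width = sheath_width,
               tendon_intensity = tendon_intensity,
               sheath_intensity = sheath_intensity,
               background_intensity = background_intensity,
               plate_intensity = plate_intensity,
               plate_offset = plate_offset, plate_thickness = plate_thickness,
               bottom_contrast = match.arg(bottom_contrast),
               fuzzy_below_intensity = fuzzy_below_intensity,
               speckle_scale = speckle_scale, perturb_sd = perturb_sd,
               perturb_amplitudes = perturb_amplitudes,
               center_jitter = center_jitter, rng_seed = rng_seed)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  margin <- 12
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  w <- spec$sheath_width
  jit <- spec$center_jitter
  ok_x <- spec$center[1] - a - w - jit >= margin &&
    spec$center[1] + a + w + jit <= spec$width - margin
  ok_y <- spec$center[2] - b - w - jit >= margin &&
    spec$center[2] + b + w + jit <= spec$height - margin
  if (!ok_x || !ok_y)
    stop("phantom spec invalid: tendon + sheath must stay >= 12 px inside the image")
  ints <- c(spec$tendon_intensity, spec$sheath_intensity,
            spec$background_intensity, spec$plate_intensity,
            spec$fuzzy_below_intensity)
  if (any(ints < 0 | ints > 255)) stop("phantom intensities must lie in [0, 255]")
  invisible(spec)
}

# Radial boundary perturbation (two truncated Fourier modes on the
# normalized ellipse radius).
perturb_rho <- function(phi, amps) {
  1 + amps[1] * cos(2 * phi) + amps[2] * sin(3 * phi)
}

#' Generate one phantom image with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix, `[0, 255]`), `tendon` and
#'   `sheath` (20-point ground-truth contours), `tendon_dense` and
#'   `sheath_dense` (dense truth polylines), `group` (the spec's
#'   bottom-contrast mode), `amplitudes`, and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  with_seed(spec$rng_seed, {
    amps <- spec$perturb_amplitudes
    if (is.null(amps)) amps <- stats::rnorm(2, 0, spec$perturb_sd)
    ctr <- spec$center
    if (spec$center_jitter > 0)
      ctr <- ctr + stats::runif(2, -spec$center_jitter, spec$center_jitter)
    a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; w <- spec$sheath_width

    xg <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
    yg <- matrix(seq_len(spec$height), spec$height, spec$width)
    u <- (xg - ctr[1]) / a; v <- (yg - ctr[2]) / b
    rho_t <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
    rho_edge <- perturb_rho(phi, amps)
    in_tendon <- rho_t <= rho_edge
    rho_s <- sqrt(((xg - ctr[1]) / (a + w))^2 + ((yg - ctr[2]) / (b + w))^2)
    in_outer <- rho_s <= 1

    img <- matrix(spec$background_intensity, spec$height, spec$width)
    plate_top <- ctr[2] + b + w + spec$plate_offset
    in_plate <- yg >= plate_top & yg <= plate_top + spec$plate_thickness
    img[in_plate] <- spec$plate_intensity
    in_band <- in_outer & !in_tendon
    img[in_band] <- spec$sheath_intensity
    if (spec$bottom_contrast == "fuzzy") {
      # fill the band below the tendon with a near-tendon intensity,
      # blended over ~4 px from the tendon boundary outward
      below <- in_band & (yg > ctr[2])
      blend <- pmin(1, pmax(0, (rho_t - rho_edge) * b / 4))
      fuzzy_val <- spec$tendon_intensity +
        (spec$fuzzy_below_intensity - spec$tendon_intensity) * blend
      img[below] <- fuzzy_val[below]
    }
    img[in_tendon] <- spec$tendon_intensity

    if (spec$speckle_scale > 0) {
      ray <- sqrt(-2 * log(stats::runif(length(img))))
      ray <- ray / sqrt(pi / 2)                  # unit-mean Rayleigh
      img <- img * (1 + spec$speckle_scale * (ray - 1))
      img <- pmin(pmax(img, 0), 255)
    }

    phi_d <- seq(0, 2 * pi, length.out = 721L)[-721L]
    rho_d <- perturb_rho(phi_d, amps)
    tendon_dense <- cbind(ctr[1] + a * rho_d * cos(phi_d),
                          ctr[2] + b * rho_d * sin(phi_d))
    sheath_dense <- cbind(ctr[1] + (a + w) * cos(phi_d),
                          ctr[2] + (b + w) * sin(phi_d))
    list(
      image = img,
      tendon = resample_contour(tendon_dense),
      sheath = resample_contour(sheath_dense),
      tendon_dense = tendon_dense,
      sheath_dense = sheath_dense,
      group = spec$bottom_contrast,
      amplitudes = amps,
      spec = spec
    )
  })
}

#' Generate a seeded phantom training set
#'
#' `n` phantoms whose tendon boundaries are drawn from the
#' two-mode radial perturbation generator (amplitudes
#' `N(0, perturb_sd^2)`), giving the shape PCA a known two-mode truth.
#'
#' @param n number of phantoms (>= 2).
#' @param spec base [phantom_spec()]; each phantom derives its own seed.
#' @param seed master seed.
#' @return list of [generate_phantom()] results.
#' @export
generate_training_set <- function(n, spec = phantom_spec(), seed = 1L) {
  if (n < 2L) stop("need n >= 2")
  lapply(seq_len(n), function(i) {
    s <- spec
    s$rng_seed <- child_seed(seed, i)
    generate_phantom(s)
  })
}

#' Generate a paired-hand phantom cohort for classification
#'
#' Each pair holds a left and right hand phantom. In symptomatic pairs
#' one hand (chosen at random) is rendered with an enlarged tendon area
#' (`+area_effect` fraction) and its speckle contrast multiplied by
#' `speckle_mult` — a surrogate for the thickened, hypoechoic diseased
#' tendon. Asymptomatic pairs get two exchangeable normal hands.
#'
#' @param n_pairs pairs per cohort (>= 4; half symptomatic).
#' @param area_effect fractional tendon area increase (default 0.30).
#' @param speckle_mult speckle contrast multiplier (default 1.5).
#' @param spec base [phantom_spec()].
#' @param subject_size_sd inter-subject tendon size variation: each
#'   pair's base semi-axes are scaled by `N(1, subject_size_sd^2)`
#'   shared by both hands (default 0.08; tendon calibre varies
#'   appreciably across people).
#' @param hand_size_sd residual left/right size asymmetry per hand
#'   (default 0.02).
#' @param seed master seed.
#' @return list with `pairs` (list of `left`, `right`, `label`,
#'   `affected`) and `manifest` (data frame of labels and affected
#'   sides).
#' @export
generate_pair_cohort <- function(n_pairs, area_effect = 0.30,
                                 speckle_mult = 1.5, spec = phantom_spec(),
                                 subject_size_sd = 0.08, hand_size_sd = 0.02,
                                 seed = 1L) {
  if (n_pairs < 4L) stop("need n_pairs >= 4")
  n_sym <- n_pairs %/% 2L
  labels <- rep(c("symptomatic", "asymptomatic"), c(n_sym, n_pairs - n_sym))
  pairs <- vector("list", n_pairs)
  draws <- with_seed(child_seed(seed, 0), list(
    affected = sample(c("left", "right"), n_pairs, replace = TRUE),
    subject = pmin(pmax(stats::rnorm(n_pairs, 1, subject_size_sd), 0.8), 1.2),
    hand = pmin(pmax(matrix(stats::rnorm(2L * n_pairs, 1, hand_size_sd),
                            n_pairs, 2L), 0.94), 1.06)
  ))
  for (i in seq_len(n_pairs)) {
    make_hand <- function(k, diseased) {
      s <- spec
      s$rng_seed <- child_seed(seed, i * 97 + k)
      s$semi_axes <- s$semi_axes * draws$subject[i] * draws$hand[i, k]
      if (diseased) {
        s$semi_axes <- s$semi_axes * sqrt(1 + area_effect)
        s$speckle_scale <- s$speckle_scale * speckle_mult
      }
      generate_phantom(s)
    }
    sym <- labels[i] == "symptomatic"
    pairs[[i]] <- list(
      left = make_hand(1L, sym && draws$affected[i] == "left"),
      right = make_hand(2L, sym && draws$affected[i] == "right"),
      label = labels[i],
      affected = if (sym) draws$affected[i] else NA_character_
    )
  }
  list(
    pairs = pairs,
    manifest = data.frame(
      pair = seq_len(n_pairs), label = labels,
      affected = vapply(pairs, function(p) p$affected %||% NA_character_, ""),
      stringsAsFactors = FALSE
    )
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Feature table of a phantom pair cohort
#'
#' Extracts the per-hand feature vectors (ground-truth contours are used
#' for the ROI and area features) and the per-pair differences.
#'
#' @param cohort result of [generate_pair_cohort()].
#' @return list with `features` (pairs x features matrix of differences)
#'   and `labels`.
#' @export
cohort_features <- function(cohort) {
  rows <- lapply(cohort$pairs, function(p) {
    fl <- hand_features(p$left$image, p$left$tendon, p$left$sheath)
    fr <- hand_features(p$right$image, p$right$tendon, p$right$sheath)
    pair_difference(fl, fr, p$label, p$affected %||% "right")
  })
  features <- do.call(rbind, rows)
  list(features = features,
       labels = vapply(cohort$pairs, function(p) p$label, ""))
}
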