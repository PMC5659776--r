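# Optimizers: a real-coded genetic algorithm over shape parameters
# (roulette selection, single-point crossover, single-gene mutation,
# elitism) and a derivative-free direction-set (Powell) local minimizer
# used for pose refinement and template matching.

#' Genetic-algorithm configuration
#'
#' Defaults follow the segmentation procedure: crossover probability 0.5,
#' per-chromosome mutation probability 0.01, convergence when the elite
#' is unchanged for 10 generations. Population size and the generation
#' cap are configurable.
#'
#' @param population_size chromosomes per generation (default 50).
#' @param crossover_prob single-point crossover probability per pair.
#' @param mutation_prob per-chromosome probability of replacing one
#'   random gene with a uniform in-bounds value.
#' @param convergence_patience generations of unchanged elite fitness
#'   (absolute tolerance 1e-9) before stopping.
#' @param max_generations hard generation cap (default 200).
#' @param rng_seed optional seed applied locally inside [ga_maximize()].
#' @export
ga_config <- function(population_size = 50L, crossover_prob = 0.5,
                      mutation_prob = 0.01, convergence_patience = 10L,
                      max_generations = 200L, rng_seed = NULL) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            convergence_patience >= 1L, population_size >= 2L)
  list(population_size = as.integer(population_size),
       crossover_prob = crossover_prob, mutation_prob = mutation_prob,
       convergence_patience = as.integer(convergence_patience),
       max_generations = as.integer(max_generations), rng_seed = rng_seed)
}

#' Maximize a fitness function with a genetic algorithm
#'
#' Chromosomes are real-valued gene vectors initialized uniformly inside
#' the bounds. Each generation applies fitness-proportional (roulette)
#' selection on min-shifted fitness, single-point crossover, single-gene
#' mutation, and elitism (the best-so-far chromosome replaces the worst
#' offspring). Evolution stops when the elite fitness is unchanged for
#' `convergence_patience` generations or at `max_generations`.
#'
#' @param fitness function mapping a gene vector to a finite scalar
#'   (non-finite values cause the chromosome to be resampled).
#' @param lower,upper gene bounds; for a shape model use
#'   `+/- 3 sqrt(lambda)` (see [shape_param_bounds()]).
#' @param config a [ga_config()].
#' @return list with `par` (elite genes), `value` (elite fitness),
#'   `history` (per-generation elite fitness) and `generations`.
#' @export
ga_maximize <- function(fitness, lower, upper, config = ga_config()) {
  m <- length(lower)
  stopifnot(length(upper) == m, all(upper >= lower), m >= 1L)
  run <- function() {
    n <- config$population_size
    rand_chrom <- function() lower + stats::runif(m) * (upper - lower)
    eval_safe <- function(chrom) {
      f <- fitness(chrom)
      tries <- 0L
      while (!is.finite(f) && tries < 50L) {
        chrom <- rand_chrom()
        f <- fitness(chrom)
        tries <- tries + 1L
      }
      if (!is.finite(f)) stop("fitness not finite on the feasible box")
      list(chrom = chrom, f = f)
    }
    pop <- matrix(0, n, m)
    fit <- numeric(n)
    for (i in seq_len(n)) {
      ev <- eval_safe(rand_chrom())
      pop[i, ] <- ev$chrom; fit[i] <- ev$f
    }
    elite_i <- which.max(fit)
    elite <- pop[elite_i, ]; elite_f <- fit[elite_i]
    history <- elite_f
    stale <- 0L
    gen <- 0L
    while (gen < config$max_generations && stale < config$convergence_patience) {
      gen <- gen + 1L
      shifted <- fit - min(fit)
      prob <- if (sum(shifted) <= 0) rep(1 / n, n) else shifted / sum(shifted)
      parents <- pop[sample.int(n, n, replace = TRUE, prob = prob), , drop = FALSE]
      if (m >= 2L) {
        for (j in seq(1L, n - 1L, by = 2L)) {
          if (stats::runif(1) < config$crossover_prob) {
            cut <- sample.int(m - 1L, 1L)
            tail_idx <- (cut + 1L):m
            tmp <- parents[j, tail_idx]
            parents[j, tail_idx] <- parents[j + 1L, tail_idx]
            parents[j + 1L, tail_idx] <- tmp
          }
        }
      }
      for (j in seq_len(n)) {
        if (stats::runif(1) < config$mutation_prob) {
          g <- sample.int(m, 1L)
          parents[j, g] <- lower[g] + stats::runif(1) * (upper[g] - lower[g])
        }
      }
      for (j in seq_len(n)) {
        ev <- eval_safe(parents[j, ])
        parents[j, ] <- ev$chrom; fit[j] <- ev$f
      }
      worst <- which.min(fit)
      parents[worst, ] <- elite; fit[worst] <- elite_f
      pop <- parents
      best <- which.max(fit)
      if (fit[best] > elite_f + 1e-9) {
        elite <- pop[best, ]; elite_f <- fit[best]
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      history <- c(history, elite_f)
    }
    list(par = elite, value = elite_f, history = history, generations = gen)
  }
  if (!is.null(config$rng_seed)) with_seed(config$rng_seed, run()) else run()
}

# Brent line minimization along a direction, with bracket expansion when
# the minimum sits at the interval edge.
line_min <- function(fn, x, dir, fx) {
  g <- function(t) fn(x + t * dir)
  lo <- -1; hi <- 1
  opt <- NULL
  for (rep in 1:10) {
    opt <- stats::optimize(g, c(lo, hi), tol = 1e-8)
    inner <- opt$minimum > lo + 0.05 * (hi - lo) &&
      opt$minimum < hi - 0.05 * (hi - lo)
    if (inner) break
    lo <- 2 * lo; hi <- 2 * hi
  }
  if (is.finite(opt$objective) && opt$objective < fx)
    list(x = x + opt$minimum * dir, f = opt$objective)
  else list(x = x, f = fx)
}

#' Powell direction-set minimization
#'
#' Derivative-free local minimizer: cycles of line minimizations along a
#' direction set, replacing the direction of largest decrease with the
#' cycle's net displacement. Stops when the fractional decrease of a
#' full cycle falls below `ftol` or after `maxit` cycles.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 starting point.
#' @param ftol fractional convergence tolerance (default 1e-4).
#' @param maxit cycle cap (default 100; hitting it returns the best
#'   point found, flagged via `converged = FALSE`).
#' @param step initial step scale per coordinate (scalar or vector);
#'   sets the units of the initial direction set.
#' @return list with `par`, `value`, `iterations`, `converged`.
#' @export
powell_minimize <- function(fn, x0, ftol = 1e-4, maxit = 100L, step = 1) {
  n <- length(x0)
  step <- rep_len(step, n)
  dirs <- diag(step, n, n)
  x <- as.numeric(x0)
  fx <- fn(x)
  if (!is.finite(fx)) stop("objective not finite at the starting point")
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    f0 <- fx
    x_start <- x
    biggest <- 0; ibig <- 1L
    for (d in seq_len(n)) {
      ls <- line_min(fn, x, dirs[, d], fx)
      if (fx - ls$f > biggest) { biggest <- fx - ls$f; ibig <- d }
      x <- ls$x; fx <- ls$f
    }
    if (2 * (f0 - fx) <= ftol * (abs(f0) + abs(fx)) + 1e-25) {
      converged <- TRUE
      break
    }
    dnew <- x - x_start
    if (sqrt(sum(dnew^2)) > 0) {
      ls <- line_min(fn, x, dnew, fx)
      x <- ls$x; fx <- ls$f
      dirs[, ibig] <- dnew
    }
  }
  list(par = x, value = fx, iterations = it, converged = converged)
}

#' Refine the pose of a shape model by local energy maximization
#'
#' Powell maximization of the weighted total energy over translation,
#' scale and rotation with the shape parameters `b` held fixed. If the
#' refined scale leaves `[0.5, 2]` times the initial scale the step is
#' considered divergent and the initial pose is returned (flagged).
#'
#' @param ctx energy context (see [energy_vector()]).
#' @param model an `atasm_shape_model`.
#' @param weights 5 x 20 energy weight matrix.
#' @param b fixed shape parameters.
#' @param pose starting pose.
#' @param ftol Powell tolerance.
#' @return list with `pose`, `value` (energy at the returned pose) and
#'   `diverged`.
#' @export
refine_pose <- function(ctx, model, weights, b, pose, ftol = 1e-4) {
  mu <- model$mean_shape
  modes <- model$modes
  bb <- clamp_shape_params(b, model)
  v <- mu
  if (length(bb) > 0L) v <- v + as.vector(modes %*% bb)
  base_shape <- vec_to_shape(v)
  w <- unclass(weights)
  obj <- function(par) {
    if (par[3] <= 0) return(Inf)
    ps <- shape_pose(par[1], par[2], par[3], par[4])
    -sum(w * energy_terms_fast(ctx, apply_pose(base_shape, ps)))
  }
  x0 <- c(pose$tx, pose$ty, pose$scale, pose$rotation)
  res <- powell_minimize(obj, x0, ftol = ftol, maxit = 10L,
                         step = c(2, 2, 0.02 * pose$scale, 0.02))
  new_pose <- shape_pose(res$par[1], res$par[2], res$par[3], res$par[4])
  if (new_pose$scale < 0.5 * pose$scale || new_pose$scale > 2 * pose$scale) {
    return(list(pose = pose, value = -obj(x0), diverged = TRUE))
  }
  list(pose = new_pose, value = -res$value, diverged = FALSE)
}
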