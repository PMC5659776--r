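# Procrustes alignment, the PCA point distribution model, shape
# synthesis and parameter clamping.

ref_contour <- resample_contour(make_ellipse(50, 30, c(0, 0)))

test_that("aligning two identical shapes returns the normalized shape as mean", {
  p <- as.matrix(ref_contour)
  res <- procrustes_align(list(p, p))
  expect_equal(res$aligned[[1]], res$aligned[[2]], tolerance = 1e-10)
  expect_equal(res$mean_shape, res$aligned[[1]], tolerance = 1e-8)
  expect_equal(colMeans(res$mean_shape), c(0, 0), tolerance = 1e-10)
  expect_equal(sqrt(mean(rowSums(res$mean_shape^2))), 1, tolerance = 1e-10)
})

test_that("a similarity-transformed copy aligns back exactly", {
  p <- as.matrix(ref_contour)
  th <- 0.4
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- sweep(1.7 * p %*% t(rot), 2, c(30, -12), `+`)
  res <- procrustes_align(list(p, q))
  expect_lt(max(abs(res$aligned[[1]] - res$aligned[[2]])), 1e-8)
})

test_that("pairwise alignment residual matches the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(7)
  p <- as.matrix(ref_contour)
  for (i in 1:5) {
    q <- p + matrix(rnorm(40, 0, 3), 20, 2)
    tf <- atasm:::fit_similarity(q, p)
    ours <- sum((tf$apply(q) - p)^2)
    oracle <- vegan::procrustes(p, q, scale = TRUE, symmetric = FALSE)$ss
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("alignment is invariant to similarity pre-transforms of the set", {
  set.seed(11)
  shapes <- lapply(1:5, function(i) as.matrix(ref_contour) + matrix(rnorm(40, 0, 2), 20, 2))
  th <- -0.8
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- lapply(shapes, function(p) sweep(0.6 * p %*% t(rot), 2, c(100, 55), `+`))
  m1 <- procrustes_align(shapes)$mean_shape
  m2 <- procrustes_align(moved)$mean_shape
  # the mean is defined up to rotation; align before comparing
  m2a <- atasm:::fit_similarity(m2, m1)$apply(m2)
  expect_lt(sqrt(mean(rowSums((m1 - m2a)^2))), 1e-6)
})

test_that("PCA handles degenerate and low-rank training sets", {
  p <- atasm:::normalize_shape(as.matrix(ref_contour))
  same <- fit_pca(list(p, p, p))
  expect_equal(length(same$eigenvalues), 0L)
  expect_equal(as.matrix(synthesize_shape(same)), atasm:::vec_to_shape(same$mean_shape),
               ignore_attr = TRUE)

  dir <- matrix(rnorm(40), 20, 2)
  dir <- dir / sqrt(sum(dir^2))
  rank1 <- lapply(c(-2, -1, 1, 2) * 0.01, function(a) p + a * dir)
  m <- fit_pca(rank1, var_retain = 0.999999)
  expect_equal(length(m$eigenvalues), 1L)
  expect_gt(m$eigenvalues[1], 0)
  expect_lt(m$all_eigenvalues[2] / m$all_eigenvalues[1], 1e-10)
})

test_that("a two-mode generator is recovered with correct eigenvalues", {
  set.seed(3)
  p <- atasm:::normalize_shape(as.matrix(ref_contour))
  u1 <- atasm:::shape_to_vec(matrix(rnorm(40), 20, 2))
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- atasm:::shape_to_vec(matrix(rnorm(40), 20, 2))
  u2 <- u2 - sum(u2 * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  s1 <- 0.05; s2 <- 0.02
  shapes <- lapply(1:60, function(i) {
    v <- atasm:::shape_to_vec(p) + rnorm(1, 0, s1) * u1 + rnorm(1, 0, s2) * u2
    atasm:::vec_to_shape(v)
  })
  m <- fit_pca(shapes, var_retain = 0.9999)
  expect_equal(length(m$eigenvalues), 2L)
  expect_equal(sqrt(m$eigenvalues[1]), s1, tolerance = 0.35)
  expect_equal(sqrt(m$eigenvalues[2]), s2, tolerance = 0.35)
  # conservation: eigenvalue sum equals total variance of shape vectors
  x <- t(sapply(shapes, atasm:::shape_to_vec))
  expect_equal(sum(m$all_eigenvalues), sum(diag(cov(x))), tolerance = 1e-9)
})

test_that("synthesis follows mean + modes + pose and clamps out-of-model b", {
  set.seed(5)
  shapes <- lapply(1:8, function(i) as.matrix(ref_contour) + matrix(rnorm(40, 0, 2), 20, 2))
  ga <- procrustes_align(shapes)
  m <- fit_pca(ga$aligned)
  expect_equal(as.matrix(synthesize_shape(m)), atasm:::vec_to_shape(m$mean_shape),
               ignore_attr = TRUE)
  shifted <- synthesize_shape(m, pose = shape_pose(10, 5))
  expect_equal(as.matrix(shifted),
               atasm:::vec_to_shape(m$mean_shape) + rep(c(10, 5), each = 20),
               ignore_attr = TRUE)
  # b = 3 sqrt(lambda_1) e1: independent vector arithmetic oracle
  b <- numeric(length(m$eigenvalues))
  b[1] <- 3 * sqrt(m$eigenvalues[1])
  direct <- atasm:::vec_to_shape(m$mean_shape + 3 * sqrt(m$eigenvalues[1]) * m$modes[, 1])
  expect_equal(as.matrix(synthesize_shape(m, b)), direct, ignore_attr = TRUE,
               tolerance = 1e-12)
  # clamping: 10 sqrt(lambda) is pulled to 3 sqrt(lambda); interior unchanged
  lim <- 3 * sqrt(m$eigenvalues)
  expect_equal(clamp_shape_params(10 * sqrt(m$eigenvalues), m), lim)
  inside <- 0.5 * lim
  expect_equal(clamp_shape_params(inside, m), inside)
  # zero-eigenvalue modes force b to 0
  m0 <- m
  m0$eigenvalues[length(m0$eigenvalues)] <- 0
  b0 <- clamp_shape_params(rep(1, length(m0$eigenvalues)), m0)
  expect_equal(b0[length(b0)], 0)
})

test_that("project/synthesize round-trips training shapes within the model", {
  set.seed(9)
  shapes <- lapply(1:10, function(i) as.matrix(ref_contour) + matrix(rnorm(40, 0, 2), 20, 2))
  ga <- procrustes_align(shapes)
  m <- fit_pca(ga$aligned, var_retain = 0.98)
  discarded <- sum(m$all_eigenvalues) - sum(m$eigenvalues)
  for (i in c(1, 5, 10)) {
    pr <- project_shape(m, ga$aligned[[i]], clamp = FALSE)
    rec <- synthesize_shape(m, clamp_shape_params(pr$b, m), pr$pose)
    err2 <- sum((as.matrix(rec) - ga$aligned[[i]])^2)
    # residual bounded by the discarded variance plus a small clamping
    # allowance (training components can sit slightly beyond 3 sd)
    expect_lt(err2, 10 * discarded * length(shapes) + 1e-3)
  }
})

test_that("degenerate alignments are rejected", {
  flat <- matrix(1, 20, 2)
  expect_error(procrustes_align(list(flat, flat)), "coincident")
  expect_error(procrustes_align(list(as.matrix(ref_contour))), "at least 2")
  expect_error(fit_pca(list(as.matrix(ref_contour))), "at least 2")
})
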