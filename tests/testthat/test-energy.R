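# The five energy terms, the weighted total, and adaptive weight
# training.

test_that("curvature angles match analytic wedge geometry", {
  collinear <- as_contour(rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_equal(curvature_term(collinear, 2), pi)
  right_angle <- as_contour(rbind(c(0, 1), c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(curvature_term(right_angle, 2), pi / 2)
  # 60-degree wedge at the origin
  wedge <- as_contour(rbind(c(1, 0), c(0, 0),
                            c(cos(pi / 3), sin(pi / 3)), c(1, 1)))
  expect_equal(curvature_term(wedge, 2), pi / 3)
  degen <- as_contour(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1)))
  expect_warning(v <- curvature_term(degen, 2), "coincident")
  expect_equal(v, pi)
})

# bright half-plane below y = 60.5, circle contour tangent to it from below
step_image <- function() {
  img <- matrix(50, 160, 160)
  img[61:160, ] <- 200
  img
}
step_contour <- function() resample_contour(make_circle(30, c(80, 91)))

test_that("gradient terms read the step with the right sign per target", {
  img <- step_image()
  ct <- step_contour()
  i_top <- which.min(as.matrix(ct)[, 2])  # boundary point on the step edge
  expect_equal(area_gradient_term(img, ct, i_top, "tendon"), 150, tolerance = 1e-6)
  expect_equal(area_gradient_term(img, ct, i_top, "sheath"), -150, tolerance = 1e-6)
  expect_equal(line_gradient_term(img, ct, i_top, "tendon"), 150, tolerance = 1e-6)
  expect_equal(line_gradient_term(img, ct, i_top, "sheath"), -150, tolerance = 1e-6)
  flat <- matrix(90, 160, 160)
  expect_equal(area_gradient_term(flat, ct, i_top, "tendon"), 0)
  expect_equal(line_gradient_term(flat, ct, i_top, "tendon"), 0)
})

test_that("sheath gradient terms are the negated tendon terms everywhere", {
  set.seed(17)
  img <- matrix(runif(160 * 160, 0, 255), 160, 160)
  ct <- step_contour()
  tm <- list(gabor = rep(0, 100), laws = rep(0, 100),
             gabor_sigma = 4, gabor_phi = 0.1, gabor_size = 25L)
  ctx_t <- atasm:::energy_context(img, structure(tm, class = "atasm_texture_model"), "tendon")
  ctx_s <- ctx_t; ctx_s$target <- "sheath"
  ft <- energy_vector(ctx_t, ct)
  fs <- energy_vector(ctx_s, ct)
  expect_equal(fs["area_grad", ], -ft["area_grad", ])
  expect_equal(fs["line_grad", ], -ft["line_grad", ])
  expect_equal(fs["curvature", ], ft["curvature", ])
  expect_equal(fs["gabor", ], ft["gabor", ])
})

test_that("texture energies are negative SSDs with per-point partials", {
  ct <- resample_contour(make_circle(30, c(64, 64)))
  flat <- matrix(3, 128, 128)
  tm <- structure(list(gabor = rep(0, 100), laws = rep(0, 100),
                       gabor_sigma = 4, gabor_phi = 0.1, gabor_size = 25L),
                  class = "atasm_texture_model")
  tex_g <- gabor_texture_image(flat)   # identically 0
  tm$gabor <- sample_profile(tex_g, ct)
  e <- gabor_energy(tm, ct, tex_g)
  expect_equal(as.numeric(e), 0)
  # model offset by 1 everywhere: 100 unit squared differences
  tm$gabor <- tm$gabor + 1
  e1 <- gabor_energy(tm, ct, tex_g)
  expect_equal(as.numeric(e1), -100)
  expect_equal(attr(e1, "partials"), rep(-5, 20))
  # random pair against a brute-force sum oracle
  set.seed(4)
  img <- matrix(runif(128 * 128, 0, 255), 128, 128)
  tex_l <- laws_texture_image(img)
  tm$laws <- runif(100, -10, 10)
  el <- laws_energy(tm, ct, tex_l)
  prof <- sample_profile(tex_l, ct)
  expect_equal(as.numeric(el), -sum((tm$laws - prof)^2), tolerance = 1e-9)
})

test_that("the weighted total equals the brute-force double sum", {
  set.seed(8)
  f <- matrix(rnorm(100), 5, 20)
  w <- matrix(runif(100), 5, 20)
  expect_equal(total_energy(f, matrix(1, 5, 20)), sum(f))
  expect_equal(total_energy(f, matrix(0, 5, 20)), 0)
  brute <- 0
  for (k in 1:5) for (i in 1:20) brute <- brute + w[k, i] * f[k, i]
  expect_equal(total_energy(f, w), brute)
  expect_error(total_energy(f, matrix(1, 5, 19)), "identical dimensions")
})

test_that("weight training rewards discriminative search lines", {
  img <- step_image()
  ct <- step_contour()
  tm <- build_texture_model(list(img), list(ct))
  w <- train_weights(list(img), list(ct), tm, "tendon")
  expect_true(all(dim(w) == c(5, 20)))
  expect_true(all(w >= 0))
  # the top point sits exactly on the step: its gradient line is maximal at
  # the true position, so its weight must exceed the weight at the bottom
  # point (whose search line sees a constant bright region)
  i_top <- which.min(as.matrix(ct)[, 2])
  i_bot <- which.max(as.matrix(ct)[, 2])
  expect_gt(w["area_grad", i_top], w["area_grad", i_bot])
  expect_lt(w["area_grad", i_bot], 1e-6)   # constant line: weight 0
})

test_that("trained weights match an independent per-line recomputation", {
  # spreadsheet-style oracle: recompute sigma * (F - min)/(Fmax - min)
  # for the area-gradient term by direct sampling on two images
  set.seed(12)
  imgs <- list(step_image(),
               step_image() + matrix(rnorm(160 * 160, 0, 5), 160, 160))
  ct <- step_contour()
  tm <- build_texture_model(imgs, list(ct, ct))
  w <- train_weights(imgs, list(ct, ct), tm, "tendon")
  p <- as.matrix(ct)
  nrm <- contour_normals(ct)
  for (i in c(1, 6, 11)) {
    contrib <- numeric(2)
    for (t in 1:2) {
      vals <- sapply(-10:10, function(d) {
        shifted <- p
        shifted[i, ] <- p[i, ] + d * nrm[i, ]
        area_gradient_term(imgs[[t]], as_contour(shifted), i, "tendon")
      })
      s <- sd(vals)
      lo <- min(vals); hi <- max(vals)
      contrib[t] <- if (hi - lo <= 0) 0 else max(0, s * (vals[11] - lo) / (hi - lo))
    }
    expect_equal(unname(w["area_grad", i]), mean(contrib), tolerance = 1e-6)
  }
})
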