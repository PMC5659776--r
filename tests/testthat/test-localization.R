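# Intensity-template training and coarse-to-fine SAD localization.

test_that("SAD is a mean absolute difference with the expected identities", {
  set.seed(2)
  a <- matrix(runif(30 * 20, 0, 255), 30, 20)
  expect_equal(sad(a, a), 0)
  expect_equal(sad(a, a + 7), 7)
  b <- matrix(runif(30 * 20, 0, 255), 30, 20)
  brute <- 0
  for (i in 1:30) for (j in 1:20) brute <- brute + abs(a[i, j] - b[i, j])
  expect_equal(sad(a, b), brute / 600)
  expect_equal(sad(a, b), sad(b, a))
  expect_error(sad(a, matrix(0, 10, 10)), "equal block dimensions")
})

test_that("the template of a single image is its own crop", {
  fx <- small_model_fixture()
  ph <- fx$train[[1]]
  tpl <- train_template(list(ph$image), list(ph$tendon))
  org <- tpl$origin
  crop <- ph$image[org["y"] + seq_len(nrow(tpl$pixels)) - 1,
                   org["x"] + seq_len(ncol(tpl$pixels)) - 1]
  expect_equal(tpl$pixels, crop, ignore_attr = TRUE)
  # two identical images average to the same template
  tpl2 <- train_template(list(ph$image, ph$image), list(ph$tendon, ph$tendon))
  expect_equal(tpl2$pixels, tpl$pixels, tolerance = 1e-9)
})

test_that("the template is the coverage-weighted mean of aligned images", {
  # two phantoms with identical geometry but different contrast levels:
  # warping is the identity, so the template is the plain per-pixel mean
  s1 <- small_spec(speckle_scale = 0, perturb_amplitudes = c(0, 0))
  s2 <- s1; s2$tendon_intensity <- 190
  ph1 <- generate_phantom(s1); ph2 <- generate_phantom(s2)
  tpl <- train_template(list(ph1$image, ph2$image), list(ph1$tendon, ph2$tendon))
  org <- tpl$origin
  rows <- org["y"] + seq_len(nrow(tpl$pixels)) - 1
  cols <- org["x"] + seq_len(ncol(tpl$pixels)) - 1
  direct <- (ph1$image[rows, cols] + ph2$image[rows, cols]) / 2
  expect_equal(tpl$pixels, direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("coarse localization recovers embeddings and breaks ties first", {
  fx <- small_model_fixture()
  tpl <- fx$model$tendon$template
  big <- matrix(100, 260, 300)
  big[41 + seq_len(nrow(tpl$pixels)) - 1, 71 + seq_len(ncol(tpl$pixels)) - 1] <-
    tpl$pixels
  loc <- coarse_locate(big, tpl)
  expect_lte(max(abs(loc$origin - c(x = 71, y = 41))), 1)
  expect_lt(loc$sad, 1e-9)
  # uniform image: every block ties, smallest (row, col) wins
  flat <- matrix(100, 260, 300)
  loc0 <- coarse_locate(flat, tpl)
  expect_equal(loc0$origin, c(x = 1, y = 1))
})

test_that("coarse localization is translation-equivariant", {
  fx <- small_model_fixture()
  tpl <- fx$model$tendon$template
  base <- matrix(100, 260, 300)
  base[31 + seq_len(nrow(tpl$pixels)) - 1, 41 + seq_len(ncol(tpl$pixels)) - 1] <-
    tpl$pixels
  shifted <- matrix(100, 260, 300)
  shifted[31 + 24 + seq_len(nrow(tpl$pixels)) - 1,
          41 + 16 + seq_len(ncol(tpl$pixels)) - 1] <- tpl$pixels
  l1 <- coarse_locate(base, tpl)
  l2 <- coarse_locate(shifted, tpl)
  expect_equal(l2$origin - l1$origin, c(x = 16, y = 24))
})

# embed the template with a similarity transform into a flat background
embed_template <- function(tpl, origin = c(80, 60), scale = 1, rot = 0,
                           size = c(260, 300)) {
  big <- matrix(100, size[1], size[2])
  ctr <- c((1 + ncol(tpl$pixels)) / 2, (1 + nrow(tpl$pixels)) / 2)
  gx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  gy <- matrix(seq_len(size[1]), size[1], size[2])
  dx <- gx - (origin[1] + ctr[1] - 1)
  dy <- gy - (origin[2] + ctr[2] - 1)
  q1 <- (cos(rot) * dx + sin(rot) * dy) / scale + ctr[1]
  q2 <- (-sin(rot) * dx + cos(rot) * dy) / scale + ctr[2]
  inside <- q1 >= 1 & q1 <= ncol(tpl$pixels) & q2 >= 1 & q2 <= nrow(tpl$pixels)
  vals <- atasm:::bilinear_sample(tpl$pixels, pmin(pmax(q1, 1), ncol(tpl$pixels)),
                                  pmin(pmax(q2, 1), nrow(tpl$pixels)))
  big[inside] <- vals[inside]
  big
}

test_that("fine localization recovers translation, scale and rotation", {
  fx <- small_model_fixture()
  tpl <- fx$model$tendon$template
  # unshifted noise-free embedding: identity refinement
  big <- embed_template(tpl, c(80, 60))
  loc <- coarse_locate(big, tpl)
  fl <- fine_locate(big, tpl, loc$origin)
  expect_lt(abs(fl$tx + loc$origin["x"] - 80), 0.5)
  expect_lt(abs(fl$ty + loc$origin["y"] - 60), 0.5)
  # scaled x1.1
  b2 <- embed_template(tpl, c(80, 60), scale = 1.1)
  l2 <- coarse_locate(b2, tpl)
  f2 <- fine_locate(b2, tpl, l2$origin)
  expect_lt(abs(f2$scale - 1.1), 0.02)
  # rotated 5 degrees
  b3 <- embed_template(tpl, c(80, 60), rot = 5 * pi / 180)
  l3 <- coarse_locate(b3, tpl)
  f3 <- fine_locate(b3, tpl, l3$origin)
  expect_lt(abs(f3$rotation - 5 * pi / 180), pi / 180)
})

test_that("a manual ROI maps the reference contour affinely onto the box", {
  fx <- small_model_fixture()
  tpl <- fx$model$tendon$template
  ref <- as.matrix(tpl$reference_contour)
  bx <- range(ref[, 1]); by <- range(ref[, 2])
  # box equal to the reference extent: contour unchanged
  same <- manual_roi_override(tpl, c(bx[1], by[1], diff(bx), diff(by)))
  expect_equal(as.matrix(same), ref, tolerance = 1e-9, ignore_attr = TRUE)
  # box twice as wide: x deviations double
  wide <- manual_roi_override(tpl, c(bx[1], by[1], 2 * diff(bx), diff(by)))
  expect_equal(as.matrix(wide)[, 1] - bx[1], 2 * (ref[, 1] - bx[1]),
               tolerance = 1e-9)
  expect_equal(as.matrix(wide)[, 2], ref[, 2], tolerance = 1e-9)
  # arbitrary box: corner-mapping oracle
  box <- c(10, 20, 50, 31)
  got <- as.matrix(manual_roi_override(tpl, box))
  expect_equal(range(got[, 1]), c(10, 60), tolerance = 1e-9)
  expect_equal(range(got[, 2]), c(20, 51), tolerance = 1e-9)
  expect_error(manual_roi_override(tpl, c(5, 5, 0, 10)), "positive size")
})
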