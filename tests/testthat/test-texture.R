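# Gabor and Laws texture images and the 100-element contour profiles.

test_that("Gabor kernel centre values and symmetries are analytic", {
  sigma <- 4
  k <- gabor_kernel(sigma = sigma, phi = 0.1, theta = 0, size = 25L)
  mid <- 13L
  expect_equal(k$real[mid, mid], 1 / (2 * pi * sigma^2))
  expect_equal(k$imag[mid, mid], 0)
  # imaginary kernel is odd under (x, y) -> (-x, -y)
  expect_equal(k$imag, -k$imag[25:1, 25:1], tolerance = 1e-14)
  # theta = pi/2 swaps the roles of x and y (grid-evaluation oracle)
  k90 <- gabor_kernel(sigma = sigma, phi = 0.1, theta = pi / 2, size = 25L)
  expect_equal(k90$imag, t(k$imag), tolerance = 1e-14)
  expect_equal(k90$real, t(k$real), tolerance = 1e-14)
  expect_error(gabor_kernel(size = 24L), "odd")
})

test_that("Gabor filtering is zero on constants, linear, and edge-localized", {
  flat <- matrix(37, 48, 48)
  expect_lt(max(abs(gabor_texture_image(flat))), 1e-9)
  # horizontal intensity step along x, theta = 0: extremal response at the edge
  img <- matrix(0, 48, 48)
  img[, 25:48] <- 100
  resp <- gabor_texture_image(img, theta_deg = 0)
  interior <- resp[20:28, ]
  expect_true(all(abs(interior[, c(24, 25)]) >= apply(abs(interior), 1, max) - 1e-6))
  # direct convolution oracle on a small patch
  k <- gabor_kernel(size = 25L)$imag
  small <- matrix(seq_len(32 * 32)^1.3 %% 97, 32, 32)
  ours <- gabor_texture_image(small)
  oracle <- matrix(0, 32, 32)
  pad <- 12L
  ridx <- c(rev(seq_len(pad) + 1L), 1:32, 32 - seq_len(pad))
  padded <- small[ridx, ridx]
  for (y in 1:32) for (x in 1:32) {
    block <- padded[y:(y + 24L), x:(x + 24L)]
    oracle[y, x] <- sum(block * k[25:1, 25:1])   # convolution flips the kernel
  }
  expect_equal(ours, oracle, tolerance = 1e-8)
  # linearity
  expect_equal(gabor_texture_image(3 * small), 3 * ours, tolerance = 1e-8)
})

test_that("the Laws level-edge kernel matches the printed matrix", {
  k <- laws_kernel()
  printed <- rbind(
    c(-1, -4, -6, -4, -1),
    c(-2, -8, -12, -8, -2),
    c(0, 0, 0, 0, 0),
    c(2, 8, 12, 8, 2),
    c(1, 4, 6, 4, 1)
  )
  expect_equal(k, printed)
  expect_equal(sum(k), 0)
})

test_that("Laws filtering: zero on constants, constant on a vertical ramp", {
  flat <- matrix(5, 40, 40)
  expect_lt(max(abs(laws_texture_image(flat))), 1e-9)
  # I(x, y) = y: symbolic convolution gives -sum(E5 * dy) * sum(L5) = -128
  ramp <- matrix(seq_len(40), 40, 40)
  resp <- laws_texture_image(ramp)
  expect_equal(resp[10:30, 10:30], matrix(-128, 21, 21), tolerance = 1e-9)
  # linearity
  img <- matrix(rnorm(1600), 40, 40)
  expect_equal(laws_texture_image(2.5 * img), 2.5 * laws_texture_image(img),
               tolerance = 1e-9)
})

test_that("profiles are 100 long, constant on constants, symmetric on disks", {
  ct <- resample_contour(make_circle(30, c(64, 64)))
  flat <- matrix(7.5, 128, 128)
  prof <- sample_profile(flat, ct)
  expect_length(prof, 100L)
  expect_equal(prof, rep(7.5, 100))
  # radially symmetric texture: identical 5-sample pattern at all points
  gx <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  gy <- matrix(seq_len(128), 128, 128)
  radial <- sqrt((gx - 64)^2 + (gy - 64)^2)
  pr <- matrix(sample_profile(radial, ct), nrow = 5L)
  expect_lt(max(apply(pr, 1, function(v) diff(range(v)))), 0.02)
})

test_that("profiles on a linear field match hand-computed normal offsets", {
  # f(x, y) = x sampled on a square-sided 20-gon: at the mid-side points
  # the outward normal is (+/-1, 0) or (0, +/-1) exactly
  sq <- rbind(
    cbind(44 + 10 * (0:4), 39),        # top side, left to right
    cbind(89, 44 + 10 * (0:4)),        # right side, downward
    cbind(84 - 10 * (0:4), 89),        # bottom side, right to left
    cbind(39, 84 - 10 * (0:4))         # left side, upward
  )
  ct <- as_contour(sq)
  p <- as.matrix(ct)
  gx <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  prof <- matrix(sample_profile(gx, ct), nrow = 5L)
  offs <- c(-4, -2, 0, 2, 4)
  right_mid <- which(p[, 1] == 89 & p[, 2] == 64)
  left_mid <- which(p[, 1] == 39 & p[, 2] == 64)
  top_mid <- which(p[, 2] == 39 & p[, 1] == 64)
  expect_equal(prof[, right_mid], 89 + offs)   # outward normal (+1, 0)
  expect_equal(prof[, left_mid], 39 - offs)    # outward normal (-1, 0)
  expect_equal(prof[, top_mid], rep(64, 5))    # normal (0, -1): x constant
})

test_that("profile sampling is translation-equivariant", {
  set.seed(21)
  img <- matrix(rnorm(150 * 150), 150, 150)
  big <- matrix(0, 170, 170)
  big[11:160, 11:160] <- img
  ct <- resample_contour(make_circle(30, c(75, 75)))
  ct_shift <- as_contour(as.matrix(ct) + 10)
  p1 <- sample_profile(img, ct)
  p2 <- sample_profile(big, ct_shift)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("the texture model is the element-wise mean of training profiles", {
  set.seed(33)
  imgs <- lapply(1:3, function(i) matrix(runif(128 * 128, 0, 255), 128, 128))
  ct <- resample_contour(make_circle(30, c(64, 64)))
  single <- build_texture_model(imgs[1], list(ct))
  expect_equal(single$gabor, sample_profile(gabor_texture_image(imgs[[1]]), ct))
  expect_equal(single$laws, sample_profile(laws_texture_image(imgs[[1]]), ct))
  pairm <- build_texture_model(imgs[1:2], list(ct, ct))
  expect_equal(pairm$laws,
               (sample_profile(laws_texture_image(imgs[[1]]), ct) +
                  sample_profile(laws_texture_image(imgs[[2]]), ct)) / 2)
  # brute-force mean oracle over all three
  all3 <- build_texture_model(imgs, list(ct, ct, ct))
  stack <- sapply(imgs, function(im) sample_profile(gabor_texture_image(im), ct))
  expect_equal(all3$gabor, rowMeans(stack), tolerance = 1e-12)
})
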