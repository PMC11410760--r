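test_that("mse/mae/psnr follow their closed forms", {
  a <- matrix(0, 5, 5)
  b <- matrix(10, 5, 5)
  expect_equal(mse(a, b), 100)
  expect_equal(mae(a, b), 10)
  expect_equal(mse(a, a), 0)
  set.seed(4)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_gte(mse(x, y), mae(x, y)^2)   # Jensen
  expect_equal(mse(x, y), mse(y, x))

  expect_identical(psnr(x, x), Inf)
  # constant difference of 10/255 on the 0-255 scale -> MSE 100
  g <- matrix(0.3, 6, 6)
  p <- g + 10 / 255
  expect_equal(psnr(g, p), 10 * log10(65025 / 100), tolerance = 1e-10)
  # halving the MSE raises PSNR by 10*log10(2)
  p2 <- g + 10 / 255 / sqrt(2)
  expect_equal(psnr(g, p2) - psnr(g, p), 10 * log10(2), tolerance = 1e-10)
  expect_error(psnr(x, matrix(0, 4, 4)), "shape")
})

test_that("ssim matches a scalar evaluation on a single window", {
  set.seed(9)
  x <- matrix(runif(121), 11, 11)
  y <- matrix(runif(121), 11, 11)
  k <- cxrpretext:::ssim_window(11L, 1.5)
  # scalar oracle: weighted moments of the single 11x11 window
  mx <- sum(k * x); my <- sum(k * y)
  vx <- sum(k * x^2) - mx^2; vy <- sum(k * y^2) - my^2
  cxy <- sum(k * x * y) - mx * my
  C1 <- 0.01^2; C2 <- 0.03^2
  oracle <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssim(x, y), oracle, tolerance = 1e-12)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # inverting a high-variance image flips the structure term negative
  z <- fixture_image(32, seed = 6)
  expect_lt(ssim(unclass(z), 1 - unclass(z)), 0)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("haar subbands match brute-force pairwise sums/differences", {
  f1 <- cxrpretext:::haar_filter_2d(1L)
  # scale-1: high-pass along rows, low-pass along columns, magnitude 1/2
  expect_equal(f1, matrix(c(0.5, -0.5, 0.5, -0.5), 2, 2), tolerance = 1e-12)
  m <- matrix(as.numeric(1:16), 4, 4)
  resp <- cxrpretext:::filter_same_even(m, f1)
  # brute force at interior position (i, j): window rows i..i+1, cols j..j+1
  for (i in 1:3) for (j in 1:3) {
    expected <- 0.5 * (m[i, j] + m[i, j + 1]) - 0.5 * (m[i + 1, j] + m[i + 1, j + 1])
    expect_equal(resp[i, j], expected, tolerance = 1e-12)
  }
  f2 <- cxrpretext:::haar_filter_2d(2L)
  expect_equal(dim(f2), c(4L, 4L))
  expect_equal(sum(f2), 0)                       # high-pass: zero mean
  expect_true(all(abs(f2) == 2^-2))              # reference normalization
})

test_that("haarpsi is 1 at identity and orders degradation severity", {
  img <- fixture_image(64, seed = 12)
  expect_equal(haarpsi(img, img), 1, tolerance = 1e-9)
  set.seed(31)
  noise <- gray_image(matrix(runif(64 * 64), 64, 64))
  light <- add_gaussian_blur(img, 3L)
  h_noise <- haarpsi(img, noise)
  h_light <- haarpsi(img, light)
  expect_lt(h_noise, h_light)
  expect_gte(h_noise, 0)
  expect_lte(h_light, 1)
  expect_error(haarpsi(matrix(0.1, 4, 4), matrix(0.1, 4, 4)), "small")
})

test_that("psnr and ssim are non-increasing under stronger noise", {
  img <- fixture_image(48, seed = 20)
  factors <- c(0.02, 0.04, 0.06, 0.08, 0.1)
  ps <- ss <- numeric(length(factors))
  for (i in seq_along(factors)) {
    deg <- add_gaussian_noise(img, factors[i], seed = 100L + i)
    ps[i] <- psnr(img, deg)
    ss[i] <- ssim(unclass(img), unclass(deg))
  }
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
})

test_that("quality_report bundles the five metrics", {
  img <- fixture_image(32)
  deg <- add_gaussian_noise(img, 0.05, seed = 2L)
  qr <- quality_report(img, deg)
  expect_named(qr, c("psnr", "ssim", "haarpsi", "mse", "mae"))
  expect_true(qr$ssim < 1 && qr$ssim > -1)
  expect_true(qr$haarpsi >= 0 && qr$haarpsi <= 1)
})
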