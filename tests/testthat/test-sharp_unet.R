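test_that("sharpening stamps the kernel on an impulse, fixes constants and ramps", {
  k <- sharpen_kernel()
  expect_equal(sum(k), 1)
  expect_equal(k[2, 2], 5)

  const <- array(0.3, c(8, 8, 3))
  expect_equal(sharpen_features(const), const, tolerance = 1e-12)

  imp <- array(0, c(9, 9, 1))
  imp[5, 5, 1] <- 1
  sh <- sharpen_features(imp)
  expect_equal(sh[4:6, 4:6, 1], k, tolerance = 1e-12)

  ramp <- array(outer(1:10, 1:10, function(i, j) 0.3 * i + 0.7 * j),
                c(10, 10, 1))
  shr <- sharpen_features(ramp)
  interior <- 2:9
  expect_equal(shr[interior, interior, 1], ramp[interior, interior, 1],
               tolerance = 1e-10)
})

test_that("restorer shapes, ranges and encoder pooling arithmetic", {
  model <- build_restorer(c(64L, 64L), width_multiplier = 1 / 8, seed = 2L)
  out <- restorer_forward(model, array(0, c(64, 64, 1, 1)), taps = TRUE)
  expect_equal(dim(out$output), c(64L, 64L, 1L, 1L))
  expect_true(all(is.finite(out$output)))
  expect_true(all(out$output > 0 & out$output < 1))
  # pre-pool activations at blocks 1-5; post-pool sizes are 32,16,8,4,4
  pre <- vapply(out$acts, function(a) dim(a)[1L], integer(1))
  expect_equal(pre, c(64L, 32L, 16L, 8L, 4L))
  # post-pool sizes: blocks 1-4 halve, block 5 stays at 4
  expect_equal(c(pre[2:5], dim(out$acts[[5]])[1L]), c(32L, 16L, 8L, 4L, 4L))
  expect_error(build_restorer(c(100L, 100L)), "divisible")

  # 224 x 224 input maps to 224 x 224 output
  m224 <- build_restorer(c(224L, 224L), width_multiplier = 1 / 16, seed = 1L)
  y <- restorer_forward(m224, array(0.5, c(224, 224, 1, 1)))
  expect_equal(dim(y)[1:2], c(224L, 224L))
})

test_that("parameter counts follow layer arithmetic and ignore sharpening", {
  # toy: one 3x3 conv (2 -> 4 channels) has 2*4*9 + 4 = 76 parameters
  layer <- cxrpretext:::layer_conv(3L, 3L, 2L, 4L)
  expect_equal(count_parameters(list(layer)), 76)

  model <- build_restorer(c(32L, 32L), width_multiplier = 1 / 8, seed = 5L)
  n_on <- count_parameters(model)
  plain <- model
  plain$sharpen <- FALSE
  expect_equal(count_parameters(plain), n_on)

  # doubling one conv layer's output filters changes the count by the
  # expected delta (its own weights+bias plus the next layer's input slice)
  f <- model$filters
  delta_own <- 9 * 1 * f[1] + f[1]          # block1 conv1: 1 -> f1 more filters
  delta_next <- 9 * f[1] * f[1]             # block1 conv2 input widens by f1
  model2 <- build_restorer(c(32L, 32L), width_multiplier = 1 / 8, seed = 5L)
  model2$enc[[1]][[1]] <- cxrpretext:::layer_conv(3L, 3L, 1L, 2L * f[1])
  model2$enc[[1]][[2]] <- cxrpretext:::layer_conv(3L, 3L, 2L * f[1], f[1])
  expect_equal(count_parameters(model2) - n_on, delta_own + delta_next)
})

test_that("sharpened skips differ from plain skips except on constants", {
  model <- build_restorer(c(32L, 32L), width_multiplier = 1 / 8, seed = 7L)
  x <- array(fixture_image(32), c(32, 32, 1, 1))
  y_sharp <- restorer_forward(model, x)
  plain <- model
  plain$sharpen <- FALSE
  y_plain <- restorer_forward(plain, x)
  expect_false(isTRUE(all.equal(y_sharp, y_plain)))
  # constant feature maps pass through the sharpener unchanged
  const_feat <- array(0.7, c(8, 8, 4, 2))
  expect_equal(sharpen_features(const_feat), const_feat, tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-identically", {
  tmp <- withr::local_tempdir()
  model <- build_restorer(c(32L, 32L), width_multiplier = 1 / 8, seed = 1L)
  x <- array(fixture_image(32), c(32, 32, 1, 1))
  y1 <- restorer_forward(model, x)
  f <- file.path(tmp, "m.ckpt")
  save_checkpoint(model, f)
  other <- build_restorer(c(32L, 32L), width_multiplier = 1 / 8, seed = 99L)
  load_checkpoint(other, f)
  expect_identical(restorer_forward(other, x), y1)
  wrong <- build_restorer(c(32L, 32L), width_multiplier = 1 / 4, seed = 1L)
  expect_error(load_checkpoint(wrong, f), "fingerprint")
})
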