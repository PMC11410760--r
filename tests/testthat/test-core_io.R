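test_that("load_image scales by 2^depth - 1 and handles extremes", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "x.png")
  png::writePNG(matrix(1, 3, 3), f)
  expect_equal(as.numeric(load_image(f)), rep(1, 9))
  png::writePNG(matrix(0, 3, 3), f)
  expect_equal(as.numeric(load_image(f)), rep(0, 9))
  png::writePNG(matrix(128 / 255, 3, 3), f)
  expect_equal(as.numeric(load_image(f)), rep(128 / 255, 9), tolerance = 1e-12)
  expect_error(load_image(file.path(tmp, "missing.png")), "exist")
})

test_that("save_image quantizes half away from zero and round-trips", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "y.png")
  save_image(gray_image(matrix(0.5, 4, 4)), f)
  raw <- png::readPNG(f) * 255
  expect_equal(as.numeric(raw), rep(128, 16))  # round(127.5) -> 128
  img <- fixture_image(16)
  save_image(img, f)
  back <- load_image(f)
  expect_lt(max(abs(back - img)), 1 / 255)
  expect_error(gray_image(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("resize is identity-safe and matches the bilinear oracle", {
  img <- fixture_image(8)
  expect_equal(as.numeric(resize(img, c(8, 8))), as.numeric(img),
               tolerance = 1e-12)
  const <- gray_image(matrix(0.37, 5, 5))
  expect_equal(as.numeric(resize(const, c(9, 7))), rep(0.37, 63),
               tolerance = 1e-12)
  checker <- gray_image(matrix(c(0, 1, 1, 0), 2, 2))
  got <- resize(checker, c(4, 4))
  expect_equal(unclass(got), oracle_bilinear(unclass(checker), 4, 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  big <- fixture_image(7, 9, seed = 2)
  expect_equal(unclass(resize(big, c(13, 5))),
               oracle_bilinear(unclass(big), 13, 5),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("crop_to_mask_bbox crops tightly and validates", {
  img <- fixture_image(8)
  full <- matrix(TRUE, 8, 8)
  expect_equal(as.numeric(crop_to_mask_bbox(img, full)), as.numeric(img))
  single <- matrix(FALSE, 8, 8); single[4, 6] <- TRUE
  cr <- crop_to_mask_bbox(img, single)
  expect_equal(dim(cr), c(1L, 1L))
  expect_equal(as.numeric(cr), img[4, 6])
  two <- matrix(FALSE, 8, 12); two[3, 4] <- TRUE; two[6, 10] <- TRUE
  img2 <- fixture_image(8, 12, seed = 3)
  cr2 <- crop_to_mask_bbox(img2, two)
  expect_equal(unclass(cr2), unclass(img2)[3:6, 4:10], ignore_attr = TRUE)
  expect_error(crop_to_mask_bbox(img, matrix(FALSE, 8, 8)), "no true")
  expect_error(crop_to_mask_bbox(img, matrix(TRUE, 4, 4)), "shape")
})

test_that("label tables and configs round-trip; derived seeds are stable", {
  tmp <- withr::local_tempdir()
  df <- data.frame(image_id = c("a", "b"), patient_id = c("p1", "p2"),
                   label = c(0L, 1L))
  f <- file.path(tmp, "labels.csv")
  write_label_table(df, f)
  back <- read_label_table(f)
  expect_equal(back$label, c(0L, 1L))
  expect_equal(back$split, c("unassigned", "unassigned"))
  df$label <- c(2L, 1L)
  expect_error(write_label_table(df, f), "0 or 1")

  cfg <- run_config(seed = 9L, image_size = c(64L, 64L),
                    stages = list(pretext = list(max_epochs = 2)))
  cf <- file.path(tmp, "cfg.yaml")
  write_run_config(cfg, cf)
  cfg2 <- read_run_config(cf)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$stages$pretext$max_epochs, 2)

  expect_identical(derive_seed(9L, "degrade"), derive_seed(9L, "degrade"))
  expect_false(derive_seed(9L, "degrade") == derive_seed(9L, "pretext"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
})
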