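test_that("phantom generation is a pure function of its spec", {
  sp <- phantom_spec(size = c(48L, 48L), abnormal = TRUE, opacity_count = 2L,
                     seed = 3L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$boxes, b$boxes)
  c <- generate_phantom(phantom_spec(size = c(48L, 48L), abnormal = TRUE,
                                     opacity_count = 2L, seed = 4L))
  expect_false(identical(unclass(a$image), unclass(c$image)))
})

test_that("normal phantoms have no boxes; opacities brighten their boxes", {
  norm <- generate_phantom(phantom_spec(size = c(64L, 64L), seed = 1L))
  expect_equal(nrow(norm$boxes), 0L)

  ab <- generate_phantom(phantom_spec(size = c(64L, 64L), abnormal = TRUE,
                                      opacity_count = 2L, seed = 2L))
  expect_equal(nrow(ab$boxes), 2L)
  img <- unclass(ab$image)
  w <- ncol(img)
  for (i in seq_len(nrow(ab$boxes))) {
    b <- ab$boxes[i, ]
    inside <- img[(b$row_min:b$row_max) + 1L, (b$col_min:b$col_max) + 1L]
    # same-size box mirrored into the opposite lung field
    mc <- sort(w - 1L - c(b$col_min, b$col_max))
    mirror <- img[(b$row_min:b$row_max) + 1L, (mc[1]:mc[2]) + 1L]
    expect_gt(mean(inside), mean(mirror))
  }
  expect_error(phantom_spec(abnormal = FALSE, opacity_count = 1L), "normal")
  expect_error(phantom_spec(size = c(16L, 16L),
                            opacity_radius_range = c(10, 12)), "radius")
})

test_that("cohort label counts match an independent recount", {
  co <- generate_cohort(100L, 0.33, size = c(16L, 16L), seed = 7L)
  expect_equal(sum(co$records$label == 1L), 33L)
  expect_equal(length(co$images), 100L)
  # recount from the records themselves
  recount <- table(factor(co$records$label, levels = c(0, 1)))
  expect_equal(as.integer(recount), c(67L, 33L))
  # every abnormal record has at least one truth box, normals none
  for (i in seq_len(nrow(co$records))) {
    id <- co$records$image_id[i]
    if (co$records$label[i] == 1L) {
      expect_gte(nrow(co$truth_boxes[[id]]), 1L)
    } else {
      expect_null(co$truth_boxes[[id]])
    }
  }
  co0 <- generate_cohort(10L, 0, size = c(16L, 16L), seed = 1L)
  expect_equal(sum(co0$records$label), 0L)
  expect_error(generate_cohort(0L, 0.5), "positive")
})

test_that("patient_split keeps patients together and hits 70/10/20", {
  records <- data.frame(image_id = sprintf("i%02d", 1:10),
                        patient_id = sprintf("p%02d", 1:10),
                        label = rep(0:1, 5), split = "unassigned",
                        stringsAsFactors = FALSE)
  co <- list(records = records)
  sp <- patient_split(co, seed = 3L)
  expect_equal(sum(sp$records$split == "train"), 7L)
  expect_equal(sum(sp$records$split == "val"), 1L)
  expect_equal(sum(sp$records$split == "test"), 2L)

  co2 <- generate_cohort(80L, 0.4, size = c(16L, 16L), seed = 9L)
  sp2 <- patient_split(co2, seed = 9L)
  by_split <- split(sp2$records$patient_id, sp2$records$split)
  expect_length(Reduce(intersect, by_split), 0L)
  # deviation bounded by the largest patient
  biggest <- max(table(sp2$records$patient_id))
  tab <- table(factor(sp2$records$split, c("train", "val", "test")))
  expect_true(all(abs(tab - c(56, 8, 16)) <= biggest))
  # deterministic re-run
  sp3 <- patient_split(co2, seed = 9L)
  expect_identical(sp2$records$split, sp3$records$split)
  expect_error(patient_split(co2, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("cohorts round-trip through disk in the core_io dialects", {
  tmp <- withr::local_tempdir()
  co <- fixture_cohort(n = 8L, size = c(16L, 16L))
  write_cohort(co, tmp)
  labs <- read_label_table(file.path(tmp, "labels.csv"))
  expect_setequal(labs$image_id, co$records$image_id)
  img <- load_image(file.path(tmp, paste0(labs$image_id[1], ".png")))
  expect_lt(max(abs(img - co$images[[labs$image_id[1]]])), 1 / 255)
  if (any(labs$label == 1L)) {
    boxes <- read_box_table(file.path(tmp, "boxes.csv"))
    expect_true(all(boxes$x_max >= boxes$x_min))
  }
})
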