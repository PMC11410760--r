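test_that("score_cam matches a manual channel-by-channel computation", {
  clf <- build_classifier(NULL, "random", input_size = c(32L, 32L),
                          width_multiplier = 1 / 256, seed = 13L)
  img <- fixture_image(32, seed = 14)
  cam <- score_cam(clf, img, target_class = 1L)
  expect_equal(dim(cam), c(32L, 32L))
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)

  # independent oracle: sequential masked forward passes per channel
  m <- unclass(img)
  ad <- asNamespace("cxrpretext")
  ad$ad_reset_tape()
  acts <- ad$classifier_forward_node(
    clf, ad$ad_const(ad$promote_batch(m)), taps = TRUE)$conv$val
  manual <- matrix(0, 32, 32)
  for (k in seq_len(dim(acts)[3L])) {
    up <- ad$bilinear_resize_matrix(matrix(acts[, , k, 1L], dim(acts)[1L], dim(acts)[2L]), 32L, 32L)
    r <- range(up)
    if (r[2L] - r[1L] <= 0) next
    mask <- (up - r[1L]) / (r[2L] - r[1L])
    w_k <- classifier_predict(clf, m * mask)$probs[1L, 2L]
    manual <- manual + w_k * up
  }
  manual <- pmax(manual, 0)
  manual <- (manual - min(manual)) / (max(manual) - min(manual))
  expect_equal(unclass(cam), manual, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("duplicate channels receive equal weights", {
  clf <- build_classifier(NULL, "random", input_size = c(32L, 32L),
                          width_multiplier = 1 / 256, seed = 15L)
  # force two identical channels by duplicating block-5 conv filters
  last <- clf$enc[[5]][[length(clf$enc[[5]])]]
  last$w$val[, , , 2L] <- last$w$val[, , , 1L]
  last$b$val[2L] <- last$b$val[1L]
  img <- fixture_image(32, seed = 16)
  ad <- asNamespace("cxrpretext")
  ad$ad_reset_tape()
  acts <- ad$classifier_forward_node(
    clf, ad$ad_const(ad$promote_batch(unclass(img))), taps = TRUE)$conv$val
  expect_equal(acts[, , 1L, 1L], acts[, , 2L, 1L], tolerance = 1e-12)
})

test_that("map_to_bbox finds extreme points; box_iou counts pixels", {
  single <- matrix(0, 10, 10); single[4, 7] <- 1
  bb <- map_to_bbox(single, 0.2)
  expect_equal(unlist(bb[c("row_min", "col_min", "row_max", "col_max")]),
               c(row_min = 3L, col_min = 6L, row_max = 3L, col_max = 6L))
  two <- matrix(0, 10, 12); two[3, 4] <- 1; two[6, 10] <- 0.9
  bb2 <- map_to_bbox(two, 0.2)
  expect_equal(c(bb2$row_min, bb2$col_min, bb2$row_max, bb2$col_max),
               c(2L, 3L, 5L, 9L))
  uni <- matrix(0.8, 6, 9)
  bb3 <- map_to_bbox(uni, 0.5)
  expect_equal(c(bb3$row_max, bb3$col_max), c(5L, 8L))
  expect_error(map_to_bbox(matrix(0, 4, 4), 0.2), "survive")
  expect_error(map_to_bbox(uni, 1.2), "rel_threshold")

  a <- bounding_box(0, 0, 9, 9)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box(20, 20, 25, 25)), 0)
  b <- bounding_box(5, 0, 14, 9)
  expect_equal(box_iou(a, b), 50 / 150)
})

test_that("score-cam boxes overlap phantom truth in most detected cases", {
  cohort <- fixture_cohort(n = 60L, size = c(32L, 32L), prevalence = 0.5,
                           seed = 41L)
  clf <- build_classifier(NULL, "random", input_size = c(32L, 32L),
                          width_multiplier = 1 / 8, seed = 42L)
  fit <- fine_tune(clf, cohort, classifier_config(max_epochs = 6L,
                                                  batch_size = 16L,
                                                  seed = 43L))
  rec <- cohort$records
  test_ab <- rec[rec$split == "test" & rec$label == 1L, ]
  hits <- 0L; scored <- 0L
  for (id in test_ab$image_id) {
    img <- cohort$images[[id]]
    if (classifier_predict(fit$model, list(img))$probs[1L, 2L] < 0.5) next
    cam <- score_cam(fit$model, img, target_class = 1L)
    box <- tryCatch(map_to_bbox(cam, 0.2), error = function(e) NULL)
    if (is.null(box)) next
    scored <- scored + 1L
    truth <- cohort$truth_boxes[[id]]
    ious <- vapply(seq_len(nrow(truth)), function(i)
      box_iou(box, as.list(truth[i, ])), numeric(1))
    if (max(ious) > 0) hits <- hits + 1L
  }
  expect_gt(scored, 0L)
  expect_gt(hits / scored, 0.5)
})
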