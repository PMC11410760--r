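make_pred_set <- function(n = 200L, seed = 17L, perfect_strength = 0.99) {
  set.seed(seed)
  labels <- rbinom(n, 1L, 0.5)
  # member 1: near-perfect; member 2: uniform random probabilities
  p1_ab <- ifelse(labels == 1L, perfect_strength, 1 - perfect_strength)
  p2_ab <- runif(n)
  prediction_set(list(cbind(1 - p1_ab, p1_ab), cbind(1 - p2_ab, p2_ab)),
                 labels = labels, model_names = c("good", "noise"))
}

test_that("simple averaging is the arithmetic mean and conserves mass", {
  ps <- prediction_set(list(cbind(0.2, 0.8), cbind(0.4, 0.6)), labels = 1L)
  expect_equal(as.numeric(simple_average(ps)), c(0.3, 0.7))
  ps2 <- make_pred_set(50)
  sa <- simple_average(ps2)
  expect_equal(rowSums(sa), rep(1, 50), tolerance = 1e-12)
  same <- prediction_set(list(ps2$probs[[1]], ps2$probs[[1]]),
                         labels = ps2$labels)
  expect_equal(simple_average(same), ps2$probs[[1]])
  expect_error(prediction_set(list(cbind(0.2, 0.9)), labels = 1L), "sum to 1")
})

test_that("slsqp weights match a 0.01-resolution simplex grid search", {
  ps <- make_pred_set(200)
  wts <- fit_slsqp_weights(ps)
  expect_equal(sum(wts$w), 1, tolerance = 1e-9)
  expect_true(all(wts$w >= 0))
  expect_gt(wts$w[1], 0.9)  # nearly all weight on the near-perfect member
  # independent oracle: exhaustive grid on the 2-simplex
  grid <- seq(0, 1, by = 0.01)
  losses <- vapply(grid, function(w1)
    cxrpretext:::weighted_logloss(c(w1, 1 - w1), ps$probs, ps$labels),
    numeric(1))
  best_grid <- grid[which.min(losses)]
  expect_lt(abs(wts$w[1] - best_grid), 0.01)
  expect_lte(wts$logloss, min(losses) + 1e-9)
})

test_that("slsqp never does worse than uniform; identical members are flat", {
  ps <- make_pred_set(120, seed = 23)
  wts <- fit_slsqp_weights(ps)
  uni <- cxrpretext:::weighted_logloss(rep(0.5, 2), ps$probs, ps$labels)
  expect_lte(wts$logloss, uni + 1e-9)
  same <- prediction_set(list(ps$probs[[1]], ps$probs[[1]]),
                         labels = ps$labels)
  wsame <- fit_slsqp_weights(same)
  single <- cxrpretext:::weighted_logloss(c(1, 0), same$probs, same$labels)
  expect_equal(wsame$logloss, single, tolerance = 1e-9)
  expect_true(all(wsame$w >= 0) && abs(sum(wsame$w) - 1) < 1e-9)
})

test_that("apply_weights reduces to members, simple average and convexity", {
  ps <- make_pred_set(80, seed = 29)
  expect_equal(apply_weights(ps, c(1, 0)), ps$probs[[1]])
  expect_equal(apply_weights(ps, c(0.5, 0.5)), simple_average(ps))
  w <- c(0.3, 0.7)
  out <- apply_weights(ps, w)
  lo <- pmin(ps$probs[[1]], ps$probs[[2]])
  hi <- pmax(ps$probs[[1]], ps$probs[[2]])
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  expect_error(apply_weights(ps, c(1, 0, 0)), "length")
  expect_error(apply_weights(ps, c(0.8, 0.8)), "sum to 1")
})

test_that("attention-fuzzy wiring: alpha simplex, gamma limits, argmax", {
  m1 <- build_classifier(NULL, "random", input_size = c(16L, 16L),
                         width_multiplier = 1 / 8, seed = 1L)
  m2 <- build_classifier(NULL, "random", input_size = c(16L, 16L),
                         width_multiplier = 1 / 8, seed = 2L)
  af <- build_af_ensemble(list(m1, m2), seed = 3L)
  set.seed(4)
  x <- array(runif(16 * 16 * 6), c(16, 16, 1, 6))
  pr <- af_predict(af, x)
  expect_equal(rowSums(pr$probs), rep(1, 6), tolerance = 1e-9)
  expect_equal(rowSums(pr$alpha), rep(1, 6), tolerance = 1e-9)
  arg1 <- apply(pr$logits, 1L, which.max)
  # gamma -> 0+ flattens towards uniform
  af$gamma$val <- 1e-10
  flat <- af_predict(af, x)
  expect_equal(as.numeric(flat$probs), rep(0.5, 12), tolerance = 1e-6)
  # positive scaling preserves the per-sample argmax
  af$gamma$val <- 7
  hot <- af_predict(af, x)
  expect_equal(apply(hot$logits, 1L, which.max), arg1)
  expect_error(build_af_ensemble(list(m1)), "two members")
})

test_that("af training updates gamma but never the frozen backbones", {
  cohort <- fixture_cohort(n = 16L, size = c(16L, 16L), prevalence = 0.5)
  m1 <- build_classifier(NULL, "random", input_size = c(16L, 16L),
                         width_multiplier = 1 / 8, seed = 5L)
  m2 <- build_classifier(NULL, "random", input_size = c(16L, 16L),
                         width_multiplier = 1 / 8, seed = 6L)
  af <- build_af_ensemble(list(m1, m2), seed = 7L)
  before <- cxrpretext:::af_backbone_checksum(af)
  g0 <- as.numeric(af$gamma$val)
  cfg <- classifier_config(max_epochs = 2L, batch_size = 8L, seed = 8L)
  fit <- train_af_ensemble(af, cohort, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_identical(cxrpretext:::af_backbone_checksum(fit$model), before)
  expect_false(isTRUE(all.equal(as.numeric(fit$model$gamma$val), g0)))
  # unfrozen members are rejected
  af2 <- build_af_ensemble(list(m1, m2), seed = 9L)
  p <- cxrpretext:::collect_frozen(af2$members[[1]]$enc)[[1]]
  p$requires_grad <- TRUE
  expect_error(train_af_ensemble(af2, cohort, cfg), "unfrozen")
})

test_that("af ensemble recovers the informative member across seeds", {
  # one informative member (briefly fine-tuned), one anti-informative
  # (its head logits flipped); the trained ensemble should match or beat
  # the best single member's validation balanced accuracy in >= 7/10 seeds
  cohort <- fixture_cohort(n = 60L, size = c(16L, 16L), prevalence = 0.5,
                           seed = 31L)
  base <- build_classifier(NULL, "random", input_size = c(16L, 16L),
                           width_multiplier = 1 / 8, seed = 11L)
  good <- fine_tune(base, cohort,
                    classifier_config(max_epochs = 4L, batch_size = 16L,
                                      seed = 12L))$model
  bad <- cxrpretext:::clone_params(good)
  bad$head$w$val <- -bad$head$w$val  # anti-informative twin
  bad$head$b$val <- -bad$head$b$val
  va <- cxrpretext:::cohort_split_batch(cohort, "val")
  acc_of <- function(probs) cxrpretext:::balanced_accuracy_from_probs(
    probs[, 2L], va$y)
  best_single <- max(acc_of(classifier_predict(good, va$x)$probs),
                     acc_of(classifier_predict(bad, va$x)$probs))
  wins <- 0L
  for (s in 1:10) {
    af <- build_af_ensemble(list(good, bad), seed = 100L + s)
    fit <- train_af_ensemble(af, cohort,
                             classifier_config(max_epochs = 4L,
                                               batch_size = 16L,
                                               seed = 200L + s))
    acc <- acc_of(af_predict(fit$model, va$x)$probs)
    if (acc >= best_single - 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
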