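test_that("se_from_ci arithmetic and linearity", {
  expect_equal(se_from_ci(0.4, 0.6), 0.2 / 3.92, tolerance = 1e-12)
  expect_equal(se_from_ci(0.5, 0.5), 0)
  expect_equal(se_from_ci(0.3, 0.7), 2 * se_from_ci(0.4, 0.6),
               tolerance = 1e-12)
  expect_error(se_from_ci(0.6, 0.4), "inverted")
})

test_that("wilson interval matches score-test inversion and edge cases", {
  expect_equal(unname(binomial_ci(0, 20)[1]), 0)
  expect_equal(unname(binomial_ci(20, 20)[2]), 1)
  ci <- binomial_ci(50, 100)
  # oracle: invert the score test by root finding
  z <- qnorm(0.975)
  score <- function(p, phat, n) (phat - p) / sqrt(p * (1 - p) / n)
  lower <- uniroot(function(p) score(p, 0.5, 100) - z, c(1e-6, 0.5 - 1e-9),
                   tol = 1e-12)$root
  upper <- uniroot(function(p) score(p, 0.5, 100) + z, c(0.5 + 1e-9, 1 - 1e-6),
                   tol = 1e-12)$root
  expect_equal(unname(ci[1]), lower, tolerance = 1e-9)
  expect_equal(unname(ci[2]), upper, tolerance = 1e-9)
  # cross-check against prop.test's uncorrected interval
  pt <- prop.test(37, 120, correct = FALSE)$conf.int
  ci2 <- binomial_ci(37, 120)
  expect_equal(unname(ci2), as.numeric(pt), tolerance = 1e-9)
  expect_error(binomial_ci(5, 0), "positive")
})

test_that("compare_sensitivities follows Z arithmetic and antisymmetry", {
  ea <- sensitivity_estimate(0.20, 0.20 - 1.96 * 0.03, 0.20 + 1.96 * 0.03)
  eb <- sensitivity_estimate(0.50, 0.50 - 1.96 * 0.04, 0.50 + 1.96 * 0.04)
  cr <- compare_sensitivities(ea, eb)
  # oracle: direct evaluation with a high-precision normal CDF (quadrature)
  z_exp <- 0.30 / sqrt(0.03^2 + 0.04^2)
  phi <- integrate(dnorm, abs(z_exp), Inf, rel.tol = 1e-12)$value
  expect_equal(cr$z, z_exp, tolerance = 1e-12)
  expect_equal(cr$p, 2 * phi, tolerance = 1e-6)  # quadrature tail accuracy
  expect_true(cr$significant)

  rev <- compare_sensitivities(eb, ea)
  expect_equal(rev$delta_sensitivity, -cr$delta_sensitivity)
  expect_equal(rev$z, -cr$z)
  expect_equal(rev$p, cr$p)

  same <- compare_sensitivities(ea, ea)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  degenerate <- sensitivity_estimate(0.5, 0.5, 0.5)
  expect_error(compare_sensitivities(degenerate, degenerate), "undefined Z")
})

test_that("pairwise_panel enumerates C(n,2) pairs consistently", {
  set.seed(8)
  ests <- lapply(1:6, function(i) estimate_sensitivity(20 + 5 * i, 80 - 5 * i))
  names(ests) <- paste0("m", 1:6)
  panel <- pairwise_panel(ests)
  expect_equal(nrow(panel), 15L)
  k <- which(panel$model_a == "m2" & panel$model_b == "m5")
  cr <- compare_sensitivities(ests[["m2"]], ests[["m5"]])
  expect_equal(panel$z[k], cr$z)
  expect_equal(panel$p[k], cr$p)
  expect_true(all(panel$p > 0 & panel$p <= 1))
  expect_error(pairwise_panel(ests[1]), "two")
  names(ests)[2] <- "m1"
  expect_error(pairwise_panel(ests), "unique")
})

test_that("a constructed panel reproduces an all-but-one significance pattern", {
  # five clearly separated models plus one pair built to be indistinguishable
  ests <- list(
    b = sensitivity_estimate(0.20, 0.17, 0.23),
    den = sensitivity_estimate(0.31, 0.28, 0.34),
    deb = sensitivity_estimate(0.315, 0.285, 0.345),
    sa = sensitivity_estimate(0.26, 0.23, 0.29),
    wa = sensitivity_estimate(0.37, 0.34, 0.40),
    af = sensitivity_estimate(0.50, 0.47, 0.53))
  panel <- pairwise_panel(ests)
  insig <- panel[!panel$significant, ]
  expect_equal(nrow(insig), 1L)
  expect_setequal(c(insig$model_a, insig$model_b), c("den", "deb"))
})
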