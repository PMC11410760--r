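# Shared fixtures, generated in code at test time.

# a deterministic textured test image
fixture_image <- function(h = 32L, w = h, seed = 11L) {
  set.seed(seed)
  m <- matrix(runif(h * w), h, w)
  m <- 0.5 * m + 0.25 + 0.2 * sin(outer(seq_len(h), seq_len(w), "+") / 5)
  gray_image(pmin(pmax(m, 0), 1))
}

# a tiny split cohort for smoke training
fixture_cohort <- function(n = 24L, size = c(32L, 32L), prevalence = 0.5,
                           seed = 5L) {
  cohort <- generate_cohort(n, prevalence, size = size, seed = seed)
  patient_split(cohort, seed = seed)
}

# brute-force bilinear interpolation with half-pixel centers (oracle,
# independent of the package implementation)
oracle_bilinear <- function(m, h, w) {
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      sy <- min(max((i - 0.5) * nrow(m) / h - 0.5, 0), nrow(m) - 1)
      sx <- min(max((j - 0.5) * ncol(m) / w - 0.5, 0), ncol(m) - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      y1 <- min(y0 + 1, nrow(m) - 1); x1 <- min(x0 + 1, ncol(m) - 1)
      out[i, j] <- (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
        (1 - fy) * fx * m[y0 + 1, x1 + 1] +
        fy * (1 - fx) * m[y1 + 1, x0 + 1] +
        fy * fx * m[y1 + 1, x1 + 1]
    }
  }
  out
}

# direct normalized-Gaussian kernel evaluation (oracle)
oracle_gaussian_kernel <- function(k, sigma) {
  c0 <- (k - 1) / 2
  m <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- exp(-((i - 1 - c0)^2) / (2 * sigma^2)) *
               exp(-((j - 1 - c0)^2) / (2 * sigma^2))
  m / sum(m)
}
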