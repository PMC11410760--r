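# Full-reference image-quality metrics: MSE, MAE, PSNR, SSIM and HaarPSI.
#
# SSIM uses the de-facto standard settings: 11x11 Gaussian window with
# sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range L = 1 on the canonical
# scale, 'valid' sliding windows. PSNR is reported on the 0-255 scale
# (MAX = 255) to match the dB magnitudes conventional for 8-bit
# radiographs; conversion from the canonical [0,1] scale is internal.
# HaarPSI follows the three-scale Haar formulation with C = 30 and
# alpha = 4.2 on the 0-255 scale, grayscale path only.

iqa_as_matrix <- function(x) {
  if (is_gray_image(x)) return(as_gray_matrix(x))
  if (!is.numeric(x)) stop("expected a numeric image")
  as.matrix(x)
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
}

#' Mean squared / absolute error between two images
#'
#' Computed on whatever intensity scale the inputs use.
#'
#' @param gt,pred Images (matrices or [gray_image()]s) of equal shape.
#' @return A non-negative scalar.
#' @export
mse <- function(gt, pred) {
  gt <- iqa_as_matrix(gt); pred <- iqa_as_matrix(pred)
  check_same_shape(gt, pred)
  mean((gt - pred)^2)
}

#' @rdname mse
#' @export
mae <- function(gt, pred) {
  gt <- iqa_as_matrix(gt); pred <- iqa_as_matrix(pred)
  check_same_shape(gt, pred)
  mean(abs(gt - pred))
}

#' Peak signal-to-noise ratio in decibels
#'
#' Inputs are on the canonical \[0, 1\] scale and are internally mapped to
#' \[0, `max_val`\]; identical images return `Inf`.
#'
#' @param gt,pred Images of equal shape on the canonical \[0, 1\] scale.
#' @param max_val Maximum possible pixel value of the reporting scale
#'   (default 255 for 8-bit images).
#' @return PSNR in dB (`Inf` when the MSE is zero).
#' @export
psnr <- function(gt, pred, max_val = 255) {
  if (max_val <= 0) stop("max_val must be positive")
  m <- mse(iqa_as_matrix(gt) * max_val, iqa_as_matrix(pred) * max_val)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

# Gaussian SSIM window, normalized to sum 1
ssim_window <- function(size = 11L, sigma = 1.5) {
  c0 <- (size - 1) / 2
  g <- exp(-((seq_len(size) - 1 - c0)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# windowed 'valid' filtering of a matrix with an arbitrary kernel
filter_valid <- function(m, k) {
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  y <- dwconv_valid(x, k)
  matrix(y, dim(y)[1L], dim(y)[2L])
}

#' Structural similarity index
#'
#' Mean over 'valid' sliding windows of the local luminance/contrast/
#' structure statistic with `C1 = (K1*L)^2`, `C2 = (K2*L)^2`. Symmetric in
#' its arguments; 1 iff the images are identical.
#'
#' @param x,y Images of equal shape.
#' @param window Window size (odd, default 11) or a custom kernel matrix.
#' @param sigma Gaussian window sd (default 1.5); ignored for custom kernels.
#' @param K1,K2 Stability constants (defaults 0.01, 0.03).
#' @param L Dynamic range of the inputs (default 1, the canonical scale).
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 1) {
  x <- iqa_as_matrix(x); y <- iqa_as_matrix(y)
  check_same_shape(x, y)
  if (L <= 0) stop("L must be positive")
  k <- if (is.matrix(window)) window / sum(window)
       else ssim_window(as.integer(window), sigma)
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x))
    stop("window larger than image")
  mean(ssim_map(x, y, k, K1, K2, L))
}

ssim_map <- function(x, y, k, K1 = 0.01, K2 = 0.03, L = 1) {
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mx <- filter_valid(x, k); my <- filter_valid(y, k)
  sxx <- filter_valid(x * x, k) - mx^2
  syy <- filter_valid(y * y, k) - my^2
  sxy <- filter_valid(x * y, k) - mx * my
  ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
}

# ---- HaarPSI -------------------------------------------------------------

# 2-D Haar analysis filter at scale j: high-pass along rows, low-pass along
# columns (orientation 1), entries +/- 2^-j as in the reference
# formulation. Orientation 2 is the transpose.
haar_filter_2d <- function(scale) {
  n <- 2L^scale
  f <- matrix(2^(-scale), n, n)
  f[(n / 2 + 1):n, ] <- -f[(n / 2 + 1):n, ]
  f
}

# 'same'-size zero-padded correlation with an even-sized kernel
filter_same_even <- function(m, k) {
  p <- nrow(k) / 2
  x <- array(0, c(nrow(m) + 2 * p, ncol(m) + 2 * p, 1L, 1L))
  x[p + seq_len(nrow(m)), p + seq_len(ncol(m)), 1L, 1L] <- m
  y <- cpp_dwconv_fw(x, k)
  # valid output is (H + p + 1) x (W + p + 1); center-crop to H x W
  matrix(y[seq_len(nrow(m)) + 1L, seq_len(ncol(m)) + 1L, 1L, 1L],
         nrow(m), ncol(m))
}

# non-overlapping 2x2 mean subsampling (odd trailing row/col dropped)
subsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
          m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)])
}

#' Haar wavelet-based perceptual similarity index
#'
#' Three-scale Haar decomposition on 2x-subsampled 0-255 intensities: local
#' similarities from the two high-frequency scales via
#' `(2*g1*g2 + C) / (g1^2 + g2^2 + C)`, importance weights from the
#' third-scale coefficient magnitudes (maximum over the two images), logistic
#' mapping with steepness `alpha` and inverse-logistic-squared aggregation of
#' the weighted mean.
#'
#' @param gt,pred Images of equal shape on the canonical \[0, 1\] scale,
#'   minimum dimension 8.
#' @param C Stability constant (default 30, on the 0-255 coefficient scale).
#' @param alpha Logistic steepness (default 4.2).
#' @return HaarPSI in \[0, 1\]; 1 iff perceptually identical.
#' @export
haarpsi <- function(gt, pred, C = 30, alpha = 4.2) {
  a <- iqa_as_matrix(gt) * 255
  b <- iqa_as_matrix(pred) * 255
  check_same_shape(a, b)
  if (min(dim(a)) < 8L) stop("image too small for HaarPSI (min dim 8)")
  a <- subsample2(a); b <- subsample2(b)
  num <- 0; den <- 0
  for (orient in 1:2) {
    coef_a <- vector("list", 3L); coef_b <- vector("list", 3L)
    for (j in 1:3) {
      f <- haar_filter_2d(j)
      if (orient == 2L) f <- t(f)
      coef_a[[j]] <- abs(filter_same_even(a, f))
      coef_b[[j]] <- abs(filter_same_even(b, f))
    }
    s1 <- (2 * coef_a[[1]] * coef_b[[1]] + C) /
      (coef_a[[1]]^2 + coef_b[[1]]^2 + C)
    s2 <- (2 * coef_a[[2]] * coef_b[[2]] + C) /
      (coef_a[[2]]^2 + coef_b[[2]]^2 + C)
    hs <- (s1 + s2) / 2
    w <- pmax(coef_a[[3]], coef_b[[3]])
    num <- num + sum(w / (1 + exp(-alpha * hs)))
    den <- den + sum(w)
  }
  q <- num / den
  (log(q / (1 - q)) / alpha)^2
}

#' Full quality report for one image pair
#'
#' @param gt,pred Images of equal shape on the canonical \[0, 1\] scale.
#' @return A one-row data.frame with psnr (dB at MAX = 255), ssim, haarpsi,
#'   and mse/mae on the canonical scale.
#' @export
quality_report <- function(gt, pred) {
  data.frame(psnr = psnr(gt, pred), ssim = ssim(gt, pred),
             haarpsi = haarpsi(gt, pred),
             mse = mse(iqa_as_matrix(gt), iqa_as_matrix(pred)),
             mae = mae(iqa_as_matrix(gt), iqa_as_matrix(pred)))
}
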