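# Stochastic Gaussian-noise and Gaussian-blur degradation producing paired
# restoration datasets.
#
# Noise: out = clip(img + factor * N(0, 1), 0, 1), i.i.d. per pixel. The
# clip is a documented choice: saving requires valid intensities and the
# alternative (linear rescale) would change clean pixels too.
# Blur: 2-D convolution with a normalized Gaussian kernel whose sigma
# follows the kernel-size rule sigma = 0.3 * ((k - 1)/2 - 1) + 0.8, with
# reflect-101 borders.

#' Specify the noise degradation
#'
#' @param variance_factors Positive scale factors applied to unit-variance
#'   Gaussian noise; the study default is `c(0.02, 0.04, 0.06, 0.08, 0.1)`.
#' @param seed Integer seed for per-image parameter draws.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(variance_factors = c(0.02, 0.04, 0.06, 0.08, 0.1),
                       seed = 1L) {
  if (length(variance_factors) == 0L) stop("empty parameter list")
  if (any(variance_factors <= 0)) stop("variance factors must be positive")
  structure(list(mode = "noise", parameters = variance_factors,
                 seed = as.integer(seed)), class = "degrade_spec")
}

#' Specify the blur degradation
#'
#' @param kernel_sizes Odd kernel sizes >= 3; the study default is
#'   `c(3, 5, 7, 9)`.
#' @param seed Integer seed for per-image parameter draws.
#' @return An object of class `blur_spec`.
#' @export
blur_spec <- function(kernel_sizes = c(3L, 5L, 7L, 9L), seed = 1L) {
  if (length(kernel_sizes) == 0L) stop("empty parameter list")
  if (any(kernel_sizes %% 2 == 0) || any(kernel_sizes < 3))
    stop("kernel sizes must be odd and >= 3")
  structure(list(mode = "blur", parameters = as.integer(kernel_sizes),
                 seed = as.integer(seed)), class = "degrade_spec")
}

#' Add scaled Gaussian noise to an image
#'
#' @param img A [gray_image()].
#' @param variance_factor Positive noise scale (std of the added noise).
#' @param seed Integer seed; same seed gives an identical output.
#' @return The degraded [gray_image()], clipped to \[0, 1\].
#' @export
add_gaussian_noise <- function(img, variance_factor, seed = 1L) {
  if (!is_gray_image(img)) img <- gray_image(img)
  if (variance_factor <= 0) stop("variance factor must be positive")
  m <- as_gray_matrix(img)
  noise <- with_seed(seed, stats::rnorm(length(m)))
  out <- m + variance_factor * matrix(noise, nrow(m), ncol(m))
  gray_image(pmin(pmax(out, 0), 1), source_depth = attr(img, "source_depth"))
}

# sigma rule tied to kernel size (the auto-sigma convention)
blur_sigma <- function(kernel_size) 0.3 * ((kernel_size - 1) / 2 - 1) + 0.8

#' Normalized 2-D Gaussian kernel
#'
#' @param kernel_size Odd size >= 3.
#' @param sigma Standard deviation; defaults to the kernel-size rule
#'   `0.3 * ((k - 1)/2 - 1) + 0.8`.
#' @return A `kernel_size` x `kernel_size` matrix summing to 1.
#' @export
gaussian_kernel <- function(kernel_size, sigma = blur_sigma(kernel_size)) {
  if (kernel_size %% 2 == 0 || kernel_size < 3)
    stop("kernel size must be odd and >= 3")
  c0 <- (kernel_size - 1) / 2
  g <- exp(-((seq_len(kernel_size) - 1 - c0)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Blur an image with a Gaussian kernel
#'
#' @param img A [gray_image()].
#' @param kernel_size Odd kernel size >= 3; sigma follows the kernel-size
#'   rule.
#' @return The blurred [gray_image()].
#' @export
add_gaussian_blur <- function(img, kernel_size) {
  if (!is_gray_image(img)) img <- gray_image(img)
  k <- gaussian_kernel(kernel_size)
  m <- as_gray_matrix(img)
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  p <- (kernel_size - 1L) / 2L
  y <- cpp_dwconv_fw(cpp_pad_reflect_fw(x, as.integer(p)), k)
  gray_image(pmin(pmax(matrix(y, nrow(m), ncol(m)), 0), 1),
             source_depth = attr(img, "source_depth"))
}

#' Degrade a set of images into restoration pairs
#'
#' For each image one parameter (variance factor or kernel size) is drawn
#' uniformly from the spec's list. Draws use a dedicated substream per image
#' index, so reordering or subsetting the dataset does not reshuffle the
#' remaining draws.
#'
#' @param images Named list of [gray_image()]s.
#' @param spec A [noise_spec()] or [blur_spec()].
#' @return A list of paired samples, each a list with `degraded`, `clean`,
#'   `applied_parameter` and `image_id`.
#' @export
degrade_dataset <- function(images, spec) {
  stopifnot(inherits(spec, "degrade_spec"))
  if (length(images) == 0L) stop("empty image list")
  ids <- names(images) %||% sprintf("img%04d", seq_along(images))
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    par_i <- with_seed(derive_seed(spec$seed, paste0("draw/", i)),
                       sample(spec$parameters, 1L))
    img <- images[[i]]
    degraded <- if (spec$mode == "noise") {
      add_gaussian_noise(img, par_i,
                         seed = derive_seed(spec$seed, paste0("noise/", i)))
    } else {
      add_gaussian_blur(img, par_i)
    }
    out[[i]] <- list(degraded = degraded, clean = img,
                     applied_parameter = par_i, image_id = ids[i])
  }
  out
}

#' Write degraded images and a manifest
#'
#' @param pairs Output of [degrade_dataset()].
#' @param spec The degradation spec used.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_degraded <- function(pairs, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in pairs)
    save_image(p$degraded, file.path(dir, paste0(p$image_id, ".png")))
  manifest <- data.frame(
    image_id = vapply(pairs, `[[`, character(1), "image_id"),
    mode = spec$mode,
    applied_parameter = vapply(pairs, `[[`, numeric(1), "applied_parameter"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
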