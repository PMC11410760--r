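# Image and table I/O, the canonical intensity representation, resizing,
# mask-based cropping, run configuration and logging.
#
# Conventions used package-wide: intensities are doubles in [0, 1] (the 0-255
# scale exists only at file boundaries); pixel coordinates are row-major,
# 0-based, inclusive; RGB inputs collapse to gray by the unweighted channel
# mean; quantization at save time rounds half away from zero.

#' Construct a grayscale image
#'
#' The canonical in-memory image type: a numeric matrix of intensities in
#' \[0, 1\] with the source bit depth recorded as an attribute.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param source_depth Bit depth of the originating file (default 8).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, source_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("zero-size image")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  structure(pixels, source_depth = as.integer(source_depth),
            class = c("gray_image", "matrix", "array"))
}

is_gray_image <- function(x) inherits(x, "gray_image")

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, depth %d, range [%.4f, %.4f]>\n",
              nrow(x), ncol(x), attr(x, "source_depth"),
              min(x), max(x)))
  invisible(x)
}

as_gray_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "source_depth") <- NULL
  m
}

#' Load a PNG or JPEG image as a grayscale image
#'
#' Single-channel files are used as-is; RGB(A) files are collapsed by the
#' unweighted mean of the color channels. Values arrive on the canonical
#' \[0, 1\] scale (the decoder divides by `2^depth - 1`).
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  depth <- 8L
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth)) depth <- as.integer(info$bit.depth)
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- jpeg::readJPEG(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(arr)) == 3L) {
    nc <- min(dim(arr)[3L], 3L)  # drop alpha from the luminance average
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  if (length(arr) == 0L) stop("zero-size image: ", path)
  gray_image(pmin(pmax(arr, 0), 1), source_depth = depth)
}

#' Save a grayscale image as an 8-bit PNG
#'
#' Quantizes to 0-255 rounding half away from zero, so a load/save round trip
#' differs by less than 1/255 per pixel.
#'
#' @param img A [gray_image()].
#' @param path Destination `.png` path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (!is_gray_image(img)) img <- gray_image(img)
  q <- floor(as_gray_matrix(img) * 255 + 0.5)  # values are non-negative
  png::writePNG(q / 255, path)
  invisible(path)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Uses half-pixel-center sampling (source coordinate
#' `(i + 0.5) * scale - 0.5`, clamped), the convention shared with the
#' Score-CAM upsampler.
#'
#' @param img A [gray_image()].
#' @param size Target `(height, width)`, positive integers.
#' @return The resized [gray_image()].
#' @export
resize <- function(img, size) {
  if (!is_gray_image(img)) img <- gray_image(img)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) stop("size must be two positive integers")
  m <- as_gray_matrix(img)
  out <- bilinear_resize_matrix(m, size[1L], size[2L])
  gray_image(pmin(pmax(out, 0), 1), source_depth = attr(img, "source_depth"))
}

# interpolation weight matrix mapping n_src samples onto n_dst positions
bilinear_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  pos <- (seq_len(n_dst) - 0.5) * scale - 0.5
  pos <- pmin(pmax(pos, 0), n_src - 1)
  i0 <- pmin(floor(pos), n_src - 1)
  fr <- pos - i0
  i1 <- pmin(i0 + 1, n_src - 1)
  W <- matrix(0, n_dst, n_src)
  W[cbind(seq_len(n_dst), i0 + 1)] <- W[cbind(seq_len(n_dst), i0 + 1)] + (1 - fr)
  W[cbind(seq_len(n_dst), i1 + 1)] <- W[cbind(seq_len(n_dst), i1 + 1)] + fr
  W
}

bilinear_resize_matrix <- function(m, h, w) {
  Wy <- bilinear_weights(nrow(m), h)
  Wx <- bilinear_weights(ncol(m), w)
  Wy %*% m %*% t(Wx)
}

#' Crop an image to the bounding box of a binary mask
#'
#' Returns the tight axis-aligned sub-image covering all true mask pixels.
#'
#' @param img A [gray_image()].
#' @param mask Logical (or 0/1) matrix of the same shape with at least one
#'   true pixel.
#' @return The cropped [gray_image()].
#' @export
crop_to_mask_bbox <- function(img, mask) {
  if (!is_gray_image(img)) img <- gray_image(img)
  mask <- mask > 0
  if (!all(dim(mask) == dim(img))) stop("mask shape must match image shape")
  if (!any(mask)) stop("mask has no true pixels")
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1L]); cc <- range(idx[, 2L])
  gray_image(as_gray_matrix(img)[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE],
             source_depth = attr(img, "source_depth"))
}

# ---- label and box tables ------------------------------------------------

#' Read a label table
#'
#' Expects a CSV with header `image_id,patient_id,label` (and optionally
#' `split`). Labels must be binary: 0 = normal, 1 = abnormal.
#'
#' @param path CSV path.
#' @return A data.frame with columns image_id, patient_id, label, split.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character",
                                       patient_id = "character"))
  validate_label_table(df)
}

validate_label_table <- function(df) {
  need <- c("image_id", "patient_id", "label")
  if (!all(need %in% names(df)))
    stop("label table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (any(!nzchar(df$patient_id))) stop("patient_id must be non-empty")
  if (is.null(df$split)) df$split <- "unassigned"
  stopifnot(all(df$split %in% c("train", "val", "test", "unassigned")))
  df
}

#' @rdname read_label_table
#' @param df Label table data.frame.
#' @export
write_label_table <- function(df, path) {
  utils::write.csv(validate_label_table(df), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a bounding-box table
#'
#' CSV dialect with header `image_id,x_min,y_min,x_max,y_max`; `x` indexes
#' columns, `y` rows, 0-based inclusive.
#'
#' @param path CSV path.
#' @return A data.frame of boxes.
#' @export
read_box_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(df)))
    stop("box table needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_box_table
#' @param df Box table data.frame.
#' @export
write_box_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration, seeds, logging -----------------------------------

#' Create a run configuration
#'
#' One global seed drives every stage; each stochastic operation derives its
#' own substream with [derive_seed()] so that re-running a single stage
#' reproduces its randomness regardless of what ran before.
#'
#' @param seed Global integer seed.
#' @param image_size Working image size `(h, w)`; the full-scale default is
#'   224 x 224.
#' @param paths Named list of directories used by the pipeline.
#' @param stages Named list of per-stage hyperparameter lists.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, image_size = c(224L, 224L),
                       paths = list(), stages = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 paths = paths, stages = stages),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(seed = y$seed %||% 1L,
             image_size = unlist(y$image_size %||% c(224L, 224L)),
             paths = y$paths %||% list(),
             stages = y$stages %||% list())
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from the global seed
#'
#' Deterministic mixing of the global seed with a stage name; results stay
#' below 2^31 so they are valid R integer seeds.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name (e.g. `"degrade"`, `"pretext/init"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

log_line <- function(logfile, stage, level, msg) {
  line <- sprintf("%s [%s] %s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, level, msg)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
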