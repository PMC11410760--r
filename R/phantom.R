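# Synthetic chest-like phantoms and labeled cohorts.
#
# The phantom is deliberately minimal: two bright lung-field ellipses on a
# darker background, horizontal rib-like banding inside the lung fields, mild
# pixel noise, and (for abnormal phantoms) one or more Gaussian-profile focal
# opacities placed inside a lung field. It emulates the contrast structure
# the restorer and classifier must exploit, not radiological realism.

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specify a synthetic chest phantom
#'
#' Defaults state the simulated world used throughout the tests: a dark
#' background (0.2), brighter lung fields (0.6), seven rib bands of amplitude
#' 0.08, additive pixel noise of sd 0.02, and focal opacities of amplitude
#' 0.25 with radii between 6% and 12% of the image height.
#'
#' @param size Image `(h, w)` in pixels.
#' @param abnormal Logical; abnormal phantoms carry focal opacities.
#' @param opacity_count Number of opacities (must be 0 when `abnormal` is
#'   FALSE, at least 1 when TRUE).
#' @param opacity_radius_range Opacity radius interval in pixels.
#' @param background_level,lung_level Base intensities in \[0, 1\].
#' @param rib_count Number of rib-like bands across the lung fields.
#' @param noise_sd Additive Gaussian texture noise sd.
#' @param opacity_amplitude Peak intensity added by each opacity.
#' @param seed Integer seed; phantom generation is a pure function of the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L), abnormal = FALSE,
                         opacity_count = if (abnormal) 1L else 0L,
                         opacity_radius_range = NULL,
                         background_level = 0.2, lung_level = 0.6,
                         rib_count = 7L, noise_sd = 0.02,
                         opacity_amplitude = 0.25, seed = 1L) {
  size <- as.integer(size)
  if (is.null(opacity_radius_range))
    opacity_radius_range <- c(max(2, round(0.06 * size[1L])),
                              max(3, round(0.12 * size[1L])))
  if (!abnormal && opacity_count != 0L)
    stop("normal phantoms must have opacity_count = 0")
  if (abnormal && opacity_count < 1L)
    stop("abnormal phantoms need at least one opacity")
  if (max(opacity_radius_range) >= min(size) / 2)
    stop("opacity radius too large for the image size")
  stopifnot(background_level >= 0, background_level <= 1,
            lung_level >= 0, lung_level <= 1)
  structure(list(size = size, abnormal = abnormal,
                 opacity_count = as.integer(opacity_count),
                 opacity_radius_range = opacity_radius_range,
                 background_level = background_level,
                 lung_level = lung_level, rib_count = as.integer(rib_count),
                 noise_sd = noise_sd, opacity_amplitude = opacity_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one chest phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [gray_image()]) and `boxes`, a data.frame
#'   of 0-based inclusive opacity bounding boxes (columns row_min, col_min,
#'   row_max, col_max); empty for normal phantoms.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  with_seed(spec$seed, {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    img <- matrix(spec$background_level, h, w)
    # two lung-field ellipses, slightly jittered but left/right symmetric
    cy <- 0.55 * h * (1 + stats::runif(1, -0.02, 0.02))
    ay <- 0.30 * h * (1 + stats::runif(1, -0.05, 0.05))
    ax <- 0.16 * w * (1 + stats::runif(1, -0.05, 0.05))
    centers_x <- c(0.30, 0.70) * w
    lung <- matrix(FALSE, h, w)
    for (cx in centers_x)
      lung <- lung | (((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1)
    img[lung] <- spec$lung_level
    # rib-like horizontal banding inside the lung fields
    band <- 0.08 * sin(2 * pi * spec$rib_count * rr / h)
    img[lung] <- img[lung] + band[lung]
    # focal opacities (abnormal phantoms only)
    boxes <- data.frame(row_min = integer(0), col_min = integer(0),
                        row_max = integer(0), col_max = integer(0))
    if (spec$opacity_count > 0L) {
      for (i in seq_len(spec$opacity_count)) {
        side <- if (i %% 2L == 1L) 1L else 2L
        cx <- centers_x[side] + stats::runif(1, -0.4, 0.4) * ax
        cyo <- cy + stats::runif(1, -0.5, 0.5) * ay
        rad <- stats::runif(1, spec$opacity_radius_range[1L],
                            spec$opacity_radius_range[2L])
        blob <- spec$opacity_amplitude *
          exp(-((rr - cyo)^2 + (cc - cx)^2) / (2 * (rad / 2)^2))
        img <- img + blob
        boxes <- rbind(boxes, data.frame(
          row_min = max(0L, floor(cyo - rad)),
          col_min = max(0L, floor(cx - rad)),
          row_max = min(h - 1L, ceiling(cyo + rad)),
          col_max = min(w - 1L, ceiling(cx + rad))))
      }
    }
    img <- img + stats::rnorm(h * w, sd = spec$noise_sd)
    list(image = gray_image(pmin(pmax(img, 0), 1)), boxes = boxes)
  })
}

#' Generate a labeled phantom cohort
#'
#' Produces `floor(n * prevalence)` abnormal phantoms; images are grouped
#' under patient identifiers with 1 to `max(images_per_patient)` images each.
#'
#' @param n Number of images (> 0).
#' @param prevalence Fraction of abnormal images in \[0, 1\].
#' @param size Phantom size `(h, w)`.
#' @param images_per_patient Integer range of images per patient.
#' @param seed Integer seed.
#' @return An object of class `phantom_cohort`: list with `records` (a label
#'   table data.frame), `images` (named list of [gray_image()]), and
#'   `truth_boxes` (named list of box data.frames for abnormal images).
#' @export
generate_cohort <- function(n, prevalence, size = c(64L, 64L),
                            images_per_patient = c(1L, 3L), seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  n <- as.integer(n)
  n_ab <- floor(n * prevalence)
  with_seed(derive_seed(seed, "cohort/patients"), {
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, sample(seq(images_per_patient[1L],
                                   images_per_patient[2L]), 1L))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0L]
    patient_of <- rep(seq_along(sizes), sizes)
    labels <- sample(c(rep(1L, n_ab), rep(0L, n - n_ab)))
  })
  image_ids <- sprintf("img%04d", seq_len(n))
  records <- data.frame(
    image_id = image_ids,
    patient_id = sprintf("P%04d", patient_of),
    label = labels,
    split = "unassigned",
    stringsAsFactors = FALSE)
  images <- vector("list", n); names(images) <- image_ids
  truth_boxes <- list()
  for (i in seq_len(n)) {
    ab <- labels[i] == 1L
    k <- if (ab) 1L + (derive_seed(seed, paste0("nblob/", i)) %% 2L) else 0L
    sp <- phantom_spec(size = size, abnormal = ab, opacity_count = k,
                       seed = derive_seed(seed, paste0("phantom/", i)))
    ph <- generate_phantom(sp)
    images[[i]] <- ph$image
    if (ab) truth_boxes[[image_ids[i]]] <- ph$boxes
  }
  structure(list(records = records, images = images,
                 truth_boxes = truth_boxes),
            class = "phantom_cohort")
}

#' Assign patient-level train/validation/test splits
#'
#' Patients are shuffled with the stage seed and greedily assigned to the
#' split whose image count is furthest below its target fraction, so no
#' patient ever spans two splits and image counts deviate from the targets by
#' at most the largest patient's image count.
#'
#' @param cohort A `phantom_cohort` (or any list with a `records` label
#'   table).
#' @param fractions Train/val/test fractions summing to 1; the study default
#'   is 70/10/20.
#' @param seed Integer seed for the patient shuffle.
#' @return The cohort with `records$split` filled in.
#' @export
patient_split <- function(cohort, fractions = c(0.70, 0.10, 0.20),
                          seed = 1L) {
  records <- cohort$records
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  patients <- unique(records$patient_id)
  if (length(patients) < 3L) stop("need at least 3 patients to split")
  counts <- table(records$patient_id)
  shuffled <- with_seed(derive_seed(seed, "split"),
                        sample(patients, length(patients)))
  total <- nrow(records)
  target <- fractions * total
  assigned <- c(train = 0, val = 0, test = 0)
  split_of <- character(length(shuffled))
  names(split_of) <- shuffled
  for (p in shuffled) {
    deficit <- target - assigned
    s <- names(which.max(deficit))
    split_of[p] <- s
    assigned[s] <- assigned[s] + counts[[p]]
  }
  records$split <- unname(split_of[records$patient_id])
  cohort$records <- records
  cohort
}

#' Write a cohort to disk
#'
#' Emits one PNG per image plus `labels.csv` and (when abnormal images are
#' present) `boxes.csv` in the x/y dialect read back by [read_box_table()]
#' (`x` = column, `y` = row, 0-based inclusive).
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$images))
    save_image(cohort$images[[id]], file.path(dir, paste0(id, ".png")))
  write_label_table(cohort$records, file.path(dir, "labels.csv"))
  if (length(cohort$truth_boxes) > 0) {
    boxes <- do.call(rbind, lapply(names(cohort$truth_boxes), function(id) {
      b <- cohort$truth_boxes[[id]]
      data.frame(image_id = id, x_min = b$col_min, y_min = b$row_min,
                 x_max = b$col_max, y_max = b$row_max)
    }))
    write_box_table(boxes, file.path(dir, "boxes.csv"))
  }
  invisible(dir)
}
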