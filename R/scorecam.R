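# Score-CAM weak localization: channel-wise masked forward passes weight the
# deepest conv-layer activations; the weighted map is converted to a single
# bounding box by thresholded extreme points. Gradient-free by construction:
# only forward evaluations of the classifier are used.

#' Construct a bounding box
#'
#' Pixel coordinates are row-major, 0-based and inclusive (the package-wide
#' convention).
#'
#' @param row_min,col_min,row_max,col_max Corner indices with
#'   `row_min <= row_max`, `col_min <= col_max`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(row_min, col_min, row_max, col_max) {
  if (row_min > row_max || col_min > col_max) stop("invalid box extents")
  if (row_min < 0 || col_min < 0) stop("box indices must be non-negative")
  structure(list(row_min = as.integer(row_min), col_min = as.integer(col_min),
                 row_max = as.integer(row_max), col_max = as.integer(col_max)),
            class = "bounding_box")
}

minmax_normalize <- function(m) {
  r <- range(m)
  if (r[2L] - r[1L] <= 0) return(NULL)
  (m - r[1L]) / (r[2L] - r[1L])
}

#' Score-CAM activation map
#'
#' For each channel of the deepest convolutional layer: upsample its
#' activation to the input size, min-max normalize it, mask the input by
#' elementwise product, forward-pass the masked input and record the
#' target-class softmax score as the channel weight. The map is the min-max
#' normalized ReLU of the weighted sum of upsampled activations. Constant
#' channels receive zero weight; if every channel is constant an all-zero
#' map is returned with a warning.
#'
#' @param model A `classifier_model`.
#' @param image A [gray_image()] or matrix at the model input size.
#' @param target_class 0 (normal) or 1 (abnormal).
#' @param batch_size Masked inputs evaluated per forward batch; the result
#'   equals the per-channel sequential computation.
#' @return A matrix in \[0, 1\] of the input shape with attributes
#'   `target_class` and `source_layer`.
#' @export
score_cam <- function(model, image, target_class = 1L, batch_size = 32L) {
  m <- if (is_gray_image(image)) as_gray_matrix(image) else as.matrix(image)
  h <- nrow(m); w <- ncol(m)
  ad_reset_tape()
  tap <- classifier_forward_node(model, ad_const(promote_batch(m)),
                                 taps = TRUE)
  acts <- tap$conv$val            # (h', w', C, 1)
  C <- dim(acts)[3L]
  ups <- vector("list", C)
  masks <- vector("list", C)
  for (k in seq_len(C)) {
    a_k <- matrix(acts[, , k, 1L], dim(acts)[1L], dim(acts)[2L])
    up <- bilinear_resize_matrix(a_k, h, w)
    ups[[k]] <- up
    masks[[k]] <- minmax_normalize(up)
  }
  live <- which(!vapply(masks, is.null, logical(1)))
  weights <- numeric(C)
  col <- target_class + 1L
  if (length(live) > 0L) {
    for (start in seq(1L, length(live), by = batch_size)) {
      idx <- live[start:min(start + batch_size - 1L, length(live))]
      xb <- array(0, c(h, w, 1L, length(idx)))
      for (j in seq_along(idx)) xb[, , 1L, j] <- m * masks[[idx[j]]]
      pr <- classifier_predict(model, xb)
      weights[idx] <- pr$probs[, col]
    }
  }
  cam <- matrix(0, h, w)
  for (k in seq_len(C)) cam <- cam + weights[k] * ups[[k]]
  cam <- pmax(cam, 0)
  norm <- minmax_normalize(cam)
  if (is.null(norm)) {
    warning("all activation channels constant; returning an all-zero map")
    norm <- matrix(0, h, w)
  }
  structure(norm, target_class = as.integer(target_class),
            source_layer = "encoder_block5")
}

#' Convert an activation map to a bounding box
#'
#' Binarizes the map at `rel_threshold * max(map)` and spans the extreme
#' surviving rows and columns.
#'
#' @param map Activation map matrix (e.g. from [score_cam()]).
#' @param rel_threshold Relative threshold in (0, 1); default 0.2.
#' @return A [bounding_box()] (0-based inclusive).
#' @export
map_to_bbox <- function(map, rel_threshold = 0.2) {
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  mx <- max(map)
  keep <- which(map >= rel_threshold * mx & map > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) stop("no pixels survive the threshold")
  bounding_box(min(keep[, 1L]) - 1L, min(keep[, 2L]) - 1L,
               max(keep[, 1L]) - 1L, max(keep[, 2L]) - 1L)
}

#' Intersection-over-union of two boxes
#'
#' Inclusive pixel counting: a box spanning rows 0..9 is 10 pixels tall.
#'
#' @param a,b [bounding_box()]s (or lists with the same fields).
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ih <- min(a$row_max, b$row_max) - max(a$row_min, b$row_min) + 1L
  iw <- min(a$col_max, b$col_max) - max(a$col_min, b$col_min) + 1L
  inter <- max(0L, ih) * max(0L, iw)
  area <- function(x) (x$row_max - x$row_min + 1L) * (x$col_max - x$col_min + 1L)
  un <- area(a) + area(b) - inter
  inter / un
}
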