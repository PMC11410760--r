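# The VGG-16 Sharp-U-Net restoration architecture.
#
# Encoder: five VGG-16 blocks ([2,2,3,3,3] 3x3 convs with ReLU, 64/128/256/
# 512/512 filters, 2x2 max-pool after blocks 1-4 only). Decoder: four
# up-blocks (2x2 stride-2 transposed convolution, then [3,3,2,2] 3x3 convs
# with ReLU, widths mirroring the encoder). Skip connections carry each
# encoder block's pre-pool activation through a fixed 3x3 sharpening
# depth-wise convolution (no learnable parameters) and are concatenated to
# the up-sampled decoder features. Head: one 3x3 conv + sigmoid to 1
# channel. A width multiplier scales all filter counts for desk-scale runs.

#' The fixed 3x3 sharpening kernel
#'
#' Coefficients `[0 -1 0; -1 5 -1; 0 -1 0]`: sums to 1 (constants pass
#' through unchanged), center 5, a discrete identity-plus-Laplacian that
#' accentuates adjacent-pixel differences.
#'
#' @return A 3x3 numeric matrix.
#' @export
sharpen_kernel <- function() {
  matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
}

#' Sharpen feature maps channel-by-channel
#'
#' Depth-wise convolution of every channel with [sharpen_kernel()], same-size
#' output via reflect-101 padding. Adds no learnable parameters.
#'
#' @param features A `(H, W, C)` or `(H, W, C, N)` numeric array with at
#'   least one channel.
#' @return An array of the same shape.
#' @export
sharpen_features <- function(features) {
  d <- dim(features)
  if (is.null(d) || length(d) < 3L) stop("expected a (H, W, C[, N]) array")
  x <- if (length(d) == 3L) array(features, c(d, 1L)) else features
  y <- cpp_dwconv_fw(cpp_pad_reflect_fw(x, 1L), sharpen_kernel())
  array(y, d)
}

# tensor-graph version used inside the forward pass
op_sharpen <- function(x) op_dwconv_fixed(op_pad_reflect(x, 1L), sharpen_kernel())

enc_block_conv_counts <- c(2L, 2L, 3L, 3L, 3L)
enc_block_filters <- c(64L, 128L, 256L, 512L, 512L)
dec_block_conv_counts <- c(3L, 3L, 2L, 2L)

scaled_filters <- function(width_multiplier) {
  f <- pmax(1L, as.integer(round(enc_block_filters * width_multiplier)))
  f
}

build_encoder_blocks <- function(in_channels, filters) {
  blocks <- vector("list", 5L)
  cin <- in_channels
  for (b in 1:5) {
    convs <- vector("list", enc_block_conv_counts[b])
    for (l in seq_len(enc_block_conv_counts[b])) {
      convs[[l]] <- layer_conv(3L, 3L, cin, filters[b], pad = 1L)
      cin <- filters[b]
    }
    blocks[[b]] <- convs
  }
  blocks
}

#' Build the Sharp-U-Net restorer
#'
#' @param input_size Input `(h, w)`, both divisible by 16 (four poolings).
#' @param width_multiplier Scales all filter counts; 1 is the full
#'   architecture, 1/8 is the desk-scale variant used in the tests.
#' @param seed Integer seed for the random weight initialization.
#' @return An object of class `restorer_model`.
#' @export
build_restorer <- function(input_size = c(224L, 224L), width_multiplier = 1,
                           seed = 1L) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 16L != 0L))
    stop("input size must be divisible by 16")
  filters <- scaled_filters(width_multiplier)
  with_seed(seed, {
    enc <- build_encoder_blocks(1L, filters)
    # decoder stage i up-samples and receives encoder block (5 - i) skips
    dec <- vector("list", 4L)
    cin <- filters[5]
    for (i in 1:4) {
      skip_b <- 5L - i
      width <- filters[skip_b]  # mirrored decoder widths
      up <- layer_upconv(cin, width)
      convs <- vector("list", dec_block_conv_counts[i])
      c_in <- width + filters[skip_b]  # concat with sharpened skip
      for (l in seq_len(dec_block_conv_counts[i])) {
        convs[[l]] <- layer_conv(3L, 3L, c_in, width, pad = 1L)
        c_in <- width
      }
      dec[[i]] <- list(up = up, convs = convs)
      cin <- width
    }
    head <- layer_conv(3L, 3L, filters[1], 1L, pad = 1L)
    structure(list(kind = "sharp_unet", input_size = input_size,
                   width_multiplier = width_multiplier, filters = filters,
                   enc = enc, dec = dec, head = head,
                   sharpen = TRUE),
              class = "restorer_model")
  })
}

# Encoder forward shared by the restorer and the classifiers. Returns the
# block-5 output tensor plus each block's pre-pool activation when tapped.
encoder_forward <- function(enc, x, taps = FALSE) {
  acts <- vector("list", 5L)
  h <- as_tensor(x)
  for (b in 1:5) {
    for (conv in enc[[b]])
      h <- op_relu(op_conv2d(h, conv$w, conv$b, pad = conv$pad))
    acts[[b]] <- h          # pre-pool activation
    if (b < 5L) h <- op_maxpool2(h)
  }
  if (taps) list(out = h, acts = acts) else list(out = h)
}

#' Forward pass of the restorer
#'
#' @param model A `restorer_model`.
#' @param x Input batch: `(H, W, 1, N)` array in \[0, 1\] (a single matrix
#'   is promoted).
#' @param taps Return encoder block activations alongside the output.
#' @return The restored `(H, W, 1, N)` array in (0, 1), or a list with
#'   `output` and `acts` when `taps = TRUE`.
#' @export
restorer_forward <- function(model, x, taps = FALSE) {
  ad_reset_tape()
  x <- promote_batch(x)
  node <- restorer_forward_node(model, ad_const(x), taps = taps)
  if (taps) {
    list(output = node$out$val,
         acts = lapply(node$acts, function(a) a$val))
  } else {
    node$out$val
  }
}

# graph-building forward used by both inference and training
restorer_forward_node <- function(model, x, taps = FALSE) {
  ef <- encoder_forward(model$enc, x, taps = TRUE)
  h <- ef$out
  for (i in 1:4) {
    stage <- model$dec[[i]]
    h <- op_upconv2(h, stage$up$w, stage$up$b)
    skip <- ef$acts[[5L - i]]
    if (isTRUE(model$sharpen)) skip <- op_sharpen(skip)
    h <- op_concat_c(h, skip)
    for (conv in stage$convs)
      h <- op_relu(op_conv2d(h, conv$w, conv$b, pad = conv$pad))
  }
  out <- op_sigmoid(op_conv2d(h, model$head$w, model$head$b,
                              pad = model$head$pad))
  if (taps) list(out = out, acts = ef$acts) else list(out = out)
}

promote_batch <- function(x) {
  if (is_gray_image(x)) x <- as_gray_matrix(x)
  d <- dim(x)
  if (length(d) == 2L) {
    array(x, c(d, 1L, 1L))
  } else if (length(d) == 3L) {
    array(x, c(d[1L], d[2L], 1L, d[3L]))
  } else x
}

# stack a list of gray images into a (H, W, 1, N) batch
stack_images <- function(images) {
  mats <- lapply(images, as_gray_matrix)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  arr <- array(0, c(h, w, 1L, length(mats)))
  for (i in seq_along(mats)) arr[, , 1L, i] <- mats[[i]]
  arr
}
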