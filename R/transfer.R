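# Transfer of the restorer encoder to a binary classifier: truncation at the
# deepest convolutional layer, GAP + 2-node softmax head, SGD fine-tuning
# with the plateau schedule. All encoder layers stay trainable during
# fine-tuning; the baseline variant differs only in its init_source.

# deep-copy any nested layer structure, duplicating parameter tensors
clone_params <- function(x) {
  if (inherits(x, "ad_tensor")) return(ad_param(x$val))
  if (is.list(x) && !is.null(attr(x, "class"))) {
    y <- lapply(x, clone_params)
    attributes(y) <- attributes(x)
    return(y)
  }
  if (is.list(x)) return(lapply(x, clone_params))
  x
}

#' Truncate a restorer at its deepest convolutional layer
#'
#' Copies the five encoder blocks (through block 5's last convolution,
#' inclusive) and discards the decoder. Weights are copied, not shared: later
#' fine-tuning does not alter the restorer.
#'
#' @param restorer A `restorer_model`.
#' @return An object of class `encoder_model`.
#' @export
truncate_encoder <- function(restorer) {
  if (!inherits(restorer, "restorer_model"))
    stop("expected a restorer_model")
  structure(list(kind = "encoder", filters = restorer$filters,
                 width_multiplier = restorer$width_multiplier,
                 enc = clone_params(restorer$enc)),
            class = "encoder_model")
}

#' Forward pass of a bare encoder
#'
#' @param encoder An `encoder_model`.
#' @param x Input batch `(H, W, 1, N)` (or a single matrix).
#' @return The block-5 feature maps, `(H/16, W/16, C, N)`.
#' @export
encoder_features <- function(encoder, x) {
  ad_reset_tape()
  encoder_forward(encoder$enc, promote_batch(x))$out$val
}

#' Classifier training configuration
#'
#' Defaults follow the fine-tuning regimen: SGD with initial learning rate
#' 1e-3, the shared plateau schedule, decision threshold 0.5.
#'
#' @inheritParams pretext_config
#' @param threshold Probability threshold for the abnormal class.
#' @return An object of class `train_config`.
#' @export
classifier_config <- function(optimizer = "sgd", initial_lr = 1e-3,
                              plateau_factor = 0.5, plateau_patience = 10L,
                              lr_floor = 1e-6, max_epochs = 30L,
                              batch_size = 16L, threshold = 0.5, seed = 1L) {
  cfg <- pretext_config(optimizer = optimizer, initial_lr = initial_lr,
                        plateau_factor = plateau_factor,
                        plateau_patience = plateau_patience,
                        lr_floor = lr_floor, max_epochs = max_epochs,
                        batch_size = batch_size, seed = seed)
  cfg$threshold <- threshold
  cfg
}

#' Build a binary classifier from an encoder
#'
#' Appends global average pooling and a dense 2-node softmax head to the
#' encoder. Class order is (normal, abnormal).
#'
#' @param encoder An `encoder_model` (e.g. from [truncate_encoder()]), or
#'   NULL with `init_source = "random"` to build a fresh random encoder.
#' @param init_source One of `"denoise_pretext"`, `"deblur_pretext"`,
#'   `"external_pretrained"`, `"random"`; recorded provenance of the encoder
#'   weights.
#' @param input_size Input `(h, w)` used for fresh encoders.
#' @param width_multiplier Width of fresh encoders.
#' @param seed Integer seed for the head (and fresh-encoder) initialization.
#' @return An object of class `classifier_model`.
#' @export
build_classifier <- function(encoder = NULL, init_source = "random",
                             input_size = c(224L, 224L),
                             width_multiplier = 1, seed = 1L) {
  init_source <- match.arg(init_source,
                           c("denoise_pretext", "deblur_pretext",
                             "external_pretrained", "random"))
  if (is.null(encoder)) {
    filters <- scaled_filters(width_multiplier)
    enc <- with_seed(derive_seed(seed, "classifier/encoder"),
                     build_encoder_blocks(1L, filters))
  } else {
    filters <- encoder$filters
    width_multiplier <- encoder$width_multiplier
    enc <- clone_params(encoder$enc)
  }
  head <- with_seed(derive_seed(seed, "classifier/head"),
                    layer_dense(filters[5], 2L))
  structure(list(kind = "classifier", filters = filters,
                 width_multiplier = width_multiplier,
                 init_source = init_source, enc = enc, head = head),
            class = "classifier_model")
}

classifier_forward_node <- function(model, x, taps = FALSE) {
  ef <- encoder_forward(model$enc, x)
  feat <- op_gap(ef$out)
  logits <- op_dense(feat, model$head$w, model$head$b)
  if (taps) list(logits = logits, conv = ef$out, feat = feat)
  else list(logits = logits)
}

#' Predict class probabilities
#'
#' @param model A `classifier_model`.
#' @param x A `(H, W, 1, N)` batch, a single matrix, or a list of
#'   [gray_image()]s.
#' @return A list with `probs` (N x 2 matrix, columns p_normal, p_abnormal)
#'   and `logits` (N x 2 matrix of pre-softmax values).
#' @export
classifier_predict <- function(model, x) {
  if (is.list(x) && !is.array(x)) x <- stack_images(x)
  ad_reset_tape()
  node <- classifier_forward_node(model, ad_const(promote_batch(x)))
  logits <- t(node$logits$val)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  colnames(probs) <- colnames(logits) <- c("p_normal", "p_abnormal")
  list(probs = probs, logits = logits)
}

# shared minibatch loop for softmax classifiers (fine_tune and the
# attention-fuzzy ensemble). forward_fn(model, x_tensor) must return the
# logits node (2 x N).
train_softmax_model <- function(model, forward_fn, x_train, y_train,
                                x_val, y_val, config, params,
                                verbose = FALSE) {
  opt <- make_optimizer(config$optimizer, params)
  st <- plateau_init(config)
  n <- dim(x_train)[4L]
  hist <- data.frame()
  best_loss <- Inf
  best_weights <- NULL
  best_epoch <- NA_integer_
  cls_tr <- y_train + 1L  # 1 = normal, 2 = abnormal
  cls_va <- y_val + 1L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("epoch/", epoch)),
                     sample.int(n))
    tl <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_train[, , , idx, drop = FALSE]
      ad_reset_tape()
      logits <- forward_fn(model, ad_const(xb))
      loss <- op_softmax_xent(logits, cls_tr[idx])
      ad_backward(loss)
      opt$step(st$lr)
      tl <- tl + loss$val
      nb <- nb + 1L
    }
    ad_reset_tape()
    vlogits <- forward_fn(model, ad_const(x_val))
    vnode <- op_softmax_xent(vlogits, cls_va)
    vloss <- vnode$val
    vp <- attr(vnode, "probs")
    vacc <- balanced_accuracy_from_probs(t(vp)[, 2L], y_val,
                                         config$threshold %||% 0.5)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   val_loss = vloss, lr = st$lr,
                                   val_bal_acc = vacc))
    if (vloss < best_loss) {
      best_loss <- vloss
      best_weights <- lapply(params, function(p) p$val)
      best_epoch <- epoch
    }
    st <- plateau_update(st, vloss)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f bal.acc %.3f",
                      epoch, tl / nb, vloss, vacc))
  }
  for (i in seq_along(params)) params[[i]]$val <- best_weights[[i]]
  attr(hist, "best_epoch") <- best_epoch
  hist
}

balanced_accuracy_from_probs <- function(p_abn, labels, threshold = 0.5) {
  pred <- as.integer(p_abn >= threshold)
  sens <- if (sum(labels == 1L) > 0) mean(pred[labels == 1L] == 1L) else NA
  spec <- if (sum(labels == 0L) > 0) mean(pred[labels == 0L] == 0L) else NA
  mean(c(sens, spec))
}

cohort_split_batch <- function(cohort, split) {
  rec <- cohort$records[cohort$records$split == split, , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty split: ", split)
  list(x = stack_images(cohort$images[rec$image_id]),
       y = rec$label, ids = rec$image_id)
}

#' Fine-tune a classifier on a split cohort
#'
#' Categorical cross-entropy over the softmax head, the configured
#' optimizer (SGD by default) with the plateau schedule, and
#' best-validation-loss checkpointing. All encoder layers are trainable.
#'
#' @param model A `classifier_model`.
#' @param cohort A split `phantom_cohort` (records carry train/val splits),
#'   or any list with `records` and `images` in the same layout.
#' @param config A [classifier_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `model` (best weights restored) and `history` (per
#'   epoch: train_loss, val_loss, lr, val_bal_acc) with attribute
#'   `best_epoch`.
#' @export
fine_tune <- function(model, cohort, config = classifier_config(),
                      verbose = FALSE) {
  tr <- cohort_split_batch(cohort, "train")
  va <- cohort_split_batch(cohort, "val")
  if (length(unique(tr$y)) < 2L)
    stop("training split contains a single class")
  params <- collect_params(model)
  hist <- train_softmax_model(
    model, function(m, x) classifier_forward_node(m, x)$logits,
    tr$x, tr$y, va$x, va$y, config, params, verbose = verbose)
  list(model = model, history = hist)
}

#' Export predictions for a cohort split
#'
#' @param model A `classifier_model`.
#' @param cohort A split cohort.
#' @param split Which split to score.
#' @return A data.frame with image_id, p_normal, p_abnormal, label.
#' @export
predict_cohort <- function(model, cohort, split = "test") {
  te <- cohort_split_batch(cohort, split)
  pr <- classifier_predict(model, te$x)
  data.frame(image_id = te$ids, p_normal = pr$probs[, 1L],
             p_abnormal = pr$probs[, 2L], label = te$y,
             stringsAsFactors = FALSE)
}
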