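# Classifier fusion: simple averaging, SLSQP-weighted averaging and the
# learnable attention-fuzzy (A-F) ensemble.
#
# The weighted-averaging objective is the log-loss of the weighted-average
# probability sum_i w_i p_i(x) on the validation split, under the simplex
# constraints sum w_i = 1, w_i >= 0, solved by sequential least-squares
# programming from a uniform start. (The literal printed form of the
# weighted objective is linear in w and degenerates at simplex vertices;
# the prose intent - minimize logarithmic loss - is what is implemented.)

#' Bundle predictions from several classifiers
#'
#' @param probs List (one per model) of N x 2 probability matrices over
#'   (normal, abnormal); rows must sum to 1.
#' @param labels Integer vector of N binary labels (1 = abnormal).
#' @param logits Optional list of N x 2 pre-softmax logit matrices.
#' @param model_names Optional character names for the models.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(probs, labels, logits = NULL,
                           model_names = NULL) {
  if (length(probs) < 1L) stop("need at least one model")
  n <- nrow(probs[[1L]])
  for (p in probs) {
    if (nrow(p) != n || ncol(p) != 2L)
      stop("all models must cover identical samples with 2 classes")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      stop("probability rows must sum to 1")
  }
  if (length(labels) != n) stop("labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (is.null(model_names))
    model_names <- names(probs) %||% sprintf("model%d", seq_along(probs))
  structure(list(probs = probs, logits = logits,
                 labels = as.integer(labels), model_names = model_names),
            class = "prediction_set")
}

#' Simple averaging ensemble
#'
#' Elementwise mean of the member probabilities.
#'
#' @param pred_set A [prediction_set()] with at least two members.
#' @return An N x 2 probability matrix.
#' @export
simple_average <- function(pred_set) {
  stopifnot(inherits(pred_set, "prediction_set"))
  if (length(pred_set$probs) < 2L) stop("need at least two members")
  Reduce(`+`, pred_set$probs) / length(pred_set$probs)
}

# validation log-loss of the weighted-average prediction
weighted_logloss <- function(w, probs, labels, floor = 1e-12) {
  P <- Reduce(`+`, Map(function(wi, pi) wi * pi, w, probs))
  pick <- ifelse(labels == 1L, P[, 2L], P[, 1L])
  -mean(log(pmax(pick, floor)))
}

#' Fit ensemble weights by SLSQP
#'
#' Minimizes the log-loss of the weighted-average probability on the
#' supplied (validation) prediction set, subject to `sum(w) = 1`,
#' `w >= 0`, via sequential least-squares programming started from uniform
#' weights. The returned weights are feasible and never worse than uniform.
#'
#' @param pred_set A [prediction_set()] with labels, at least two members.
#' @return An object of class `ensemble_weights`: list with `w` and the
#'   achieved `logloss`.
#' @export
fit_slsqp_weights <- function(pred_set) {
  stopifnot(inherits(pred_set, "prediction_set"))
  N <- length(pred_set$probs)
  if (N < 2L) stop("need at least two members")
  probs <- pred_set$probs
  labels <- pred_set$labels
  w0 <- rep(1 / N, N)
  fn <- function(w) weighted_logloss(w, probs, labels)
  res <- nloptr::slsqp(
    w0, fn,
    lower = rep(0, N), upper = rep(1, N),
    heq = function(w) sum(w) - 1,
    control = list(xtol_rel = 1e-10, maxeval = 500))
  w <- pmax(res$par, 0)
  w <- w / sum(w)
  if (fn(w) > fn(w0)) w <- w0  # never worse than the uniform start
  structure(list(w = w, logloss = fn(w),
                 model_names = pred_set$model_names),
            class = "ensemble_weights")
}

#' Apply ensemble weights
#'
#' @param pred_set A [prediction_set()].
#' @param w An `ensemble_weights` object or a feasible numeric weight
#'   vector.
#' @return An N x 2 probability matrix `sum_i w_i p_i(x)`.
#' @export
apply_weights <- function(pred_set, w) {
  stopifnot(inherits(pred_set, "prediction_set"))
  if (inherits(w, "ensemble_weights")) w <- w$w
  if (length(w) != length(pred_set$probs)) stop("weight length mismatch")
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1")
  Reduce(`+`, Map(function(wi, pi) wi * pi, w, pred_set$probs))
}

# ---- attention-fuzzy ensemble -------------------------------------------

freeze_params <- function(x) {
  if (inherits(x, "ad_tensor")) {
    x$requires_grad <- FALSE
    return(invisible(NULL))
  }
  if (is.list(x)) for (el in x) freeze_params(el)
  invisible(NULL)
}

#' Build the attention-fuzzy ensemble
#'
#' Member convolutional backbones are copied and frozen. Per-member GAP
#' features are concatenated and fed to a trainable dense attention layer
#' producing one score per member; a softmax turns the scores into
#' per-sample attention weights `alpha_i`. The combined logits
#' `sum_i alpha_i f_i(x)` (with `f_i` the member head logits, trainable) are
#' multiplied by the trainable fuzziness scalar `gamma` (initialized to 1,
#' unconstrained) before the final softmax.
#'
#' @param members List of at least two `classifier_model`s with identical
#'   feature widths.
#' @param seed Integer seed for the attention-layer initialization.
#' @return An object of class `af_ensemble_model`.
#' @export
build_af_ensemble <- function(members, seed = 1L) {
  if (length(members) < 2L) stop("need at least two members")
  filters <- members[[1L]]$filters
  for (m in members) {
    if (!inherits(m, "classifier_model")) stop("members must be classifiers")
    if (!identical(m$filters, filters)) stop("incompatible member widths")
  }
  members <- lapply(members, clone_params)
  for (m in members) freeze_params(m$enc)   # backbones frozen
  M <- length(members)
  C <- filters[5L]
  attention <- with_seed(derive_seed(seed, "af/attention"),
                         layer_dense(M * C, M))
  gamma <- ad_param(1.0)
  structure(list(kind = "af_ensemble", members = members,
                 attention = attention, gamma = gamma, filters = filters),
            class = "af_ensemble_model")
}

af_forward_node <- function(model, x, taps = FALSE) {
  feats <- list()
  logits <- list()
  for (i in seq_along(model$members)) {
    m <- model$members[[i]]
    ef <- encoder_forward(m$enc, x)
    feats[[i]] <- op_gap(ef$out)
    logits[[i]] <- op_dense(feats[[i]], m$head$w, m$head$b)
  }
  concat <- op_concat_rows(feats)
  scores <- op_dense(concat, model$attention$w, model$attention$b)
  alpha <- op_softmax(scores)               # (M, N), columns sum to 1
  combined <- NULL
  for (i in seq_along(logits)) {
    term <- op_colscale(logits[[i]], op_row(alpha, i))
    combined <- if (is.null(combined)) term else op_add(combined, term)
  }
  out <- op_scale_by_param(combined, model$gamma)
  if (taps) list(logits = out, alpha = alpha) else list(logits = out)
}

#' Predict with the attention-fuzzy ensemble
#'
#' @param model An `af_ensemble_model`.
#' @param x A `(H, W, 1, N)` batch, matrix, or list of images.
#' @return A list with `probs` (N x 2), `logits` (N x 2, post-gamma) and
#'   `alpha` (N x M per-sample attention weights).
#' @export
af_predict <- function(model, x) {
  if (is.list(x) && !is.array(x)) x <- stack_images(x)
  ad_reset_tape()
  node <- af_forward_node(model, ad_const(promote_batch(x)), taps = TRUE)
  logits <- t(node$logits$val)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  colnames(probs) <- colnames(logits) <- c("p_normal", "p_abnormal")
  list(probs = probs, logits = logits, alpha = t(node$alpha$val))
}

af_backbone_checksum <- function(model) {
  s <- 0
  for (m in model$members)
    for (p in collect_frozen(m$enc)) s <- s + sum(p$val)
  s
}

collect_frozen <- function(x, out = list()) {
  if (inherits(x, "ad_tensor")) {
    out[[length(out) + 1L]] <- x
    return(out)
  }
  if (is.list(x)) for (el in x) out <- collect_frozen(el, out)
  out
}

#' Train the attention-fuzzy ensemble
#'
#' Only the attention layer, the member logit (head) layers and the
#' fuzziness scalar receive updates; member backbones must be frozen (it is
#' an error if any backbone parameter is trainable) and their checksums are
#' verified unchanged after training.
#'
#' @param model An `af_ensemble_model`.
#' @param cohort A split cohort (see [fine_tune()]).
#' @param config A [classifier_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `model` and `history` (attribute `best_epoch`).
#' @export
train_af_ensemble <- function(model, cohort, config = classifier_config(),
                              verbose = FALSE) {
  for (m in model$members)
    if (length(collect_params(m$enc)) > 0L)
      stop("unfrozen member backbone detected")
  before <- af_backbone_checksum(model)
  tr <- cohort_split_batch(cohort, "train")
  va <- cohort_split_batch(cohort, "val")
  params <- collect_params(model)
  hist <- train_softmax_model(
    model, function(m, x) af_forward_node(m, x)$logits,
    tr$x, tr$y, va$x, va$y, config, params, verbose = verbose)
  stopifnot(isTRUE(all.equal(before, af_backbone_checksum(model))))
  list(model = model, history = hist)
}
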