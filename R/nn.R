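# Layer construction, weight initialization, optimizers and checkpointing
# shared by the restorer, the classifiers and the attention-fuzzy ensemble.

he_conv <- function(kh, kw, cin, cout, rng_sd = NULL) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
}

glorot_dense <- function(k, d) {
  lim <- sqrt(6 / (k + d))
  matrix(stats::runif(k * d, -lim, lim), nrow = k, ncol = d)
}

layer_conv <- function(kh, kw, cin, cout, pad = 1L) {
  list(kind = "conv",
       w = ad_param(he_conv(kh, kw, cin, cout)),
       b = ad_param(numeric(cout)),
       pad = pad)
}

layer_upconv <- function(cin, cout) {
  list(kind = "upconv",
       w = ad_param(he_conv(2, 2, cin, cout)),
       b = ad_param(numeric(cout)))
}

layer_dense <- function(din, dout) {
  list(kind = "dense",
       w = ad_param(glorot_dense(dout, din)),
       b = ad_param(numeric(dout)))
}

# Collect every ad_param reachable inside nested lists of layers.
collect_params <- function(x, out = list()) {
  if (inherits(x, "ad_tensor")) {
    if (x$requires_grad) out[[length(out) + 1L]] <- x
    return(out)
  }
  if (is.list(x)) for (el in x) out <- collect_params(el, out)
  out
}

#' Count learnable parameters of a model
#'
#' Sums the sizes of all weight and bias tensors in a restorer, classifier or
#' ensemble model. The sharpening skip connections contribute nothing: their
#' kernel is a fixed constant.
#'
#' @param model A model built by [build_restorer()], [build_classifier()] or
#'   [build_af_ensemble()].
#' @return Integer total number of learnable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$val), numeric(1)))
}

# ---- optimizers ----------------------------------------------------------

# classical momentum (0.9, the conventional setting for VGG-style
# fine-tuning); momentum = 0 gives plain SGD
optimizer_sgd <- function(params, momentum = 0.9) {
  vel <- lapply(params, function(p) p$val * 0)
  list(
    step = function(lr) {
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        vel[[i]] <<- momentum * vel[[i]] - lr * p$grad
        p$val <- p$val + vel[[i]]
      }
      ad_zero_grads(params)
    }
  )
}

optimizer_adam <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(params, function(p) p$val * 0)
  state$v <- lapply(params, function(p) p$val * 0)
  list(
    step = function(lr) {
      state$t <- state$t + 1L
      bc1 <- 1 - beta1^state$t
      bc2 <- 1 - beta2^state$t
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * p$grad
        state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * p$grad^2
        p$val <- p$val - lr * (state$m[[i]] / bc1) /
          (sqrt(state$v[[i]] / bc2) + eps)
      }
      ad_zero_grads(params)
    }
  )
}

make_optimizer <- function(name, params) {
  switch(name,
         adam = optimizer_adam(params),
         sgd = optimizer_sgd(params),
         stop("unknown optimizer: ", name))
}

# ---- weight (de)serialization -------------------------------------------

# Flatten all parameters into a named list of plain arrays.
get_weights <- function(model) {
  params <- collect_params(model)
  out <- lapply(params, function(p) p$val)
  names(out) <- paste0("p", seq_along(out))
  out
}

set_weights <- function(model, weights) {
  params <- collect_params(model)
  stopifnot(length(params) == length(weights))
  for (i in seq_along(params)) {
    stopifnot(length(params[[i]]$val) == length(weights[[i]]))
    v <- weights[[i]]
    dim(v) <- dim(params[[i]]$val)
    params[[i]]$val <- v
  }
  invisible(model)
}

model_fingerprint <- function(model) {
  params <- collect_params(model)
  shapes <- vapply(params, function(p)
    paste(if (is.null(dim(p$val))) length(p$val) else dim(p$val),
          collapse = "x"), character(1))
  paste0(model$kind, "|", paste(shapes, collapse = ";"))
}

#' Save model weights to a checkpoint file
#'
#' The checkpoint stores the weights together with an architecture
#' fingerprint; [load_checkpoint()] refuses to restore weights into a model
#' whose fingerprint differs.
#'
#' @param model A built model.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(fingerprint = model_fingerprint(model),
              kind = model$kind,
              weights = get_weights(model))
  saveRDS(obj, path)
  invisible(path)
}

#' Load model weights from a checkpoint file
#'
#' @param model A built model whose architecture matches the checkpoint.
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return `model` with restored weights, invisibly.
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  if (!identical(obj$fingerprint, model_fingerprint(model)))
    stop("checkpoint fingerprint mismatch: expected ",
         model_fingerprint(model), " got ", obj$fingerprint)
  set_weights(model, obj$weights)
  invisible(model)
}

weights_checksum <- function(weights) {
  sum(vapply(weights, function(w) sum(as.numeric(w)), numeric(1)))
}
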