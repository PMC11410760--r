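# Restorer training on paired degraded/clean images: SSIM objective, Adam,
# plateau learning-rate schedule, best-validation-loss checkpointing.

#' Pretext training configuration
#'
#' Defaults follow the study regimen: Adam, initial learning rate 1e-3,
#' halved after 10 epochs without validation-loss improvement, floored at
#' 1e-6, keeping only the lowest-validation-loss weights. Batch size and the
#' epoch budget are exposed (the regimen does not fix them); the full-scale
#' default is 100 epochs, desk-scale runs use fewer.
#'
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param initial_lr Initial learning rate.
#' @param plateau_factor Multiplicative LR reduction on plateau, in (0, 1).
#' @param plateau_patience Epochs without improvement before reduction.
#' @param lr_floor Lower bound on the learning rate.
#' @param max_epochs Training epoch budget.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for shuffling and any head initialization.
#' @return An object of class `train_config`.
#' @export
pretext_config <- function(optimizer = "adam", initial_lr = 1e-3,
                           plateau_factor = 0.5, plateau_patience = 10L,
                           lr_floor = 1e-6, max_epochs = 100L,
                           batch_size = 8L, seed = 1L) {
  stopifnot(plateau_factor > 0, plateau_factor < 1, lr_floor < initial_lr)
  structure(list(optimizer = optimizer, initial_lr = initial_lr,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 lr_floor = lr_floor, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' SSIM loss between predicted and target batches
#'
#' `1 - mean(SSIM)` with the package-wide SSIM settings (11x11 Gaussian
#' window, sigma 1.5, K1 = 0.01, K2 = 0.03, L = 1); 0 iff the batches are
#' identical, always within \[0, 2\].
#'
#' @param pred,target `(H, W, 1, N)` arrays (or single matrices) in \[0, 1\].
#' @return A scalar loss.
#' @export
ssim_loss <- function(pred, target) {
  pred <- promote_batch(pred); target <- promote_batch(target)
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  n <- dim(pred)[4L]
  vals <- vapply(seq_len(n), function(i)
    ssim(pred[, , 1L, i], target[, , 1L, i]), numeric(1))
  1 - mean(vals)
}

# graph version of the SSIM loss (identical window and constants)
ssim_loss_node <- function(pred, target_arr, K1 = 0.01, K2 = 0.03, L = 1) {
  k <- ssim_window(11L, 1.5)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  targ <- ad_const(target_arr)
  mux <- op_dwconv_fixed(pred, k)
  muy <- op_dwconv_fixed(targ, k)
  sxx <- op_sub(op_dwconv_fixed(op_mul(pred, pred), k), op_mul(mux, mux))
  syy <- op_sub(op_dwconv_fixed(op_mul(targ, targ), k), op_mul(muy, muy))
  sxy <- op_sub(op_dwconv_fixed(op_mul(pred, targ), k), op_mul(mux, muy))
  num <- op_mul(op_sadd(op_smul(op_mul(mux, muy), 2), C1),
                op_sadd(op_smul(sxy, 2), C2))
  den <- op_mul(op_sadd(op_add(op_mul(mux, mux), op_mul(muy, muy)), C1),
                op_sadd(op_add(sxx, syy), C2))
  op_sadd(op_smul(op_mean(op_div(num, den)), -1), 1)
}

#' Plateau learning-rate schedule
#'
#' Replays a validation-loss history through the reduce-on-plateau rule: the
#' learning rate is multiplied by `plateau_factor` whenever the loss has not
#' strictly improved for `plateau_patience` consecutive epochs (the patience
#' counter resets on every reduction and on every improvement), and never
#' drops below `lr_floor`.
#'
#' @param val_losses Numeric vector of per-epoch validation losses (oldest
#'   first), at least one epoch.
#' @param config A [pretext_config()] or [classifier_config()].
#' @return The learning rate in force after the last recorded epoch.
#' @export
schedule_lr <- function(val_losses, config) {
  if (length(val_losses) < 1L) stop("need at least one recorded epoch")
  st <- plateau_init(config)
  for (l in val_losses) st <- plateau_update(st, l)
  st$lr
}

plateau_init <- function(config) {
  list(lr = config$initial_lr, best = Inf, wait = 0L,
       factor = config$plateau_factor, patience = config$plateau_patience,
       floor = config$lr_floor)
}

plateau_update <- function(st, val_loss) {
  if (val_loss < st$best) {
    st$best <- val_loss
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= st$patience) {
      st$lr <- max(st$lr * st$factor, st$floor)
      st$wait <- 0L
    }
  }
  st
}

pairs_to_batches <- function(pairs) {
  list(x = stack_images(lapply(pairs, `[[`, "degraded")),
       y = stack_images(lapply(pairs, `[[`, "clean")))
}

#' Train the restorer on paired degraded/clean images
#'
#' Minimizes the SSIM loss with the configured optimizer and plateau
#' schedule; MSE, MAE, PSNR and SSIM on the validation pairs are tracked as
#' secondary metrics. The weights achieving the lowest validation loss are
#' restored into the model before returning.
#'
#' @param model A `restorer_model` from [build_restorer()].
#' @param train_pairs,val_pairs Non-empty lists of paired samples from
#'   [degrade_dataset()].
#' @param config A [pretext_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `model` (best weights restored) and `history` (one
#'   row per epoch: train_loss, val_loss, lr, val_ssim, val_psnr, val_mse,
#'   val_mae) with attribute `best_epoch`.
#' @export
train_pretext <- function(model, train_pairs, val_pairs, config = pretext_config(),
                          verbose = FALSE) {
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("train and validation pair sets must be non-empty")
  tr <- pairs_to_batches(train_pairs)
  va <- pairs_to_batches(val_pairs)
  params <- collect_params(model)
  opt <- make_optimizer(config$optimizer, params)
  st <- plateau_init(config)
  n <- dim(tr$x)[4L]
  hist <- data.frame()
  best_loss <- Inf
  best_weights <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("epoch/", epoch)),
                     sample.int(n))
    tl <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[, , , idx, drop = FALSE]
      ad_reset_tape()
      out <- restorer_forward_node(model, ad_const(xb))$out
      loss <- ssim_loss_node(out, yb)
      ad_backward(loss)
      opt$step(st$lr)
      tl <- tl + loss$val
      nb <- nb + 1L
    }
    pred <- restorer_forward(model, va$x)
    vl <- ssim_loss(pred, va$y)
    nval <- dim(va$x)[4L]
    vssim <- 1 - vl
    vmse <- mean((pred - va$y)^2)
    vmae <- mean(abs(pred - va$y))
    vpsnr <- mean(vapply(seq_len(nval), function(i)
      psnr(va$y[, , 1L, i], pred[, , 1L, i]), numeric(1)))
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = tl / nb, val_loss = vl, lr = st$lr,
      val_ssim = vssim, val_psnr = vpsnr, val_mse = vmse, val_mae = vmae))
    if (vl < best_loss) {
      best_loss <- vl
      best_weights <- get_weights(model)
      best_epoch <- epoch
    }
    st <- plateau_update(st, vl)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f lr %.2e",
                      epoch, tl / nb, vl, st$lr))
  }
  set_weights(model, best_weights)
  attr(hist, "best_epoch") <- best_epoch
  list(model = model, history = hist)
}
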