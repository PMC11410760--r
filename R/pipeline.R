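# End-to-end orchestration: phantoms -> degradation -> pretext training ->
# transfer -> ensembles -> metrics -> significance -> explanations, driven
# by one run_config. Stages are content-addressed: each stage writes a stamp
# hashing its parameters, its seed and its upstream stamps, so unchanged
# stages are skipped on re-run and any upstream change invalidates exactly
# its downstream cone.

pipeline_stage_order <- c("phantom", "degrade", "pretext", "transfer",
                          "ensembles", "clf_metrics", "stats", "scorecam")

pipeline_deps <- list(
  phantom = character(0),
  degrade = "phantom",
  pretext = "degrade",
  transfer = c("phantom", "pretext"),
  ensembles = c("phantom", "transfer"),
  clf_metrics = c("phantom", "ensembles"),
  stats = "clf_metrics",
  scorecam = c("phantom", "transfer")
)

pipeline_defaults <- function() {
  list(
    phantom = list(n = 60L, prevalence = 0.4),
    degrade = list(),
    pretext = list(width_multiplier = 1 / 8, max_epochs = 3L,
                   batch_size = 8L),
    transfer = list(max_epochs = 3L, batch_size = 16L,
                    inits = c("denoise_pretext", "deblur_pretext", "random")),
    ensembles = list(max_epochs = 3L, batch_size = 16L),
    clf_metrics = list(threshold = 0.5),
    stats = list(alpha = 0.05),
    scorecam = list(rel_threshold = 0.2, max_images = 5L)
  )
}

stage_params <- function(config, stage) {
  p <- pipeline_defaults()[[stage]]
  user <- config$stages[[stage]]
  for (nm in names(user)) p[[nm]] <- user[[nm]]
  p
}

# stage seeds derive from the global seed unless overridden per stage
stage_seed <- function(config, stage) {
  s <- config$stages[[stage]]$seed
  if (is.null(s)) derive_seed(config$seed, stage) else as.integer(s)
}

stage_stamp_value <- function(config, stage, dir) {
  upstream <- vapply(pipeline_deps[[stage]], function(up) {
    f <- file.path(dir, up, ".stamp")
    if (!file.exists(f))
      stop("missing upstream artifact for stage '", stage,
           "': stage '", up, "' has not run")
    readLines(f, n = 1L)
  }, character(1))
  payload <- paste(
    stage, stage_seed(config, stage),
    paste(deparse(stage_params(config, stage)), collapse = ""),
    paste(config$image_size, collapse = "x"),
    paste(upstream, collapse = "|"), sep = "::")
  tmp <- tempfile()
  writeLines(payload, tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(dir, stage, stamp) {
  f <- file.path(dir, stage, ".stamp")
  file.exists(f) && identical(readLines(f, n = 1L), stamp)
}

mark_stage <- function(dir, stage, stamp) {
  writeLines(stamp, file.path(dir, stage, ".stamp"))
}

#' Run the experiment pipeline
#'
#' Executes the requested stages in dependency order
#' (phantom, degrade, pretext, transfer, ensembles, clf_metrics, stats,
#' scorecam). Re-running with an unchanged configuration skips completed
#' stages; changing one stage's parameters or seed re-runs that stage and
#' everything downstream of it.
#'
#' @param config A [run_config()]. `config$image_size` sets the phantom and
#'   model size (must be divisible by 16); per-stage settings live in
#'   `config$stages`.
#' @param dir Working directory for artifacts (created if missing).
#' @param stages Character subset of stages to run (default: all).
#' @return The pipeline manifest: a list with one entry per requested stage
#'   (status, seed, parameters, output files with md5 hashes), also written
#'   to `dir/manifest.yaml`.
#' @export
run_pipeline <- function(config, dir, stages = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stages)) stages <- pipeline_stage_order
  unknown <- setdiff(stages, pipeline_stage_order)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(dir, "run.log")
  manifest <- list()
  for (stage in stages) {
    sdir <- file.path(dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    stamp <- stage_stamp_value(config, stage, dir)
    seed <- stage_seed(config, stage)
    params <- stage_params(config, stage)
    if (stage_done(dir, stage, stamp)) {
      log_line(logfile, stage, "INFO", "up to date; skipped")
      status <- "skipped"
    } else {
      log_line(logfile, stage, "INFO",
               paste0("running (seed ", seed, ")"))
      runner <- get(paste0("pipeline_stage_", stage), mode = "function")
      runner(config, params, seed, dir, sdir)
      mark_stage(dir, stage, stamp)
      status <- "run"
    }
    outputs <- setdiff(list.files(sdir, full.names = TRUE),
                       file.path(sdir, ".stamp"))
    manifest[[stage]] <- list(
      status = status, seed = seed, params = params, stamp = stamp,
      outputs = as.list(tools::md5sum(outputs)))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

pipeline_stage_phantom <- function(config, params, seed, dir, sdir) {
  cohort <- generate_cohort(params$n, params$prevalence,
                            size = config$image_size, seed = seed)
  cohort <- patient_split(cohort, seed = seed)
  saveRDS(cohort, file.path(sdir, "cohort.rds"))
  write_label_table(cohort$records, file.path(sdir, "labels.csv"))
}

pipeline_stage_degrade <- function(config, params, seed, dir, sdir) {
  cohort <- readRDS(file.path(dir, "phantom", "cohort.rds"))
  rec <- cohort$records
  for (mode in c("noise", "blur")) {
    spec <- if (mode == "noise") noise_spec(seed = derive_seed(seed, "noise"))
            else blur_spec(seed = derive_seed(seed, "blur"))
    for (split in c("train", "val")) {
      ids <- rec$image_id[rec$split == split]
      pairs <- degrade_dataset(cohort$images[ids], spec)
      saveRDS(pairs, file.path(sdir, paste0(mode, "_", split, ".rds")))
    }
    manifest <- data.frame(image_id = rec$image_id[rec$split %in% c("train", "val")])
    utils::write.csv(manifest, file.path(sdir, paste0(mode, "_manifest.csv")),
                     row.names = FALSE)
  }
}

pipeline_stage_pretext <- function(config, params, seed, dir, sdir) {
  for (mode in c("noise", "blur")) {
    tr <- readRDS(file.path(dir, "degrade", paste0(mode, "_train.rds")))
    va <- readRDS(file.path(dir, "degrade", paste0(mode, "_val.rds")))
    model <- build_restorer(config$image_size,
                            width_multiplier = params$width_multiplier,
                            seed = derive_seed(seed, paste0("init/", mode)))
    cfg <- pretext_config(max_epochs = params$max_epochs,
                          batch_size = params$batch_size,
                          seed = derive_seed(seed, paste0("train/", mode)))
    fit <- train_pretext(model, tr, va, cfg)
    save_checkpoint(fit$model, file.path(sdir, paste0(mode, ".ckpt")))
    utils::write.csv(fit$history,
                     file.path(sdir, paste0(mode, "_history.csv")),
                     row.names = FALSE)
  }
}

pipeline_load_restorer <- function(config, dir, mode) {
  params <- stage_params(config, "pretext")
  model <- build_restorer(config$image_size,
                          width_multiplier = params$width_multiplier)
  load_checkpoint(model, file.path(dir, "pretext", paste0(mode, ".ckpt")))
}

pipeline_init_classifier <- function(config, dir, init, seed) {
  params <- stage_params(config, "pretext")
  if (init %in% c("denoise_pretext", "deblur_pretext")) {
    mode <- if (init == "denoise_pretext") "noise" else "blur"
    enc <- truncate_encoder(pipeline_load_restorer(config, dir, mode))
    build_classifier(enc, init_source = init, seed = seed)
  } else {
    build_classifier(NULL, init_source = "random",
                     input_size = config$image_size,
                     width_multiplier = params$width_multiplier, seed = seed)
  }
}

classifier_tag <- function(init) {
  c(denoise_pretext = "den_p", deblur_pretext = "deb_p",
    external_pretrained = "baseline", random = "random")[[init]]
}

pipeline_stage_transfer <- function(config, params, seed, dir, sdir) {
  cohort <- readRDS(file.path(dir, "phantom", "cohort.rds"))
  for (init in params$inits) {
    tag <- classifier_tag(init)
    clf <- pipeline_init_classifier(config, dir, init,
                                    derive_seed(seed, paste0("init/", tag)))
    cfg <- classifier_config(max_epochs = params$max_epochs,
                             batch_size = params$batch_size,
                             seed = derive_seed(seed, paste0("train/", tag)))
    fit <- fine_tune(clf, cohort, cfg)
    save_checkpoint(fit$model, file.path(sdir, paste0(tag, ".ckpt")))
    for (split in c("val", "test")) {
      preds <- predict_cohort(fit$model, cohort, split)
      utils::write.csv(preds,
                       file.path(sdir, paste0(tag, "_", split, ".csv")),
                       row.names = FALSE)
    }
  }
}

read_preds <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

pipeline_stage_ensembles <- function(config, params, seed, dir, sdir) {
  cohort <- readRDS(file.path(dir, "phantom", "cohort.rds"))
  tdir <- file.path(dir, "transfer")
  members <- c("den_p", "deb_p")
  val <- lapply(members, function(m) read_preds(file.path(tdir, paste0(m, "_val.csv"))))
  test <- lapply(members, function(m) read_preds(file.path(tdir, paste0(m, "_test.csv"))))
  as_ps <- function(dfs) prediction_set(
    lapply(dfs, function(d) as.matrix(d[, c("p_normal", "p_abnormal")])),
    labels = dfs[[1]]$label, model_names = members)
  ps_val <- as_ps(val)
  ps_test <- as_ps(test)
  sa <- simple_average(ps_test)
  wts <- fit_slsqp_weights(ps_val)
  wa <- apply_weights(ps_test, wts)
  write_pred <- function(p, name) {
    utils::write.csv(data.frame(image_id = test[[1]]$image_id,
                                p_normal = p[, 1L], p_abnormal = p[, 2L],
                                label = test[[1]]$label),
                     file.path(sdir, paste0(name, "_test.csv")),
                     row.names = FALSE)
  }
  write_pred(sa, "sa")
  write_pred(wa, "slsqp_wa")
  yaml::write_yaml(list(weights = as.list(stats::setNames(wts$w, members)),
                        logloss = wts$logloss),
                   file.path(sdir, "slsqp_weights.yaml"))
  # attention-fuzzy ensemble over the two pretext classifiers
  clfs <- lapply(members, function(tag) {
    init <- if (tag == "den_p") "denoise_pretext" else "deblur_pretext"
    clf <- pipeline_init_classifier(config, dir, init, seed)
    load_checkpoint(clf, file.path(tdir, paste0(tag, ".ckpt")))
  })
  af <- build_af_ensemble(clfs, seed = derive_seed(seed, "af/init"))
  cfg <- classifier_config(max_epochs = params$max_epochs,
                           batch_size = params$batch_size,
                           seed = derive_seed(seed, "af/train"))
  fit <- train_af_ensemble(af, cohort, cfg)
  te <- cohort_split_batch(cohort, "test")
  pr <- af_predict(fit$model, te$x)
  utils::write.csv(data.frame(image_id = te$ids,
                              p_normal = pr$probs[, 1L],
                              p_abnormal = pr$probs[, 2L], label = te$y),
                   file.path(sdir, "af_test.csv"), row.names = FALSE)
  yaml::write_yaml(list(gamma = as.numeric(fit$model$gamma$val)),
                   file.path(sdir, "af_params.yaml"))
}

pipeline_model_files <- function(dir) {
  c(den_p = file.path(dir, "transfer", "den_p_test.csv"),
    deb_p = file.path(dir, "transfer", "deb_p_test.csv"),
    random = file.path(dir, "transfer", "random_test.csv"),
    sa = file.path(dir, "ensembles", "sa_test.csv"),
    slsqp_wa = file.path(dir, "ensembles", "slsqp_wa_test.csv"),
    af = file.path(dir, "ensembles", "af_test.csv"))
}

pipeline_stage_clf_metrics <- function(config, params, seed, dir, sdir) {
  files <- pipeline_model_files(dir)
  files <- files[file.exists(files)]
  rows <- lapply(names(files), function(m) {
    d <- read_preds(files[[m]])
    cbind(model = m,
          compute_metrics(confusion(d$p_abnormal, d$label,
                                    params$threshold)))
  })
  utils::write.csv(do.call(rbind, rows), file.path(sdir, "metrics.csv"),
                   row.names = FALSE)
}

pipeline_stage_stats <- function(config, params, seed, dir, sdir) {
  files <- pipeline_model_files(dir)
  files <- files[file.exists(files)]
  ests <- lapply(names(files), function(m) {
    d <- read_preds(files[[m]])
    cc <- confusion(d$p_abnormal, d$label)
    estimate_sensitivity(cc$tp, cc$fn)
  })
  names(ests) <- names(files)
  panel <- pairwise_panel(ests, alpha = params$alpha)
  utils::write.csv(panel, file.path(sdir, "comparisons.csv"),
                   row.names = FALSE)
}

pipeline_stage_scorecam <- function(config, params, seed, dir, sdir) {
  cohort <- readRDS(file.path(dir, "phantom", "cohort.rds"))
  clf <- pipeline_init_classifier(config, dir, "deblur_pretext", seed)
  load_checkpoint(clf, file.path(dir, "transfer", "deb_p.ckpt"))
  rec <- cohort$records
  ab <- rec[rec$split == "test" & rec$label == 1L, , drop = FALSE]
  ab <- utils::head(ab, params$max_images)
  rows <- list()
  for (id in ab$image_id) {
    img <- cohort$images[[id]]
    cam <- score_cam(clf, img, target_class = 1L)
    save_image(gray_image(cam), file.path(sdir, paste0(id, "_cam.png")))
    box <- tryCatch(map_to_bbox(cam, params$rel_threshold),
                    error = function(e) NULL)
    if (is.null(box)) next
    truth <- cohort$truth_boxes[[id]]
    best <- max(vapply(seq_len(nrow(truth)), function(i)
      box_iou(box, as.list(truth[i, ])), numeric(1)))
    rows[[id]] <- data.frame(image_id = id,
                             row_min = box$row_min, col_min = box$col_min,
                             row_max = box$row_max, col_max = box$col_max,
                             iou = best)
  }
  utils::write.csv(do.call(rbind, rows), file.path(sdir, "iou.csv"),
                   row.names = FALSE)
}
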