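# End-to-end pipeline: phantom generation (or NIfTI ingestion) ->
# segmentation -> feature extraction -> scale scoring and network
# classification -> metric reports, with a persisted resolved
# configuration so every output is reproducible from config + seed.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param n_phantoms Cohort size when generating synthetic data.
#' @param mixture Q/S/T mixture for the cohort.
#' @param seed Master seed.
#' @param use_provided_labels If `TRUE`, skip segmentation training and
#'   evaluate the classifiers on the reference label maps (mirroring a
#'   workflow where automatic segmentations are expert-corrected).
#' @param cv_k Folds for the classification network's cross-validation.
#' @param train_fraction Fraction of the cohort used to train the
#'   segmentation network when `use_provided_labels = FALSE`.
#' @param unet Options passed to [unet_config()].
#' @param qstnet Options passed to [qstnet_config()].
#' @param thresholds Scale threshold overrides for [binarize_items()].
#' @param input_paths Optional data frame / list with `mri`, `labels`,
#'   `type` giving NIfTI paths of an existing cohort instead of phantoms.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "sellarqst_run", n_phantoms = 30L,
                            mixture = c(0.218, 0.165, 0.617), seed = 1L,
                            use_provided_labels = TRUE,
                            train_fraction = 0.5, cv_k = 5L,
                            unet = list(), qstnet = list(),
                            thresholds = list(), input_paths = NULL) {
  structure(list(out_dir = out_dir, n_phantoms = as.integer(n_phantoms),
                 mixture = mixture, seed = as.integer(seed),
                 use_provided_labels = isTRUE(use_provided_labels),
                 train_fraction = train_fraction, cv_k = as.integer(cv_k),
                 unet = unet,
                 qstnet = qstnet, thresholds = thresholds,
                 input_paths = input_paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full pipeline
#'
#' Stages: (1) generate a phantom cohort (or ingest NIfTI pairs); (2)
#' either train the segmentation network on a training split and predict
#' the rest, or take the provided label maps as the segmentation; (3)
#' extract the 34 clinical features; (4) diagnose every sample with both
#' the clinical scale and the multimodal network (5-fold CV); (5) write
#' Dice and classification reports, the feature table, predictions and the
#' resolved configuration to `out_dir`. Any stage failure aborts with an
#' error naming the stage; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return List with `dice` (a `dice_report` or `NULL` when segmentation
#'   is skipped), `scale_report`, `network_report`, `features`,
#'   `predictions` and `out_dir`, invisibly returned file paths in
#'   `files`.
#' @export
run_full <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stage <- function(name, expr) {
    log_stage("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("data", {
    if (!is.null(config$input_paths)) {
      ip <- config$input_paths
      samples <- lapply(seq_along(ip$mri), function(i) {
        list(mri = read_volume(ip$mri[[i]]),
             map = read_volume(ip$labels[[i]], expect_labels = TRUE),
             type = ip$type[[i]])
      })
      list(samples = samples,
           manifest = data.frame(id = seq_along(samples),
                                 type = unlist(ip$type)))
    } else {
      generate_cohort(config$n_phantoms, config$mixture, config$seed)
    }
  })
  n <- length(cohort$samples)
  types <- vapply(cohort$samples, `[[`, character(1), "type")

  seg <- stage("segmentation", {
    if (config$use_provided_labels) {
      log_stage("using provided label maps; segmentation training skipped")
      list(maps = lapply(cohort$samples, `[[`, "map"), dice = NULL)
    } else {
      ucfg <- do.call(unet_config, c(config$unet,
                                     list(seed = config$seed)))
      ntrain <- max(1L, round(config$train_fraction * n))
      tr_idx <- with_seed(config$seed, sample.int(n, ntrain))
      slices <- phantom_slices(cohort$samples[tr_idx], ucfg$input_size,
                               min_tumor_px = 50L)
      fit <- train_segmentation(slices, ucfg)
      maps <- vector("list", n)
      dices <- list()
      for (i in seq_len(n)) {
        maps[[i]] <- predict_segmentation(fit$net, cohort$samples[[i]]$mri)
        if (!(i %in% tr_idx))
          dices[[length(dices) + 1L]] <-
            multiclass_dice(maps[[i]], cohort$samples[[i]]$map)
      }
      per <- rowMeans(vapply(dices, function(d) d$per_class, numeric(6)))
      dice_rep <- structure(list(per_class = per, mean = mean(per)),
                            class = "dice_report")
      list(maps = maps, dice = dice_rep)
    }
  })

  feats <- stage("features", {
    df <- feature_table(seg$maps,
                        path = file.path(config$out_dir, "features.csv"))
    files <<- c(files, file.path(config$out_dir, "features.csv"))
    df
  })

  scale_rep <- stage("scale", {
    preds <- vapply(seg$maps, function(m)
      qst_scale(m, config$thresholds)$type, character(1))
    classification_report(types, preds)
  })

  net_res <- stage("classification_network", {
    qcfg <- do.call(qstnet_config, c(config$qstnet,
                                     list(seed = config$seed)))
    prepared <- lapply(seq_len(n), function(i)
      prepare_inputs(cohort$samples[[i]]$mri, seg$maps[[i]],
                     qcfg$input_size))
    folds <- make_cv_folds(n, config$cv_k, labels = types,
                           seed = config$seed)
    train_classifier(prepared, types, qcfg, folds = folds)
  })

  stage("reports", {
    if (!is.null(seg$dice)) {
      write_report(seg$dice, file.path(config$out_dir, "dice_report.csv"))
      files <<- c(files, file.path(config$out_dir, "dice_report.csv"))
    }
    write_report(scale_rep, file.path(config$out_dir, "scale_report.csv"))
    write_report(net_res$report,
                 file.path(config$out_dir, "network_report.csv"))
    write.csv(net_res$predictions,
              file.path(config$out_dir, "network_predictions.csv"),
              row.names = FALSE)
    cfg_out <- config
    cfg_out$input_paths <- NULL
    yaml::write_yaml(unclass(cfg_out),
                     file.path(config$out_dir, "resolved_config.yaml"))
    files <<- c(files,
                file.path(config$out_dir,
                          c("scale_report.csv", "network_report.csv",
                            "network_predictions.csv",
                            "resolved_config.yaml")))
  })

  log_stage("done; outputs in ", config$out_dir)
  list(dice = seg$dice, scale_report = scale_rep,
       network_report = net_res$report, features = feats,
       predictions = net_res$predictions, out_dir = config$out_dir,
       files = files)
}
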