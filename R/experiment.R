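#' @title Experiment driver
#'
#' @description Wires the whole pipeline for the four training/testing
#'   modes -- `axi` and `sag` (single plane), `axi_sag` (pooled single-frame
#'   images of both planes) and `bg` (bipartite edge fusion) -- each with or
#'   without the age prior. All modes share the same backbone and
#'   decision-layer fusion; only the data presented to the model differs.
#'
#' @name experiment
NULL

#' Experiment configuration
#'
#' Exactly one data source must be given: `train_manifest`/`test_manifest`
#' (paths or in-memory manifests) or a [phantom_config()] to generate data
#' in-run (the test split is generated with an independent seed derived
#' from the phantom seed).
#'
#' @param mode `"axi"`, `"sag"`, `"axi_sag"` or `"bg"`.
#' @param use_age Blend the training-set age prior into the decision fusion.
#' @param train_manifest,test_manifest Manifest paths or `dataset_manifest`
#'   objects.
#' @param phantom A [phantom_config()], or `NULL`.
#' @param n_test_patients Test-split size when generating phantoms.
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param augment An [augment_config()]; its `output_side` must match the
#'   model's `input_side`.
#' @param fusion A [fusion_params()].
#' @param age_bin_width Age-prior bin width in years.
#' @param output_dir Optional directory for run artifacts (predictions CSV,
#'   metrics JSON, loss trace, resolved config).
#' @param seed Global seed; fans out to phantom generation, model
#'   initialization and the training loop unless those configs carry their
#'   own explicit seeds.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("bg", "axi", "sag", "axi_sag"),
                              use_age = FALSE,
                              train_manifest = NULL, test_manifest = NULL,
                              phantom = NULL, n_test_patients = 20L,
                              model = model_config(tiny_preset = TRUE),
                              train = train_config(),
                              augment = NULL,
                              fusion = fusion_params(),
                              age_bin_width = 10,
                              output_dir = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  has_manifests <- !is.null(train_manifest) && !is.null(test_manifest)
  if (identical(has_manifests, !is.null(phantom)))
    stop("exactly one data source: train/test manifests XOR a phantom config",
         call. = FALSE)
  if (is.null(augment))
    augment <- augment_config(output_side = model$input_side)
  if (augment$output_side != model$input_side)
    stop("augment output_side must match the model input_side", call. = FALSE)
  structure(list(mode = mode, use_age = use_age,
                 train_manifest = train_manifest,
                 test_manifest = test_manifest,
                 phantom = phantom, n_test_patients = as.integer(n_test_patients),
                 model = model, train = train, augment = augment,
                 fusion = fusion, age_bin_width = age_bin_width,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

resolve_manifest <- function(x, split) {
  if (inherits(x, "dataset_manifest")) x
  else read_manifest(x)
}

experiment_data <- function(config) {
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    train_cfg <- ph
    test_cfg <- ph
    test_cfg$n_patients <- config$n_test_patients
    test_cfg$seed <- ph$seed + 10000L
    list(train = generate_dataset(train_cfg, split = "train"),
         test = generate_dataset(test_cfg, split = "test"))
  } else {
    list(train = resolve_manifest(config$train_manifest, "train"),
         test = resolve_manifest(config$test_manifest, "test"))
  }
}

# Build the per-patient probability sets C on the test split:
# single-plane modes give one element per image of that plane, axi_sag
# n + m per-image elements, bg all n x m edge probabilities.
patient_probability_sets <- function(model, manifest, mode, augment) {
  out <- list()
  for (p in manifest$patients) {
    inputs <- switch(mode,
      bg = {
        es <- enumerate_edges(p)
        lapply(seq_len(nrow(es$edges)), function(i)
          prepare_edge(p$axial_images[[es$edges$axial_index[i]]],
                       p$sagittal_images[[es$edges$sagittal_index[i]]],
                       augment, train = FALSE))
      },
      axi = lapply(p$axial_images, prepare_single, config = augment,
                   train = FALSE),
      sag = lapply(p$sagittal_images, prepare_single, config = augment,
                   train = FALSE),
      axi_sag = lapply(c(p$axial_images, p$sagittal_images), prepare_single,
                       config = augment, train = FALSE))
    if (length(inputs) == 0L)
      stop(sprintf("patient '%s' has no images for mode '%s'",
                   p$patient_id, mode), call. = FALSE)
    out[[p$patient_id]] <- predict_proba(model, inputs)
  }
  out
}

#' Run one experiment end to end
#'
#' Generates or loads the data, trains the backbone in the configured mode,
#' builds each test patient's probability set C, applies decision-layer
#' fusion (with the age prior when `use_age`), and computes patient-level
#' metrics. With `output_dir` set, writes `predictions.csv`,
#' `metrics.json`, `loss_trace.csv` and `config.yaml`.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-epoch training progress.
#' @return List with `metrics` (a `metrics_report`), `predictions` (data
#'   frame), `fused` (list of `patient_prediction`), `loss_trace`,
#'   `acc_trace`, `model`, `prior` and the resolved `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  data <- experiment_data(config)
  train_cfg <- config$train
  if (is.null(train_cfg$seed) || is.na(train_cfg$seed))
    train_cfg$seed <- config$seed
  model <- build_model(config$model, seed = config$seed)
  fit <- train_model(model, data$train, mode = config$mode,
                     augment = config$augment, train_cfg = train_cfg,
                     verbose = verbose)
  prior <- if (config$use_age)
    build_age_prior(data$train, bin_width = config$age_bin_width) else NULL
  sets <- patient_probability_sets(fit$model, data$test, config$mode,
                                   config$augment)
  ages <- vapply(data$test$patients, `[[`, numeric(1), "age")
  names(ages) <- vapply(data$test$patients, `[[`, character(1), "patient_id")
  fused <- fuse_cohort(sets, ages = ages[names(sets)], prior = prior,
                       params = config$fusion)
  truth <- vapply(data$test$patients, `[[`, character(1), "label")
  names(truth) <- names(ages)
  scores <- stats::setNames(
    vapply(fused, function(f) if (f$degenerate) 0.5 else f$pm, numeric(1)),
    vapply(fused, `[[`, character(1), "patient_id"))
  metrics <- metrics_report(fused, truth, scores = scores,
                            threshold = config$fusion$threshold)
  predictions <- data.frame(
    patient_id = names(scores),
    pb = vapply(fused, function(f) if (f$degenerate) NA_real_ else f$pb,
                numeric(1)),
    pm = vapply(fused, function(f) if (f$degenerate) NA_real_ else f$pm,
                numeric(1)),
    q = vapply(fused, `[[`, integer(1), "q"),
    w = vapply(fused, `[[`, integer(1), "w"),
    degenerate = vapply(fused, `[[`, logical(1), "degenerate"),
    label = vapply(fused, `[[`, character(1), "label"),
    truth = truth[names(scores)],
    stringsAsFactors = FALSE)
  result <- list(metrics = metrics, predictions = predictions, fused = fused,
                 loss_trace = fit$loss_trace, acc_trace = fit$acc_trace,
                 model = fit$model, prior = prior, config = config,
                 test_truth = truth)
  if (!is.null(config$output_dir)) write_run_artifacts(result, config)
  result
}

write_run_artifacts <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$predictions,
                   file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  m <- result$metrics
  jsonlite::write_json(
    list(N = m$N, ACC = m$ACC, SE = m$SE, SP = m$SP, AUC = m$AUC,
         halfwidths = as.list(m$halfwidths), threshold = m$threshold,
         seed = config$seed),
    file.path(config$output_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(
    data.frame(epoch = seq_along(result$loss_trace),
               loss = result$loss_trace, train_acc = result$acc_trace),
    file.path(config$output_dir, "loss_trace.csv"), row.names = FALSE)
  yaml::write_yaml(serialize_config(config),
                   file.path(config$output_dir, "config.yaml"))
  invisible(NULL)
}

serialize_config <- function(config) {
  drop_class <- function(x)
    if (is.list(x)) lapply(unclass(x), drop_class) else x
  cfg <- config
  cfg$train_manifest <- if (inherits(cfg$train_manifest, "dataset_manifest"))
    "<in-memory>" else cfg$train_manifest
  cfg$test_manifest <- if (inherits(cfg$test_manifest, "dataset_manifest"))
    "<in-memory>" else cfg$test_manifest
  drop_class(cfg)
}

#' Compare several experiment modes on shared data
#'
#' Runs each config (they must share the data source and seed so every mode
#' sees the same train/test split) and tabulates one row per run, mirroring
#' a mode-comparison results table.
#'
#' @param configs List of [experiment_config()] differing only in `mode` /
#'   `use_age`.
#' @param verbose Print training progress.
#' @return List with `table` (data frame: mode, use_age, AUC/ACC/SE/SP and
#'   half-widths) and `runs` (the individual [run_experiment()] results).
#' @export
compare_modes <- function(configs, verbose = FALSE) {
  stopifnot(length(configs) >= 1L)
  key <- function(cfg) {
    if (!is.null(cfg$phantom))
      paste("phantom", cfg$phantom$seed, cfg$n_test_patients)
    else paste("manifest", format(cfg$test_manifest))
  }
  keys <- vapply(configs, key, character(1))
  if (length(unique(keys)) != 1L)
    stop("all configs in a comparison must share the same test data source",
         call. = FALSE)
  runs <- lapply(configs, run_experiment, verbose = verbose)
  rows <- lapply(runs, function(r) {
    m <- r$metrics
    data.frame(mode = r$config$mode, use_age = r$config$use_age,
               AUC = m$AUC, ACC = m$ACC, SE = m$SE, SP = m$SP,
               AUC_hw = m$halfwidths[["AUC"]], ACC_hw = m$halfwidths[["ACC"]],
               SE_hw = m$halfwidths[["SE"]], SP_hw = m$halfwidths[["SP"]],
               N = m$N, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), runs = runs)
}
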