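#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis (simulate ->
#' preprocess -> features -> compare -> classify) into one serialisable
#' object. Defaults reproduce the study conditions on synthetic data:
#' 12-second epochs at 500 Hz, a 0.5-60 Hz pass band, embedding m = 10 and
#' lag = 1, 300 epochs per group with a balanced 150/150 train/test split.
#'
#' @param master_seed Integer seed from which every stage's randomness is
#'   derived.
#' @param n_per_group Epochs generated per group.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_seconds Epoch duration in seconds.
#' @param band_low_hz,band_high_hz,filter_order Band-pass settings.
#' @param m,lag Embedding dimension and delay.
#' @param theiler Theiler window (`NULL` for `m * lag`).
#' @param n_train_per_class,n_test_per_class Split sizes for the SVM.
#' @param out_dir Output directory for persisted artifacts.
#' @param write_epochs Whether to persist every epoch as a text file.
#' @return A list of class `chaos_pipeline_config`.
#' @export
chaos_pipeline_config <- function(master_seed = 1L, n_per_group = 300L,
                                  sampling_rate = 500, epoch_seconds = 12,
                                  band_low_hz = 0.5, band_high_hz = 60,
                                  filter_order = 6L, m = 10L, lag = 1L,
                                  theiler = NULL,
                                  n_train_per_class = 150L,
                                  n_test_per_class = 150L,
                                  out_dir = file.path(tempdir(), "chaos_run"),
                                  write_epochs = TRUE) {
  cfg <- list(master_seed = as.integer(master_seed),
              n_per_group = as.integer(n_per_group),
              sampling_rate = as.numeric(sampling_rate),
              epoch_seconds = as.numeric(epoch_seconds),
              band_low_hz = as.numeric(band_low_hz),
              band_high_hz = as.numeric(band_high_hz),
              filter_order = as.integer(filter_order),
              m = as.integer(m), lag = as.integer(lag),
              theiler = if (is.null(theiler)) as.integer(m) * as.integer(lag)
                        else as.integer(theiler),
              n_train_per_class = as.integer(n_train_per_class),
              n_test_per_class = as.integer(n_test_per_class),
              out_dir = as.character(out_dir),
              write_epochs = isTRUE(write_epochs))
  # validate nested configs early
  preprocess_config(cfg$band_low_hz, cfg$band_high_hz, cfg$epoch_seconds,
                    cfg$filter_order)
  if (cfg$n_per_group < 1) stop("n_per_group must be >= 1")
  structure(cfg, class = "chaos_pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips a [chaos_pipeline_config()] through a human-readable YAML
#' file; reading re-validates through the constructor so
#' `read_pipeline_config(write_pipeline_config(cfg, f))` is identical to
#' `cfg`.
#'
#' @param config A `chaos_pipeline_config`.
#' @param path File path.
#' @return `path` invisibly (write); the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "chaos_pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(chaos_pipeline_config, yaml::read_yaml(path))
}

# Hash of the scientific configuration only: where the artifacts land
# (out_dir, write_epochs) does not change what was computed.
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "write_epochs"))]
  fnv1a_hash(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full chaotic-analysis pipeline
#'
#' Executes simulate -> preprocess -> features -> compare -> classify with
#' every stage's randomness derived from `master_seed`, and persists the
#' cohort manifest, the feature table, the group-comparison report, ROC
#' coordinates for both features, and the classifier report under
#' `config$out_dir`. Re-running with the same configuration overwrites the
#' same artifacts byte-for-byte; stage timings are logged to the console
#' only, so they never perturb the persisted outputs.
#'
#' @param config A [chaos_pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return An object of class `chaos_pipeline_result` with elements
#'   `features` (data frame), `comparison` (per-feature
#'   [compare_groups()] and [roc_curve()] results), `classifier`
#'   (a [svm_classify()] report), `config`, `config_hash`, `out_dir` and
#'   `warnings`.
#' @export
run_chaos_pipeline <- function(config = chaos_pipeline_config(),
                               quiet = FALSE) {
  stopifnot(inherits(config, "chaos_pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warn_log <<- c(warn_log, sprintf("%s: %s", name,
                                         conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (!quiet)
      message(sprintf("[%s] done in %.1f s", name,
                      proc.time()[["elapsed"]] - t0))
    res
  }

  n_samples <- round(config$epoch_seconds * config$sampling_rate)
  cohort <- log_stage("simulate", {
    coh <- generate_cohort(config$n_per_group, seed = config$master_seed,
                           n_samples = n_samples,
                           sampling_rate = config$sampling_rate)
    if (config$write_epochs) write_cohort(coh, config$out_dir)
    coh
  })

  pc <- preprocess_config(config$band_low_hz, config$band_high_hz,
                          config$epoch_seconds, config$filter_order)
  filtered <- log_stage("preprocess",
                        lapply(cohort$epochs, bandpass, config = pc))

  features <- log_stage("features", {
    ft <- cohort_features(filtered, labels = as.character(cohort$labels),
                          m = config$m, lag = config$lag,
                          theiler = config$theiler)
    ft$config_hash <- hash
    write.csv(ft, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    ft
  })

  comparison <- log_stage("compare", {
    out <- lapply(c(cd = "cd", lle = "lle"), function(feat) {
      cmp <- compare_groups(features[[feat]], features$label, feat)
      roc <- roc_curve(features[[feat]], features$label,
                       positive = "encephalopathy", orientation = "lower")
      write.csv(data.frame(threshold = roc$thresholds,
                           sensitivity = roc$sensitivity,
                           specificity = roc$specificity),
                file.path(config$out_dir, sprintf("roc_%s.csv", feat)),
                row.names = FALSE)
      list(comparison = cmp, roc = roc)
    })
    report <- lapply(out, function(o) list(
      feature = o$comparison$feature_name,
      groups = stats::setNames(o$comparison$groups,
                               o$comparison$group_names),
      u_statistic = o$comparison$u_statistic,
      z_value = o$comparison$z_value,
      p_value = o$comparison$p_value,
      auc = o$roc$auc,
      orientation = o$roc$orientation))
    write_json_file(list(config_hash = hash, features = report),
                    file.path(config$out_dir, "comparison.json"))
    out
  })

  classifier <- log_stage("classify", {
    parts <- split_features(features, config$n_train_per_class,
                            config$n_test_per_class,
                            seed = config$master_seed)
    rep <- svm_classify(parts$train, parts$test)
    write_json_file(
      list(config_hash = hash,
           matrix = rep$matrix[c("tn", "fp", "fn", "tp", "positive")],
           accuracy = rep$accuracy, sensitivity = rep$sensitivity,
           specificity = rep$specificity, model = rep$model),
      file.path(config$out_dir, "classifier.json"))
    rep
  })

  write_json_file(
    list(config = unclass(config), config_hash = hash,
         n_epochs = length(cohort$epochs),
         warnings = if (length(warn_log)) warn_log else list()),
    file.path(config$out_dir, "report.json"))

  structure(list(features = features, comparison = comparison,
                 classifier = classifier, config = config,
                 config_hash = hash, out_dir = config$out_dir,
                 warnings = warn_log),
            class = "chaos_pipeline_result")
}

#' @export
print.chaos_pipeline_result <- function(x, ...) {
  cat(sprintf("<chaos_pipeline_result> %d epochs, config %s\n",
              nrow(x$features), x$config_hash))
  cat(sprintf("  artifacts in %s\n", x$out_dir))
  for (feat in names(x$comparison)) {
    o <- x$comparison[[feat]]
    cat(sprintf("  %-3s: medians %.3f vs %.3f, z = %.2f, p = %.3g, AUC = %.3f\n",
                feat, o$comparison$groups[[1]]$median,
                o$comparison$groups[[2]]$median, o$comparison$z_value,
                o$comparison$p_value, o$roc$auc))
  }
  cat(sprintf("  SVM test accuracy %.2f%%\n", 100 * x$classifier$accuracy))
  invisible(x)
}

#' @export
summary.chaos_pipeline_result <- function(object, ...) {
  print(object)
  for (feat in names(object$comparison))
    print(object$comparison[[feat]]$comparison)
  print(object$classifier)
  invisible(object)
}
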