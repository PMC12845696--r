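pipeline_config_keys <- function()
  c("synth", "input_dir", "filter", "n_samples", "sampen", "bands",
    "feature_set", "effects_features", "models", "k_folds", "nu",
    "variability_features", "seed", "out_dir")

#' Resolve and validate a pipeline configuration
#'
#' Merges user settings over the defaults and rejects unknown keys by
#' name. A configuration must provide either an \code{input_dir} of
#' recording CSVs or a \code{synth} block (synthetic cohort parameters
#' forwarded to \code{\link{synth_config}}).
#'
#' @param config Named list, or path to a YAML/JSON config file.
#' @return Validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(synth = NULL, input_dir = NULL,
                   filter = list(order = 4, cutoff = 20),
                   n_samples = 128L,
                   sampen = list(m = 2, r = 0.2),
                   bands = list(c(0.5, 3), c(3, 8), c(8, 20)),
                   feature_set = "extended",
                   effects_features = c("acc_mag_kurt", "acc_z_mean",
                                        "acc_y_max", "gyro_y_rms"),
                   models = c("rf", "svm", "gb"),
                   k_folds = 5L, nu = 0.1,
                   variability_features = c("acc_mag_rms", "gyro_mag_rms"),
                   seed = 1L, out_dir = "stridefatigue-out")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$synth) && is.null(cfg$input_dir))
    stop("configuration must provide either 'synth' or 'input_dir'")
  if (!is.null(cfg$synth)) {
    unknown <- setdiff(names(cfg$synth), names(formals(synth_config)))
    if (length(unknown))
      stop("unknown synth key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$feature_set <- match.arg(cfg$feature_set, c("base", "extended"))
  cfg$models <- match.arg(cfg$models, c("rf", "svm", "gb"),
                          several.ok = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- function()
  c("simulate", "segment", "features", "effects", "global-eval",
    "personal-eval", "variability")

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

read_stage_csv <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream output ", path, " required by stage '", stage,
         "'; run the preceding stage first")
  as.data.frame(data.table::fread(path))
}

#' Run one pipeline stage
#'
#' Stages communicate exclusively through CSV files under the configured
#' output directory, so chained single-stage runs produce identical files
#' to a one-shot \code{\link{run_pipeline}} on the same seed.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param stage One of \code{simulate}, \code{segment}, \code{features},
#'   \code{effects}, \code{global-eval}, \code{personal-eval},
#'   \code{variability}.
#' @return Invisibly, the paths written by the stage.
#' @export
run_stage <- function(cfg, stage) {
  stage <- match.arg(stage, pipeline_stages())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         "simulate" = stage_simulate(cfg),
         "segment" = stage_segment(cfg),
         "features" = stage_features(cfg),
         "effects" = stage_effects(cfg),
         "global-eval" = stage_global(cfg),
         "personal-eval" = stage_personal(cfg),
         "variability" = stage_variability(cfg))
}

stage_simulate <- function(cfg) {
  if (is.null(cfg$synth)) stop("no 'synth' block in configuration")
  scfg <- do.call(synth_config,
                  utils::modifyList(cfg$synth, list(seed = cfg$seed)))
  cohort <- generate_cohort(scfg)
  rec_dir <- stage_path(cfg, "recordings")
  dir.create(rec_dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(rec_dir, sprintf("%s_%s.csv",
                                                    rec$participant_id,
                                                    rec$condition)))
  }
  gt_path <- stage_path(cfg, "ground_truth.csv")
  data.table::fwrite(cohort$ground_truth, gt_path)
  message("simulate: wrote ", length(cohort$recordings), " recordings")
  invisible(c(rec_dir, gt_path))
}

stage_segment <- function(cfg) {
  rec_dir <- if (!is.null(cfg$input_dir)) cfg$input_dir else
    stage_path(cfg, "recordings")
  files <- sort(list.files(rec_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files))
    stop("no recording CSVs found in ", rec_dir,
         "; run the simulate stage or point input_dir at recordings")
  fspec <- filter_spec(order = cfg$filter$order, cutoff = cfg$filter$cutoff)
  all_windows <- list()
  n_detected <- 0L
  for (f in files) {
    rec <- read_recording(f)
    for (ch in raw_channel_names())
      rec$data[[ch]] <- lowpass_filter(rec$data[[ch]], rec$sampling_rate,
                                       fspec)
    rec <- add_magnitude_channels(rec)
    events <- detect_foot_strikes(rec$data$az, rec$sampling_rate)
    if (!isTRUE(attr(events, "segmentable"))) {
      warning("recording ", basename(f), " not segmentable; skipped")
      next
    }
    n_detected <- n_detected + length(events)
    wins <- segment_and_normalize(rec, events, N = cfg$n_samples)
    all_windows <- c(all_windows, unclass(wins))
  }
  if (!length(all_windows)) stop("no stride windows produced")
  windows <- structure(all_windows, class = "stride_windows",
                       N = as.integer(cfg$n_samples))
  path <- stage_path(cfg, "stride_windows.csv")
  data.table::fwrite(windows_to_table(windows), path)
  message("segment: ", n_detected, " foot strikes detected, ",
          length(all_windows), " stride windows written")
  invisible(path)
}

stage_features <- function(cfg) {
  tab <- read_stage_csv(stage_path(cfg, "stride_windows.csv"), "features")
  windows <- table_to_windows(tab)
  ft <- build_feature_table(
    windows,
    sampen = sampen_params(cfg$sampen$m, cfg$sampen$r),
    bands = band_spec(cfg$bands),
    extended = identical(cfg$feature_set, "extended"))
  path <- stage_path(cfg, "features.csv")
  data.table::fwrite(ft, path)
  message("features: ", nrow(ft), " strides x ", ncol(ft) - 3, " features")
  invisible(path)
}

load_feature_table <- function(cfg, stage) {
  ft <- read_stage_csv(stage_path(cfg, "features.csv"), stage)
  if (!"participant" %in% names(ft))
    stop("feature table lacks the 'participant' column")
  if (!"condition" %in% names(ft))
    stop("feature table lacks the 'condition' column")
  ft
}

stage_effects <- function(cfg) {
  ft <- load_feature_table(cfg, "effects")
  features <- intersect(cfg$effects_features, names(ft))
  if (!length(features))
    stop("none of the requested effects features are in the table")
  et <- effects_table(ft, features)
  p1 <- stage_path(cfg, "effects.csv")
  p2 <- stage_path(cfg, "forest.csv")
  data.table::fwrite(et$effects, p1)
  data.table::fwrite(et$forest, p2)
  message("effects: ", nrow(et$effects), " features fitted, ",
          length(et$failures), " failed")
  invisible(c(p1, p2))
}

stage_global <- function(cfg) {
  ft <- load_feature_table(cfg, "global-eval")
  folds <- lopo_splits(ft)
  paths <- character(0)
  summaries <- list()
  for (model in cfg$models) {
    res <- train_eval_feature_model(ft, model, folds,
                                    features = base_feature_names(ft),
                                    seed = cfg$seed)
    p <- stage_path(cfg, sprintf("lopo_%s.csv", model))
    data.table::fwrite(res$per_participant, p)
    paths <- c(paths, p)
    s <- res$summary
    s$model <- model
    summaries[[model]] <- s
    if (!is.null(res$importance)) {
      pi <- stage_path(cfg, "importance_rf.csv")
      data.table::fwrite(res$importance, pi)
      paths <- c(paths, pi)
    }
    message("global-eval [", model, "]: ", nrow(res$per_participant),
            " folds, mean accuracy ",
            sprintf("%.4f", res$summary$accuracy[1]))
  }
  ps <- stage_path(cfg, "lopo_summary.csv")
  data.table::fwrite(do.call(rbind, c(summaries, make.row.names = FALSE)), ps)
  invisible(c(paths, ps))
}

stage_personal <- function(cfg) {
  ft <- load_feature_table(cfg, "personal-eval")
  features <- base_feature_names(ft)
  sup <- list(); anom <- list()
  skipped <- 0L
  for (p in unique(as.character(ft$participant))) {
    ft_p <- ft[ft$participant == p, ]
    sup[[p]] <- tryCatch(
      personal_supervised_cv(ft_p, K = cfg$k_folds, features = features,
                             seed = cfg$seed),
      error = function(e) { warning("supervised [", p, "]: ",
                                    conditionMessage(e)); NULL })
    anom[[p]] <- tryCatch({
      nf_rows <- ft_p[ft_p$condition == 0, features]
      model <- fit_nf_ocsvm(nf_rows, nu = cfg$nu)
      evaluate_anomaly(model, ft_p)
    }, error = function(e) { warning("anomaly [", p, "]: ",
                                     conditionMessage(e)); NULL })
    if (is.null(anom[[p]])) skipped <- skipped + 1L
  }
  sup_df <- do.call(rbind, c(Filter(Negate(is.null), sup),
                             make.row.names = FALSE))
  anom_df <- do.call(rbind, c(Filter(Negate(is.null), anom),
                              make.row.names = FALSE))
  paths <- character(0)
  if (!is.null(sup_df)) {
    p1 <- stage_path(cfg, "personal_supervised.csv")
    data.table::fwrite(sup_df, p1)
    data.table::fwrite(aggregate_personal(sup_df),
                       stage_path(cfg, "personal_supervised_summary.csv"))
    paths <- c(paths, p1)
  }
  if (!is.null(anom_df)) {
    p2 <- stage_path(cfg, "personal_anomaly.csv")
    data.table::fwrite(anom_df, p2)
    data.table::fwrite(aggregate_personal(anom_df),
                       stage_path(cfg, "personal_anomaly_summary.csv"))
    paths <- c(paths, p2)
  }
  message("personal-eval: ", length(sup), " participants, ", skipped,
          " anomaly model(s) skipped")
  invisible(paths)
}

stage_variability <- function(cfg) {
  ft <- load_feature_table(cfg, "variability")
  features <- intersect(cfg$variability_features, names(ft))
  if (!length(features))
    stop("none of the requested variability features are in the table")
  records <- variability_table(ft, features,
                               sampen = sampen_params(cfg$sampen$m,
                                                      cfg$sampen$r))
  deltas <- state_deltas(records)
  p1 <- stage_path(cfg, "variability.csv")
  p2 <- stage_path(cfg, "variability_deltas.csv")
  data.table::fwrite(records, p1)
  data.table::fwrite(deltas, p2)
  message("variability: ", nrow(records), " records, ",
          nrow(deltas), " deltas")
  invisible(c(p1, p2))
}

#' Run the full fatigue-analysis pipeline
#'
#' Orchestrates all stages end to end: synthetic cohort generation (or
#' ingestion of recording CSVs), filtering and stride segmentation, feature
#' extraction, mixed-effects fatigue effects, global LOPO classification,
#' personalized supervised and anomaly models, and variability reporting.
#' All randomness flows from \code{seed}; identical configurations produce
#' byte-identical output tables. The resolved configuration is written next
#' to the outputs as \code{config.yaml}.
#'
#' @param config A \code{\link{pipeline_config}}, a plain list, or a path
#'   to a YAML/JSON configuration file.
#' @param stages Stages to run, in pipeline order (default: all that are
#'   applicable; \code{simulate} is skipped when \code{input_dir} is set).
#' @return Invisibly, a named list of the files each stage wrote.
#' @export
run_pipeline <- function(config, stages = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  all_stages <- pipeline_stages()
  if (is.null(stages)) {
    stages <- all_stages
    if (is.null(cfg$synth)) stages <- setdiff(stages, "simulate")
  } else {
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
    stages <- all_stages[all_stages %in% stages]
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), stage_path(cfg, "config.yaml"))
  outputs <- list()
  for (stage in stages) {
    outputs[[stage]] <- run_stage(cfg, stage)
  }
  invisible(outputs)
}
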