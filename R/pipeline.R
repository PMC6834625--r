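# File-based pipeline stages: each stage reads/writes the CSV formats the
# ingest functions understand and records a JSON manifest (config snapshot,
# seeds, file hashes, timing, warnings) so a run is auditable and
# re-runnable.

manifest_files <- function(paths) {
  tibble(
    path = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths))
  )
}

write_manifest <- function(out_dir, stage, config, seed, files, t0,
                           warnings = character(0)) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("swayrisk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
    warnings = warnings,
    files = manifest_files(files)
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort and writes one CSV per recording
#' (`<id>.csv`, columns `ap`, `ml` in cm) plus `participants.csv` and a run
#' manifest with content hashes. Round-trips through [read_cop_file()].
#'
#' @param out_dir output directory (created if needed).
#' @param config a [cohort_config()], or a path to a YAML file whose keys
#'   are `cohort_config()` arguments.
#' @return (invisibly) the manifest list.
#' @export
simulate_cohort_files <- function(out_dir, config = cohort_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.character(config)) config <- load_cohort_yaml(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  paths <- character(0)
  for (id in names(cohort$recordings)) {
    p <- file.path(out_dir, paste0(id, ".csv"))
    rec <- cohort$recordings[[id]]
    readr::write_csv(tibble(ap = sprintf("%.6f", rec$ap),
                            ml = sprintf("%.6f", rec$ml)), p, quote = "none")
    paths <- c(paths, p)
  }
  ppath <- file.path(out_dir, "participants.csv")
  readr::write_csv(cohort$participants, ppath)
  paths <- c(paths, ppath)
  cfg_plain <- lapply(unclass(config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  invisible(write_manifest(out_dir, "simulate", cfg_plain, config$seed,
                           paths, t0))
}

# YAML keys map 1:1 to cohort_config() arguments; per-group values are
# named maps.
load_cohort_yaml <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("Malformed YAML config ", path, ": ", conditionMessage(e)),
          class = "swayrisk_configuration_error")
  })
  if (!is.list(cfg)) {
    abort(paste0("YAML config ", path, " must be a mapping."),
          class = "swayrisk_configuration_error")
  }
  vecs <- c("group_sizes", "sigma_ml", "sigma_ap", "rho", "bbs_mean",
            "bbs_sd", "conf_mean", "conf_sd", "ppa_mean", "ppa_sd")
  for (v in intersect(vecs, names(cfg))) cfg[[v]] <- unlist(cfg[[v]])
  do.call(cohort_config, cfg)
}

#' Extract features for every recording in a directory
#'
#' Reads each `<id>.csv` recording in `in_dir` (skipping
#' `participants.csv`), preprocesses it and extracts the sway metric panel,
#' writing a tidy feature CSV (one row per trial) and a manifest.
#'
#' @param in_dir directory written by [simulate_cohort_files()] (or any
#'   directory of compatible recordings).
#' @param out_csv path of the feature CSV to write.
#' @param sampling_rate sampling rate of the recordings (Hz); required
#'   metadata for tabular exports.
#' @param cutoff_hz,order,eparams,sparams,entropy_fs see
#'   [extract_cohort_features()].
#' @return (invisibly) the feature tibble.
#' @export
extract_features_files <- function(in_dir, out_csv, sampling_rate,
                                   cutoff_hz = 10, order = 4,
                                   eparams = entropy_params(),
                                   sparams = spectral_params(),
                                   entropy_fs = 100) {
  t0 <- as.numeric(Sys.time())
  if (missing(sampling_rate) || is.null(sampling_rate)) {
    abort("`sampling_rate` must be supplied for feature extraction.",
          class = "swayrisk_configuration_error")
  }
  files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "participants.csv"]
  if (!length(files)) {
    abort(paste0("No recording CSVs found in ", in_dir),
          class = "swayrisk_input_error")
  }
  cfg <- ingest_config(sampling_rate = sampling_rate)
  recs <- lapply(sort(files), read_cop_file, config = cfg)
  feats <- extract_cohort_features(recs, cutoff_hz = cutoff_hz, order = order,
                                   eparams = eparams, sparams = sparams,
                                   entropy_fs = entropy_fs)
  dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(feats, out_csv)
  write_manifest(dirname(out_csv), "extract",
                 list(sampling_rate = sampling_rate, cutoff_hz = cutoff_hz,
                      order = order, m = eparams$m, r_coeff = eparams$r_coeff,
                      band = c(sparams$band_low, sparams$band_high),
                      psd_method = sparams$psd_method,
                      entropy_fs = entropy_fs),
                 NA, out_csv, t0)
  invisible(feats)
}

#' Classify a cohort from feature and participant tables
#'
#' Joins the feature table with the prepared participant table and runs
#' every pairwise random-forest comparison, writing the diagnostic results
#' CSV (metrics in percent, one decimal), a JSON importance report, and a
#' manifest.
#'
#' @param features_csv feature table CSV from [extract_features_files()]
#'   (or a tibble).
#' @param participants_csv participant table CSV (or a tibble) with
#'   `participant_id`, `is_ms`, `ppa`, `bbs`, `abc`, `fes_i`.
#' @param out_dir output directory.
#' @param feature_sets,config see [run_all_comparisons()].
#' @return (invisibly) the `sway_report`.
#' @export
classify_cohort <- function(features_csv, participants_csv, out_dir,
                            feature_sets = c("sway", "clinical"),
                            config = forest_config()) {
  t0 <- as.numeric(Sys.time())
  feats <- if (is.character(features_csv)) {
    readr::read_csv(features_csv, show_col_types = FALSE)
  } else as_tibble(features_csv)
  parts <- if (is.character(participants_csv)) {
    readr::read_csv(participants_csv, show_col_types = FALSE)
  } else as_tibble(participants_csv)
  parts <- prepare_participants(parts)
  data <- dplyr::inner_join(feats, parts, by = "participant_id")
  if (!nrow(data)) {
    abort("Feature and participant tables share no participant_id.",
          class = "swayrisk_input_error")
  }
  report <- run_all_comparisons(data, feature_sets = feature_sets,
                                config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, "comparisons.csv")
  readr::write_csv(report$results[, c(
    "feature_set", "comparison", "positive", "tp", "fn", "tn", "fp",
    "accuracy_pct", "sensitivity_pct", "specificity_pct")], res_path)
  imp_path <- file.path(out_dir, "importance.json")
  imp_plain <- lapply(report$importance, function(im) {
    as.data.frame(im[, c("feature", "share", "rank", "top")])
  })
  jsonlite::write_json(imp_plain, imp_path, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "classify",
                 list(feature_sets = feature_sets,
                      n_trees = config$n_trees, cv_folds = config$cv_folds),
                 config$seed, c(res_path, imp_path), t0)
  invisible(report)
}
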