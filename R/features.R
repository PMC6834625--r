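#' Names of the sway metric panel
#'
#' The 19 metrics extracted per trial: sway path length (AP, ML, resultant),
#' mean sway velocity (AP, ML, resultant), 95% confidence ellipse area, sway
#' range (AP, ML), RMS amplitude (AP, ML), four spectral summaries of the
#' resultant-distance series, and sample/approximate entropy per axis.
#'
#' @return character vector of the 19 metric column names.
#' @export
sway_metric_names <- function() {
  c("path_length_ap", "path_length_ml", "path_length_rd",
    "mean_velocity_ap", "mean_velocity_ml", "mean_velocity_rd",
    "ellipse_area_95", "range_ap", "range_ml", "rms_ap", "rms_ml",
    "total_power", "centroidal_freq", "freq_dispersion", "power_freq_95",
    "sampen_ap", "sampen_ml", "apen_ap", "apen_ml")
}

#' Extract the full sway metric panel from one trial
#'
#' Computes all 19 metrics of [sway_metric_names()] from a preprocessed
#' trial. Metrics that are undefined for the input (zero-variance series,
#' zero in-band power, unmatched entropy templates) are returned as `NA`
#' and listed in the `undefined_metrics` column; a failing metric never
#' aborts extraction of the rest.
#'
#' @param trial a `cop_trial` from [preprocess_cop()].
#' @param eparams an [entropy_params()] (defaults m = 3, r = 0.2 * SD).
#' @param sparams a [spectral_params()]; spectral metrics are computed on
#'   the resultant-distance series.
#' @param entropy_fs optional target rate (Hz) at which entropies are
#'   computed via [decimate_for_entropy()]; `NULL` (default) uses the full
#'   series. When set it is recorded in `undefined_metrics`' sibling
#'   provenance and must be at least twice the low-pass cutoff.
#' @return one-row tibble: `participant_id`, the 19 metrics, and
#'   `undefined_metrics` (semicolon-separated names of `NA` metrics, `""`
#'   when all are defined).
#' @export
extract_features <- function(trial, eparams = entropy_params(),
                             sparams = spectral_params(), entropy_fs = NULL) {
  stopifnot(inherits(trial, "cop_trial"))
  dur <- trial_duration(trial)
  fs <- sampling_rate(trial)

  safe <- function(expr) {
    tryCatch(expr, error = function(e) NA_real_)
  }

  pl_ap <- safe(path_length(trial$ap))
  pl_ml <- safe(path_length(trial$ml))
  pl_rd <- safe(path_length_rd(trial$ap, trial$ml))

  spec <- safe(spectral_features(trial$rd, fs, sparams))
  if (!is.data.frame(spec)) {
    spec <- tibble(total_power = NA_real_, centroidal_freq = NA_real_,
                   freq_dispersion = NA_real_, power_freq_95 = NA_real_)
  }

  etrial <- trial
  if (!is.null(entropy_fs)) {
    etrial <- decimate_for_entropy(trial, entropy_fs)
  }

  out <- tibble(
    participant_id = participant_id(trial),
    path_length_ap = pl_ap,
    path_length_ml = pl_ml,
    path_length_rd = pl_rd,
    mean_velocity_ap = safe(mean_velocity(pl_ap, dur)),
    mean_velocity_ml = safe(mean_velocity(pl_ml, dur)),
    mean_velocity_rd = safe(mean_velocity(pl_rd, dur)),
    ellipse_area_95 = safe(ellipse_area_95(trial$ap, trial$ml)),
    range_ap = safe(sway_range(trial$ap)),
    range_ml = safe(sway_range(trial$ml)),
    rms_ap = safe(rms_amplitude(trial$ap)),
    rms_ml = safe(rms_amplitude(trial$ml)),
    total_power = spec$total_power,
    centroidal_freq = spec$centroidal_freq,
    freq_dispersion = spec$freq_dispersion,
    power_freq_95 = spec$power_freq_95,
    sampen_ap = safe(sample_entropy(etrial$ap, eparams)),
    sampen_ml = safe(sample_entropy(etrial$ml, eparams)),
    apen_ap = safe(approximate_entropy(etrial$ap, eparams)),
    apen_ml = safe(approximate_entropy(etrial$ml, eparams))
  )
  metrics <- sway_metric_names()
  undef <- metrics[vapply(out[metrics], function(v) is.na(v[1]), logical(1))]
  out$undefined_metrics <- paste(undef, collapse = ";")
  out
}

#' Extract sway features for a list of recordings
#'
#' Preprocesses and extracts the metric panel for every recording, returning
#' a tidy feature table (one row per trial). This is the batch surface the
#' classification stage consumes.
#'
#' @param recordings list of `cop_recording` objects (e.g. from
#'   [generate_cohort()] or repeated [read_cop_file()] calls).
#' @param cutoff_hz,order low-pass settings passed to [preprocess_cop()].
#' @param eparams,sparams,entropy_fs passed to [extract_features()].
#' @return tibble with `participant_id`, 19 metric columns and
#'   `undefined_metrics`.
#' @export
extract_cohort_features <- function(recordings, cutoff_hz = 10, order = 4,
                                    eparams = entropy_params(),
                                    sparams = spectral_params(),
                                    entropy_fs = 100) {
  purrr::map_dfr(recordings, function(rec) {
    trial <- preprocess_cop(rec, cutoff_hz = cutoff_hz, order = order)
    efs <- entropy_fs
    if (!is.null(efs) && efs >= sampling_rate(trial)) efs <- NULL
    extract_features(trial, eparams = eparams, sparams = sparams,
                     entropy_fs = efs)
  })
}
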