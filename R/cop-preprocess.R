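# Zero-phase Butterworth low-pass with reflective edge padding.
# signal::butter supplies the coefficients; the forward-backward pass and the
# reflective pad (3 x order samples each end) are applied here so edge
# handling is explicit.
butter_zerophase <- function(x, fs, cutoff_hz, order) {
  w <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, w, type = "low")
  pad <- 3L * order
  n <- length(x)
  if (n <= pad + 1L) {
    abort(paste0("Signal too short to filter: need more than ", pad + 1L,
                 " samples for a ", order, "-order filter."),
          class = "swayrisk_input_error")
  }
  # reflect about the end points (odd extension keeps the signal continuous)
  head_pad <- 2 * x[1] - x[seq(pad + 1L, 2L, by = -1L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  xe <- c(head_pad, x, tail_pad)
  # subtract the edge value around each pass so the filter's zero initial
  # state is exact for the signal's local DC level (a constant input then
  # passes through unchanged)
  one_pass <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(bf, v - v0)) + v0
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Preprocess a raw COP recording into an analysis-ready trial
#'
#' Applies a 4th-order Butterworth low-pass at 10 Hz (the standard static
#' posturography setting) in a zero-phase, forward-backward manner, then
#' mean-centres each axis over the trial and computes the resultant distance
#' series `rd = sqrt(ap^2 + ml^2)` from the centred axes. Forward-backward
#' application doubles the effective attenuation order of the stated filter
#' but introduces no phase distortion, which matters for time-domain sway
#' metrics.
#'
#' @param recording a `cop_recording` from [read_cop_file()] or
#'   [new_cop_recording()].
#' @param cutoff_hz low-pass cutoff in Hz (default 10); must be below the
#'   Nyquist frequency.
#' @param order Butterworth order (default 4).
#' @return a `cop_trial`: tibble with columns `ap`, `ml`, `rd` (cm) and
#'   attributes `sampling_rate`, `duration` (s), `participant_id`.
#' @export
#' @examples
#' rec <- new_cop_recording(ap = sin(seq(0, 2 * pi, length.out = 200)),
#'                          ml = cos(seq(0, 2 * pi, length.out = 200)),
#'                          sampling_rate = 100)
#' trial <- preprocess_cop(rec)
#' colMeans(trial[, c("ap", "ml")])  # ~0 after centring
preprocess_cop <- function(recording, cutoff_hz = 10, order = 4) {
  stopifnot(inherits(recording, "cop_recording"))
  fs <- sampling_rate(recording)
  if (cutoff_hz >= fs / 2) {
    abort(paste0("Cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
                 fs / 2, " Hz)."), class = "swayrisk_parameter_error")
  }
  ap <- butter_zerophase(recording$ap, fs, cutoff_hz, order)
  ml <- butter_zerophase(recording$ml, fs, cutoff_hz, order)
  ap <- ap - mean(ap)
  ml <- ml - mean(ml)
  out <- tibble(ap = ap, ml = ml, rd = sqrt(ap^2 + ml^2))
  attr(out, "sampling_rate") <- fs
  attr(out, "duration") <- length(ap) / fs
  attr(out, "participant_id") <- participant_id(recording)
  class(out) <- c("cop_trial", class(out))
  prov_add(out, c(provenance(recording),
                  paste0("preprocess: Butterworth order ", order,
                         " low-pass ", cutoff_hz,
                         " Hz, zero-phase, mean-centred")))
}

#' @export
print.cop_trial <- function(x, ...) {
  cat("<cop_trial> ", attr(x, "participant_id"), ": ", nrow(x),
      " samples @ ", attr(x, "sampling_rate"), " Hz (",
      attr(x, "duration"), " s)\n", sep = "")
  NextMethod()
}

#' Trial duration in seconds
#' @param x a `cop_trial`.
#' @return duration in seconds.
#' @export
trial_duration <- function(x) attr(x, "duration")

#' Decimate a trial for entropy computation
#'
#' Template-matching entropies are quadratic in series length, so 30 s
#' recordings at 1000 Hz are expensive; decimating to e.g. 100 Hz preserves
#' all content below the 10 Hz low-pass cutoff while cutting the cost 100x.
#' The trial must already be low-pass filtered with `target_hz >= 2 * cutoff`
#' so plain subsampling does not alias. Duration is preserved.
#'
#' @param trial a `cop_trial`.
#' @param target_hz target sampling rate (Hz); must divide into the trial's
#'   rate (to within rounding) and not exceed it.
#' @return a `cop_trial` at `target_hz`.
#' @export
decimate_for_entropy <- function(trial, target_hz) {
  stopifnot(inherits(trial, "cop_trial"))
  fs <- sampling_rate(trial)
  if (target_hz > fs) {
    abort(paste0("target_hz (", target_hz, ") exceeds the sampling rate (",
                 fs, ")."), class = "swayrisk_parameter_error")
  }
  if (target_hz == fs) return(trial)
  step <- fs / target_hz
  if (abs(step - round(step)) > 1e-8) {
    abort("target_hz must divide the sampling rate.",
          class = "swayrisk_parameter_error")
  }
  idx <- seq(1L, nrow(trial), by = as.integer(round(step)))
  out <- trial[idx, ]
  attr(out, "sampling_rate") <- target_hz
  attr(out, "duration") <- trial_duration(trial)
  attr(out, "participant_id") <- participant_id(trial)
  class(out) <- class(trial)
  prov_add(out, c(provenance(trial),
                  paste0("decimated ", fs, " -> ", target_hz, " Hz for entropy")))
}
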