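#' Entropy parameters for regularity statistics
#'
#' Template length `m` and tolerance coefficient `r_coeff` for sample and
#' approximate entropy. The tolerance actually used is
#' `r = r_coeff * sd(x)`, the standard reading of "r = 0.2", so both
#' statistics are invariant to affine rescaling of the series. Defaults
#' `m = 3`, `r_coeff = 0.2` follow common posturography practice.
#'
#' @param m template length, integer >= 1.
#' @param r_coeff tolerance as a fraction of the series SD, > 0.
#' @return a list of class `entropy_params`.
#' @export
entropy_params <- function(m = 3, r_coeff = 0.2) {
  if (m < 1 || m != round(m)) {
    abort("`m` must be a positive integer.", class = "swayrisk_parameter_error")
  }
  if (!is.finite(r_coeff) || r_coeff <= 0) {
    abort("`r_coeff` must be positive.", class = "swayrisk_parameter_error")
  }
  structure(list(m = as.integer(m), r_coeff = r_coeff),
            class = "entropy_params")
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts pairs of distinct m-length
#' templates within Chebyshev distance `r` of each other and `A` counts the
#' same pairs still matching when extended to length m+1. Self-matches are
#' excluded. Lower values indicate a more regular (more predictable) series.
#'
#' @param x numeric vector, length > m + 1.
#' @param params an [entropy_params()]; tolerance is
#'   `r = r_coeff * sd(x)`.
#' @return sample entropy (unitless, >= 0), or `NA` when undefined: zero
#'   series SD, or no template matches at length m or m+1 (never `Inf`).
#' @export
#' @examples
#' sample_entropy(seq_len(100))              # perfectly regular ramp: 0
#' sample_entropy(rnorm(200), entropy_params(m = 2))
sample_entropy <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  m <- params$m
  if (length(x) <= m + 1) {
    abort(paste0("sample_entropy needs more than m + 1 = ", m + 1, " samples."),
          class = "swayrisk_input_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  counts <- .sampen_counts(as.numeric(x), m, params$r_coeff * s)
  if (counts$B == 0 || counts$A == 0) return(NA_real_)
  -log(counts$A / counts$B)
}

#' Approximate entropy of a time series
#'
#' `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)` with
#' `Phi_m = mean(log(C_i^m))`, where `C_i^m` is the fraction of m-length
#' templates (self-match included) within Chebyshev distance `r` of template
#' `i`. Self-matches make ApEn defined for any series, at the cost of a
#' regularity bias relative to [sample_entropy()].
#'
#' @inheritParams sample_entropy
#' @return approximate entropy (unitless). A zero-SD series returns 0 (all
#'   templates match themselves) — flagged as degenerate by callers.
#' @export
approximate_entropy <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  m <- params$m
  if (length(x) <= m + 1) {
    abort(paste0("approximate_entropy needs more than m + 1 = ", m + 1,
                 " samples."), class = "swayrisk_input_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  .apen_cpp(as.numeric(x), m, params$r_coeff * s)
}
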