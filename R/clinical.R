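#' Convert FES-I fall-efficacy score to a confidence percentage
#'
#' The Falls Efficacy Scale - International totals 16-64, with lower scores
#' meaning higher perceived self-efficacy at avoiding a fall. To put it on
#' the same footing as the ABC scale (0-100, higher = more confident) it is
#' rescaled as `FES_p = 100 * |FES - 64| / (64 - 16)`, an affine, strictly
#' decreasing map of \[16, 64\] onto \[100, 0\].
#'
#' @param fes_i numeric vector of FES-I total scores in \[16, 64\]; `NA`
#'   passes through.
#' @return confidence percentage in [0, 100].
#' @export
#' @examples
#' fes_to_percentage(c(16, 40, 64))  # 100, 50, 0
fes_to_percentage <- function(fes_i) {
  bad <- !is.na(fes_i) & (fes_i < 16 | fes_i > 64)
  if (any(bad)) {
    abort(paste0("FES-I scores must lie in [16, 64]; got ",
                 paste(fes_i[bad], collapse = ", ")),
          class = "swayrisk_validation_error")
  }
  100 * abs(fes_i - 64) / (64 - 16)
}

#' Self-reported balance confidence from ABC and/or FES
#'
#' Balance confidence (0-100) is the average of the ABC score and the
#' FES-derived percentage [fes_to_percentage()]; when only one instrument
#' was administered, that one is used.
#'
#' @param abc numeric vector, ABC scores in [0, 100] or `NA`.
#' @param fes_p numeric vector, FES-derived percentages in [0, 100] or `NA`.
#' @return numeric vector of balance confidence values.
#' @export
#' @examples
#' balance_confidence(80, 60)   # 70
#' balance_confidence(80, NA)   # 80
balance_confidence <- function(abc, fes_p) {
  n <- max(length(abc), length(fes_p))
  abc <- rep_len(abc, n)
  fes_p <- rep_len(fes_p, n)
  if (any(is.na(abc) & is.na(fes_p))) {
    abort("balance_confidence needs at least one of `abc`, `fes_p` per record.",
          class = "swayrisk_validation_error")
  }
  rowMeans(cbind(abc, fes_p), na.rm = TRUE)
}

risk_group_levels <- function() c("HC", "MS_Low", "MS_Mod", "MS_High")

#' Assign a physiological fall-risk group from the PPA index
#'
#' MS participants are binned by the Physiological Profile Assessment
#' composite: `< 1` low risk, `1-2` moderate risk (both boundaries
#' inclusive by default), `> 2` high risk. Healthy controls are `HC`
#' regardless of PPA.
#'
#' @param ppa numeric vector of PPA composite scores (z-score-based); must
#'   be finite.
#' @param is_ms logical vector: `TRUE` for MS participants.
#' @param boundaries two cut points (default `c(1, 2)`), both assigned to
#'   the moderate bin.
#' @return factor with levels `HC`, `MS_Low`, `MS_Mod`, `MS_High`.
#' @export
#' @examples
#' assign_risk_group(c(0.28, 1.0, 3.01, -0.1), c(TRUE, TRUE, TRUE, FALSE))
assign_risk_group <- function(ppa, is_ms, boundaries = c(1, 2)) {
  n <- max(length(ppa), length(is_ms))
  ppa <- rep_len(ppa, n)
  is_ms <- rep_len(as.logical(is_ms), n)
  if (any(!is.finite(ppa))) {
    abort("PPA scores must be finite.", class = "swayrisk_validation_error")
  }
  out <- ifelse(!is_ms, "HC",
         ifelse(ppa < boundaries[1], "MS_Low",
         ifelse(ppa <= boundaries[2], "MS_Mod", "MS_High")))
  factor(out, levels = risk_group_levels())
}

#' Prepare a participant table for classification
#'
#' Takes a raw participant table (columns `participant_id`, `is_ms`, `ppa`,
#' `bbs`, and `abc` and/or `fes_i`, missing values as `NA`) and derives
#' `fes_p`, `balance_confidence` and `risk_group`. Records which
#' instrument(s) fed the confidence score in `confidence_source`.
#'
#' @param participants data frame with the columns above.
#' @param boundaries PPA bin cut points, see [assign_risk_group()].
#' @return tibble with the input columns plus `fes_p`,
#'   `balance_confidence`, `confidence_source` and `risk_group`.
#' @export
prepare_participants <- function(participants, boundaries = c(1, 2)) {
  req <- c("participant_id", "is_ms", "ppa", "bbs")
  miss <- setdiff(req, names(participants))
  if (length(miss)) {
    abort(paste0("Participant table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "swayrisk_format_error")
  }
  p <- as_tibble(participants)
  if (is.null(p$abc)) p$abc <- NA_real_
  if (is.null(p$fes_i)) p$fes_i <- NA_real_
  bad_bbs <- !is.na(p$bbs) & (p$bbs < 0 | p$bbs > 56)
  if (any(bad_bbs)) {
    abort("BBS scores must lie in [0, 56].", class = "swayrisk_validation_error")
  }
  p$fes_p <- fes_to_percentage(p$fes_i)
  p$balance_confidence <- balance_confidence(p$abc, p$fes_p)
  p$confidence_source <- dplyr::case_when(
    !is.na(p$abc) & !is.na(p$fes_p) ~ "abc+fes",
    !is.na(p$abc) ~ "abc",
    TRUE ~ "fes"
  )
  p$risk_group <- assign_risk_group(p$ppa, p$is_ms, boundaries)
  p
}
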