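#' Ingest configuration for force-plate exports
#'
#' Describes how a delimited force-plate export maps onto the two COP axes.
#' Columns can be identified by header name or 1-based index. The canonical
#' internal unit is centimetres; `unit` declares the unit of the source file
#' and values are converted on read.
#'
#' @param ap_col,ml_col column name (character) or 1-based index (numeric) of
#'   the anterior-posterior and mediolateral COP displacement columns.
#' @param sampling_rate sampling frequency of the recording in Hz.
#' @param unit unit of the displacement columns: `"cm"`, `"mm"` or `"m"`.
#' @param delim field delimiter; `","` (default) or e.g. `"\t"`.
#' @return a list of class `cop_ingest_config`.
#' @export
#' @examples
#' ingest_config(sampling_rate = 1000)
#' ingest_config(ap_col = "COPy", ml_col = "COPx", sampling_rate = 100, unit = "mm")
ingest_config <- function(ap_col = "ap", ml_col = "ml", sampling_rate = 1000,
                          unit = c("cm", "mm", "m"), delim = ",") {
  unit <- match.arg(unit)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).",
          class = "swayrisk_parameter_error")
  }
  structure(
    list(ap_col = ap_col, ml_col = ml_col, sampling_rate = sampling_rate,
         unit = unit, delim = delim),
    class = "cop_ingest_config"
  )
}

unit_to_cm <- function(unit) {
  switch(unit, cm = 1, mm = 0.1, m = 100)
}

# Resolve a column spec (name or index) against a header; NULL if absent.
resolve_col <- function(spec, header) {
  if (is.numeric(spec)) {
    if (spec >= 1 && spec <= length(header)) return(as.integer(spec))
    return(NULL)
  }
  i <- match(spec, header)
  if (is.na(i)) NULL else i
}

#' Read a raw COP recording from a delimited text file
#'
#' Reads a force-plate export (CSV/TSV) and returns a raw two-axis COP
#' recording in centimetres. Rows with non-numeric or non-finite entries in
#' either axis column are an error (the offending data line is named), so a
#' returned recording never contains non-finite values.
#'
#' @param path path to the delimited text file. A header row is required.
#' @param config a [ingest_config()] declaring column mapping, unit and
#'   sampling rate.
#' @param participant_id identifier stored with the recording; defaults to
#'   the file name without extension.
#' @return a `cop_recording`: a tibble with columns `ap` and `ml` (cm) and
#'   attributes `sampling_rate` and `participant_id`.
#' @export
read_cop_file <- function(path, config = ingest_config(), participant_id = NULL) {
  stopifnot(inherits(config, "cop_ingest_config"))
  if (!file.exists(path)) {
    abort(paste0("COP file not found: ", path), class = "swayrisk_input_error")
  }
  raw <- readr::read_delim(path, delim = config$delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE, trim_ws = TRUE)
  header <- names(raw)
  i_ap <- resolve_col(config$ap_col, header)
  i_ml <- resolve_col(config$ml_col, header)
  if (is.null(i_ap) || is.null(i_ml)) {
    missing <- c(if (is.null(i_ap)) config$ap_col, if (is.null(i_ml)) config$ml_col)
    abort(paste0("COP file ", path, " is missing expected column(s): ",
                 paste(missing, collapse = ", "),
                 " (found: ", paste(header, collapse = ", "), ")"),
          class = "swayrisk_format_error")
  }
  if (nrow(raw) < 2) {
    abort(paste0("COP file ", path, " has fewer than 2 samples."),
          class = "swayrisk_input_error")
  }
  parse_axis <- function(chr, colname) {
    val <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.finite(val))
    if (length(bad) > 0) {
      # +1 for the header row, so this is the physical line in the file
      abort(paste0("Non-numeric or non-finite value '", chr[bad[1]],
                   "' in column '", colname, "' of ", path,
                   " at line ", bad[1] + 1L, "."),
            class = "swayrisk_parse_error")
    }
    val
  }
  scale <- unit_to_cm(config$unit)
  ap <- parse_axis(raw[[i_ap]], header[i_ap]) * scale
  ml <- parse_axis(raw[[i_ml]], header[i_ml]) * scale
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_cop_recording(ap, ml, config$sampling_rate, participant_id,
                    provenance = paste0(
                      "read ", path, ": ", length(ap), " samples, AP<-'",
                      header[i_ap], "', ML<-'", header[i_ml], "', unit=",
                      config$unit, ", fs=", config$sampling_rate, " Hz"))
}

#' Construct a raw COP recording from vectors
#'
#' @param ap,ml numeric vectors (cm) of equal length >= 2, finite.
#' @param sampling_rate sampling frequency (Hz).
#' @param participant_id identifier.
#' @param provenance optional log line(s).
#' @return a `cop_recording` tibble with columns `ap`, `ml`.
#' @export
new_cop_recording <- function(ap, ml, sampling_rate, participant_id = "unknown",
                              provenance = NULL) {
  if (length(ap) != length(ml)) {
    abort("`ap` and `ml` must have equal length.", class = "swayrisk_input_error")
  }
  if (length(ap) < 2) {
    abort("A COP recording needs at least 2 samples.", class = "swayrisk_input_error")
  }
  if (!all(is.finite(ap)) || !all(is.finite(ml))) {
    abort("COP recording contains non-finite values.", class = "swayrisk_input_error")
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.", class = "swayrisk_parameter_error")
  }
  out <- tibble(ap = as.numeric(ap), ml = as.numeric(ml))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "participant_id") <- participant_id
  class(out) <- c("cop_recording", class(out))
  if (!is.null(provenance)) out <- prov_add(out, provenance)
  out
}

#' @export
print.cop_recording <- function(x, ...) {
  cat("<cop_recording> ", attr(x, "participant_id"), ": ", nrow(x),
      " samples @ ", attr(x, "sampling_rate"), " Hz\n", sep = "")
  NextMethod()
}

#' Sampling rate of a recording or trial
#' @param x a `cop_recording` or `cop_trial`.
#' @return sampling frequency in Hz.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' Participant identifier of a recording or trial
#' @param x a `cop_recording` or `cop_trial`.
#' @return the stored identifier (character).
#' @export
participant_id <- function(x) attr(x, "participant_id")
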