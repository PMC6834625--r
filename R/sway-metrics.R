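#' Sway path length
#'
#' Total excursion of the COP along one axis: the sum of absolute successive
#' displacements `sum(|x[i+1] - x[i]|)` (cm). Translation-invariant.
#'
#' @param x numeric vector of at least 2 samples (cm).
#' @return path length in cm.
#' @export
#' @examples
#' path_length(c(0, 1, 0, 1))  # 3
path_length <- function(x) {
  if (length(x) < 2) {
    abort("path_length needs at least 2 samples.", class = "swayrisk_input_error")
  }
  sum(abs(diff(x)))
}

#' Resultant (planar) sway path length
#'
#' Total planar excursion: `sum(sqrt(diff(ap)^2 + diff(ml)^2))` (cm).
#'
#' @param ap,ml numeric vectors of equal length >= 2 (cm).
#' @return resultant path length in cm.
#' @export
#' @examples
#' path_length_rd(c(0, 3), c(0, 4))  # 5
path_length_rd <- function(ap, ml) {
  if (length(ap) != length(ml) || length(ap) < 2) {
    abort("path_length_rd needs equal-length vectors of at least 2 samples.",
          class = "swayrisk_input_error")
  }
  sum(sqrt(diff(ap)^2 + diff(ml)^2))
}

#' Mean sway velocity
#'
#' Path length divided by trial duration (cm/s).
#'
#' @param path_len path length in cm (from [path_length()] or
#'   [path_length_rd()]).
#' @param duration trial duration in seconds, > 0.
#' @return mean velocity in cm/s.
#' @export
mean_velocity <- function(path_len, duration) {
  if (!is.finite(duration) || duration <= 0) {
    abort("`duration` must be positive.", class = "swayrisk_parameter_error")
  }
  path_len / duration
}

#' Sway range
#'
#' Peak-to-peak COP excursion along one axis: `max(x) - min(x)` (cm).
#'
#' @param x numeric vector of at least 1 sample.
#' @return range in cm.
#' @export
sway_range <- function(x) {
  if (length(x) < 1) {
    abort("sway_range needs at least 1 sample.", class = "swayrisk_input_error")
  }
  max(x) - min(x)
}

#' Root-mean-square sway amplitude
#'
#' RMS displacement about the trial mean: `sqrt(mean((x - mean(x))^2))` (cm).
#'
#' @param x numeric vector of at least 1 sample.
#' @return RMS amplitude in cm.
#' @export
rms_amplitude <- function(x) {
  if (length(x) < 1) {
    abort("rms_amplitude needs at least 1 sample.", class = "swayrisk_input_error")
  }
  sqrt(mean((x - mean(x))^2))
}

#' 95% confidence ellipse sway area
#'
#' Area of the ellipse expected to contain 95% of the COP points, from the
#' bivariate sample covariance of the two axes and an F quantile:
#' `area = 2 * pi * F(0.95; 2, n - 2) * sqrt(s_ap^2 * s_ml^2 - s_apml^2)`
#' where `s` are the sample variances/covariance. For large n the F quantile
#' approaches 3.0 and the ellipse is the chi-squared(2) 95% contour.
#'
#' @param ap,ml numeric vectors (cm) of equal length n >= 3, mean-centred
#'   axes of one trial (centring does not change the area, which uses
#'   central moments).
#' @return area in cm^2. A numerically negative covariance discriminant is
#'   clamped to 0 with a warning.
#' @export
#' @examples
#' set.seed(1)
#' ellipse_area_95(rnorm(1000), rnorm(1000))  # ~ 2*pi*3 = 18.9
ellipse_area_95 <- function(ap, ml) {
  n <- length(ap)
  if (length(ml) != n || n < 3) {
    abort("ellipse_area_95 needs equal-length vectors of at least 3 samples.",
          class = "swayrisk_input_error")
  }
  s_ap <- var(ap)
  s_ml <- var(ml)
  s_apml <- var(ap, ml)
  disc <- s_ap * s_ml - s_apml^2
  if (disc < 0) {
    if (disc < -1e-12 * max(s_ap * s_ml, 1)) {
      warn("Degenerate covariance in ellipse_area_95; clamping area to 0.")
    }
    disc <- 0
  }
  2 * pi * qf(0.95, 2, n - 2) * sqrt(disc)
}

#' Spectral estimation settings for sway analysis
#'
#' @param band_low,band_high analysis band in Hz (defaults 0.15-5 Hz, the
#'   conventional static-posturography band: below 0.15 Hz the spectrum is
#'   dominated by slow drift, above 5 Hz by noise).
#' @param psd_method `"periodogram"` (default, mean removed) or `"welch"`
#'   (8 segments, 50% overlap, Hann window).
#' @return a list of class `spectral_params`.
#' @export
spectral_params <- function(band_low = 0.15, band_high = 5.0,
                            psd_method = c("periodogram", "welch")) {
  psd_method <- match.arg(psd_method)
  if (!(band_low >= 0 && band_low < band_high)) {
    abort("Need 0 <= band_low < band_high.", class = "swayrisk_parameter_error")
  }
  structure(list(band_low = band_low, band_high = band_high,
                 psd_method = psd_method),
            class = "spectral_params")
}

# One-sided periodogram PSD (density, unit^2/Hz), DC bin excluded.
psd_periodogram <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  half <- floor(n / 2)
  X <- fft(x)
  p <- (2 / (fs * n)) * Mod(X[2:(half + 1)])^2
  if (n %% 2 == 0) p[half] <- p[half] / 2  # Nyquist bin is not two-sided
  tibble(freq = (1:half) * fs / n, psd = p)
}

# Welch-averaged PSD: 8 Hann-windowed segments with 50% overlap.
psd_welch <- function(x, fs, n_segments = 8) {
  n <- length(x)
  seg_len <- floor(n / (n_segments / 2 + 0.5))
  seg_len <- max(seg_len, 16L)
  step <- floor(seg_len / 2)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- mean(w^2)
  half <- floor(seg_len / 2)
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- (2 / (fs * seg_len * u)) * Mod(X[2:(half + 1)])^2
    if (seg_len %% 2 == 0) p[half] <- p[half] / 2
    acc <- acc + p
  }
  tibble(freq = (1:half) * fs / seg_len, psd = acc / length(starts))
}

#' Frequency-domain sway features from spectral moments
#'
#' Computes the four classic spectral summaries of the sway power spectrum
#' `G(f)` over the analysis band, using the spectral moments
#' `mu_k = sum(f^k * G(f) * df)`:
#' total power `mu_0` (cm^2), centroidal frequency `sqrt(mu_2 / mu_0)` (Hz),
#' frequency dispersion `sqrt(1 - mu_1^2 / (mu_0 * mu_2))` (unitless, 0 for
#' a single spectral line, bounded by 1), and the 95% power frequency (the
#' lowest frequency below which 95% of the in-band power lies).
#'
#' @param x numeric vector, the series to analyse (conventionally the
#'   resultant-distance series), length >= 64.
#' @param fs sampling rate in Hz.
#' @param params a [spectral_params()].
#' @return one-row tibble with columns `total_power`, `centroidal_freq`,
#'   `freq_dispersion`, `power_freq_95`. If the in-band power is zero (e.g.
#'   a constant signal) total power is 0 and the three frequency summaries
#'   are `NA` (undefined).
#' @export
spectral_features <- function(x, fs, params = spectral_params()) {
  stopifnot(inherits(params, "spectral_params"))
  if (length(x) < 64) {
    abort("spectral_features needs at least 64 samples.",
          class = "swayrisk_input_error")
  }
  if (params$band_high > fs / 2) {
    abort("band_high exceeds the Nyquist frequency.",
          class = "swayrisk_parameter_error")
  }
  spec <- switch(params$psd_method,
                 periodogram = psd_periodogram(x, fs),
                 welch = psd_welch(x, fs))
  df <- spec$freq[2] - spec$freq[1]
  inband <- spec$freq >= params$band_low & spec$freq <= params$band_high
  f <- spec$freq[inband]
  g <- spec$psd[inband]
  mu0 <- sum(g) * df
  if (!length(f) || mu0 <= 0) {
    return(tibble(total_power = 0, centroidal_freq = NA_real_,
                  freq_dispersion = NA_real_, power_freq_95 = NA_real_))
  }
  mu1 <- sum(f * g) * df
  mu2 <- sum(f^2 * g) * df
  disp2 <- 1 - mu1^2 / (mu0 * mu2)
  cum <- cumsum(g) * df
  tibble(
    total_power = mu0,
    centroidal_freq = sqrt(mu2 / mu0),
    freq_dispersion = sqrt(min(max(disp2, 0), 1)),
    power_freq_95 = f[which(cum >= 0.95 * mu0)[1]]
  )
}
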