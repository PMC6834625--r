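test_that("path length, velocity, range and rms match direct formulas", {
  expect_equal(path_length(c(0, 1, 0, 1)), 3)
  expect_equal(path_length_rd(c(0, 3), c(0, 4)), 5)
  expect_equal(mean_velocity(3, 30), 0.1)
  expect_equal(sway_range(c(-1, 1)), 2)
  expect_equal(rms_amplitude(c(-1, 1)), 1)
  expect_equal(sway_range(rep(4, 10)), 0)
  expect_equal(rms_amplitude(rep(4, 10)), 0)
  # many-cycle unit sinusoid: rms -> 1/sqrt(2)
  s <- sin(2 * pi * seq(0, 50, by = 0.001))
  expect_equal(rms_amplitude(s), 1 / sqrt(2), tolerance = 1e-3)
})

test_that("resultant path length equals the brute-force increment sum", {
  set.seed(3)
  ap <- cumsum(rnorm(100))
  ml <- cumsum(rnorm(100))
  expect_equal(path_length_rd(ap, ml), oracle_path_rd(ap, ml),
               tolerance = 1e-12)
  expect_equal(path_length(ap), sum(abs(diff(ap))), tolerance = 1e-12)
})

test_that("path metrics are translation-invariant; velocity scales with duration", {
  set.seed(4)
  x <- rnorm(50)
  expect_equal(path_length(x + 100), path_length(x))
  expect_equal(mean_velocity(path_length(x), 60),
               mean_velocity(path_length(x), 30) / 2)
  expect_error(path_length(1), class = "swayrisk_input_error")
  expect_error(mean_velocity(1, 0), class = "swayrisk_parameter_error")
})

test_that("ellipse area: degenerate, homogeneity and large-n normal value", {
  expect_equal(ellipse_area_95(rep(1, 10), rep(2, 10)), 0)
  set.seed(6)
  ap <- rnorm(2000); ml <- rnorm(2000)
  a1 <- ellipse_area_95(ap, ml)
  expect_equal(ellipse_area_95(3 * ap, 3 * ml), 9 * a1, tolerance = 1e-9)
  # large-n independent standard normal: area -> 2*pi*F(0.95;2,Inf) ~ 18.8
  set.seed(7)
  big <- ellipse_area_95(rnorm(2e4), rnorm(2e4))
  expect_equal(big, 2 * pi * qf(0.95, 2, 2e4 - 2), tolerance = 0.05)
})

test_that("95% ellipse contains about 95% of bivariate normal points", {
  set.seed(8)
  n <- 10000
  cover <- replicate(20, {
    ap <- rnorm(n, sd = 1.3)
    ml <- 0.4 * ap + rnorm(n, sd = 0.7)
    ap <- ap - mean(ap); ml <- ml - mean(ml)
    S <- cov(cbind(ap, ml))
    d2 <- mahalanobis(cbind(ap, ml), c(0, 0), S)
    mean(d2 <= 2 * qf(0.95, 2, n - 2))
  })
  # and the area formula agrees with pi * c * sqrt(det S) for that contour
  expect_true(all(abs(cover - 0.95) < 0.01))
  set.seed(9)
  ap <- rnorm(5000); ml <- rnorm(5000, sd = 2)
  S <- cov(cbind(ap, ml))
  expect_equal(ellipse_area_95(ap, ml),
               pi * 2 * qf(0.95, 2, 4998) * sqrt(det(S)), tolerance = 1e-9)
})

test_that("spectral features recover single- and two-line spectra", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)  # bin width 0.05 Hz, 1 Hz on-bin
  s <- spectral_features(sin(2 * pi * 1 * t), fs)
  bin <- 1 / 20
  expect_lt(abs(s$centroidal_freq - 1), bin)
  expect_lt(s$freq_dispersion, 0.05)
  expect_lt(abs(s$power_freq_95 - 1), bin)
  # equal-power lines at 1 and 3 Hz: centroid sqrt((1+9)/2)
  s2 <- spectral_features(sin(2 * pi * t) + sin(2 * pi * 3 * t), fs)
  expect_equal(s2$centroidal_freq, sqrt(5), tolerance = 0.01)
  expect_equal(s2$total_power, 1, tolerance = 0.02)  # 2 * (1/2 each) in cm^2
  # 95% of power is below the upper line
  expect_lt(abs(s2$power_freq_95 - 3), bin + 1e-9)
})

test_that("constant signals flag the spectral ratios undefined", {
  s <- spectral_features(rep(2, 1000), 100)
  expect_equal(s$total_power, 0)
  expect_true(is.na(s$centroidal_freq))
  expect_true(is.na(s$freq_dispersion))
  expect_true(is.na(s$power_freq_95))
})

test_that("frequency dispersion stays in [0, 1] on random signals", {
  set.seed(10)
  for (k in 1:20) {
    x <- rnorm(512)
    s <- spectral_features(x, 100)
    expect_gte(s$freq_dispersion, 0)
    expect_lte(s$freq_dispersion, 1)
  }
  # welch estimator also valid
  s <- spectral_features(rnorm(2048), 100,
                         spectral_params(psd_method = "welch"))
  expect_true(s$total_power > 0 && s$freq_dispersion <= 1)
})

test_that("extract_features populates all metrics and flags degenerates", {
  set.seed(12)
  trial <- preprocess_cop(new_cop_recording(rnorm(3000), rnorm(3000), 100))
  fv <- extract_features(trial, entropy_params(m = 2))
  expect_setequal(setdiff(names(fv), c("participant_id", "undefined_metrics")),
                  sway_metric_names())
  expect_true(all(is.finite(unlist(fv[sway_metric_names()]))))
  expect_identical(fv$undefined_metrics, "")
  expect_equal(fv$mean_velocity_ap * trial_duration(trial),
               fv$path_length_ap, tolerance = 1e-9)

  # identical input -> identical output
  expect_identical(fv, extract_features(trial, entropy_params(m = 2)))

  # constant trial: amplitude metrics 0, ratios/entropies flagged
  const <- preprocess_cop(new_cop_recording(rep(1, 500), rep(1, 500), 100))
  fc <- extract_features(const)
  expect_equal(fc$path_length_ap, 0)
  expect_equal(fc$range_ml, 0)
  expect_equal(fc$ellipse_area_95, 0)
  expect_true(is.na(fc$centroidal_freq))
  expect_true(is.na(fc$sampen_ap))
  flagged <- strsplit(fc$undefined_metrics, ";")[[1]]
  expect_true(all(c("centroidal_freq", "sampen_ap", "sampen_ml") %in% flagged))
})

test_that("time-domain metrics are invariant under time reversal", {
  set.seed(13)
  trial <- preprocess_cop(new_cop_recording(rnorm(2000), rnorm(2000), 100))
  for (f in list(path_length, sway_range, rms_amplitude)) {
    expect_equal(f(trial$ap), f(rev(trial$ap)), tolerance = 1e-12)
  }
  expect_equal(ellipse_area_95(trial$ap, trial$ml),
               ellipse_area_95(rev(trial$ap), rev(trial$ml)), tolerance = 1e-12)
})
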