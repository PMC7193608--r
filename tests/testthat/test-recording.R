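sine_epoch <- function(amps_mV, frequency_hz = 1000, fs_hz = 20000,
                       duration_s = 3, noise_sd = 0, seed = 1,
                       intensity_mA = 1, dc = 0) {
  n <- fs_hz * duration_s
  s <- sin(2 * pi * frequency_hz * seq_len(n) / fs_hz)
  data <- outer(amps_mV, s) + dc
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + matrix(rnorm(length(data), sd = noise_sd), nrow(data))
  }
  recording_epoch(data, fs_hz, intensity_mA, frequency_hz)
}

test_that("bandpass preserves in-band sines, removes DC and rejects bad bands", {
  ep <- sine_epoch(2, noise_sd = 0.5)
  filt <- bandpass(ep, 900, 1100)
  mid <- 20000:40000
  # amplitude via projection onto the stimulus phase (noise-unbiased)
  ph <- 2 * pi * 1000 * mid / 20000
  amp <- 2 * mean(filt$data[1, mid] * sin(ph))
  expect_lt(abs(amp - 2) / 2, 0.01)
  # noise power drops, signal survives: output closer to the clean sine
  clean <- sine_epoch(2)$data[1, mid]
  expect_lt(sd(filt$data[1, mid] - clean), 0.5 * sd(ep$data[1, mid] - clean))

  pure <- bandpass(sine_epoch(2), 900, 1100)
  amp_pure <- (max(pure$data[1, mid]) - min(pure$data[1, mid])) / 2
  expect_lt(abs(amp_pure - 2) / 2, 0.005)

  dc <- bandpass(sine_epoch(1, dc = 5), 20, 2000)
  expect_lt(abs(mean(dc$data[1, mid])), 0.01)

  expect_error(bandpass(ep, 500, 11000), "Nyquist")
  expect_error(bandpass(ep, 0, 100), "Nyquist")
})

test_that("cycle averaging folds exact cycles and suppresses noise ~ 1/N", {
  ep <- sine_epoch(1, frequency_hz = 100)
  tmpl <- cycle_average(ep)
  expect_equal(ncol(tmpl), 200)
  one_cycle <- ep$data[1, 1:200]
  expect_equal(as.numeric(tmpl[1, ]), one_cycle, tolerance = 1e-10)

  # noise variance reduced by about the number of cycles (300 here)
  set.seed(5)
  noise <- matrix(rnorm(60000), 1)
  epn <- recording_epoch(noise, 20000, 1, 100)
  tn <- cycle_average(epn)
  ratio <- var(as.numeric(tn)) / var(as.numeric(noise))
  expect_lt(ratio, 2 / 300)
  expect_gt(ratio, 0.3 / 300)

  # cycle length not dividing the sample count: partial cycle dropped
  n2 <- 59060                                 # 295 cycles + 60 samples
  s2 <- sin(2 * pi * 100 * seq_len(n2) / 20000)
  ep2 <- recording_epoch(matrix(s2, 1), 20000, 1, 100)
  tmpl2 <- cycle_average(ep2)
  expect_equal(ncol(tmpl2), 200)
  # template phase matches the first cycle exactly (no drift accumulated)
  expect_equal(as.numeric(tmpl2), s2[1:200], tolerance = 1e-10)

  expect_error(cycle_average(sine_epoch(1, frequency_hz = 1,
                                        duration_s = 3)), ">= 10")
})

test_that("peak-to-peak amplitudes follow max - min per channel", {
  t <- seq(0, 1, length.out = 1000)
  expect_equal(unname(peak_to_peak(2 * sin(2 * pi * 5 * t))), 4,
               tolerance = 1e-4)
  expect_equal(unname(peak_to_peak(rep(3, 100))), 0)
  expect_equal(unname(peak_to_peak(c(rep(0, 10), 1, rep(0, 10), -1))), 2)
  expect_error(peak_to_peak(numeric(0)), "empty")
})

test_that("strip gradients divide adjacent differences by the spacing", {
  fm <- strip_gradient(c(10, 5, 0), spacing_mm = 5)
  expect_equal(fm$pair_fields_mV_mm, c(1, 1))
  expect_equal(fm$summary_mV_mm, 1)
  expect_equal(strip_gradient(rep(7, 8))$summary_mV_mm, 0)
  expect_error(strip_gradient(5), "2 channels")
  expect_error(strip_gradient(c(1, 2), spacing_mm = 0), "positive")
})

test_that("the full chain recovers solver strip fields end to end", {
  m <- beagle_shells()
  strip <- strip_on_inner_surface(m, 8)
  sol <- solve_potential(m, shell_pair(m, "skull-surface"))
  truth <- strip_pair_fields(field_along_strip(sol, strip))
  ep <- make_strip_recording(truth, frequency_hz = 1000, noise_sd_mV = 0.02,
                             seed = 9, condition = "SES-closed")
  fm <- measure_epoch(ep)
  expect_lt(max(abs(fm$pair_fields_mV_mm - truth) / max(truth)), 0.03)
})

test_that("chain output scales linearly with stimulus intensity", {
  base <- c(0.8, 0.5, 0.3, 0.1, 0.05, 0.02, 0.01)
  f1 <- measure_epoch(make_strip_recording(base, intensity_mA = 1))
  f3 <- measure_epoch(make_strip_recording(3 * base, intensity_mA = 3))
  expect_equal(f3$pair_fields_mV_mm, 3 * f1$pair_fields_mV_mm,
               tolerance = 1e-6)
})

test_that("per-milliamp slopes summarize dose linearity", {
  tes <- as_field_measurements(
    strip_field_reference()[strip_field_reference()$condition == "TES", ])
  ps <- per_milliamp_slope(tes)
  expect_equal(ps$mean_ratio, mean(c(0.348, 0.687 / 2, 1.019 / 3,
                                     1.362 / 4, 1.704 / 5)))
  # origin-constrained least squares reproduces the reported 0.34 slope
  expect_equal(round(ps$slope_mV_mm_per_mA, 3), 0.341)
  expect_gt(ps$pearson_r, 0.999)

  # perfectly linear data
  lin <- as_field_measurements(data.frame(condition = "x",
                                          intensity_mA = 1:4,
                                          field_mV_mm = 2 * (1:4)))
  expect_equal(per_milliamp_slope(lin)$pearson_r, 1, tolerance = 1e-12)
  expect_equal(per_milliamp_slope(lin)$slope_mV_mm_per_mA, 2)

  med <- as_field_measurements(data.frame(condition = "x",
                                          intensity_mA = c(1, 1, 1),
                                          field_mV_mm = c(0.17, 0.20, 0.22)))
  expect_error(per_milliamp_slope(med), "distinct")
  expect_equal(median(c(0.17, 0.20, 0.22) / 1), 0.20)

  two <- as_field_measurements(data.frame(condition = "x",
                                          intensity_mA = c(1, 1, 1, 2),
                                          field_mV_mm = c(0.17, 0.20,
                                                          0.22, 0.40)))
  expect_equal(per_milliamp_slope(two)$median_ratio, 0.20)
})

test_that("shunting ratios reproduce the published worked example", {
  ref <- strip_field_reference()
  tes <- as_field_measurements(ref[ref$condition == "TES", ])
  rem <- as_field_measurements(ref[ref$condition == "SES-removed", ])
  clo <- as_field_measurements(ref[ref$condition == "SES-closed", ])

  r_rem <- shunting_ratio(rem, tes, pairing = "intensity")
  expected <- c(1.395, 2.783, 4.166, 5.534, 6.877) /
    c(0.348, 0.687, 1.019, 1.362, 1.704)
  expect_equal(r_rem$pairs$ratio, expected, tolerance = 1e-12)
  expect_equal(round(r_rem$pairs$ratio, 2), c(4.01, 4.05, 4.09, 4.06, 4.04))
  expect_equal(r_rem$mean_ratio, mean(expected))

  r_clo <- shunting_ratio(clo, tes, pairing = "intensity")
  expect_equal(round(r_clo$mean_ratio, 2), 2.89)

  ident <- shunting_ratio(tes, tes, pairing = "intensity")
  expect_true(all(ident$pairs$ratio == 1))

  # invariance to common rescaling of both conditions
  sc <- function(ms, k) lapply(ms, function(m) {
    m$summary_mV_mm <- m$summary_mV_mm * k
    m$pair_fields_mV_mm <- m$pair_fields_mV_mm * k
    m
  })
  r_sc <- shunting_ratio(sc(rem, 3.7), sc(tes, 3.7), pairing = "intensity")
  expect_equal(r_sc$mean_ratio, r_rem$mean_ratio, tolerance = 1e-12)
})

test_that("shunting ratio by frequency supports a one-way ANOVA", {
  set.seed(13)
  mk <- function(cond, f, e) as_field_measurements(
    data.frame(condition = cond, intensity_mA = 1, frequency_hz = f,
               field_mV_mm = e))
  freqs <- rep(c(20, 100, 1000), each = 4)
  ses <- mk("SES", freqs, 4 + rnorm(12, sd = 0.1))
  tes <- mk("TES", freqs, 1 + rnorm(12, sd = 0.03))
  r <- shunting_ratio(ses, tes, pairing = "frequency", anova = TRUE)
  expect_equal(nrow(r$pairs), 12)
  expect_true(is.numeric(r$anova_p) && r$anova_p >= 0 && r$anova_p <= 1)
  # oracle: same ANOVA by explicit F-statistic formula
  g <- split(r$pairs$ratio, r$pairs$key)
  k <- length(g); n <- length(r$pairs$ratio)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) -
                                                  mean(r$pairs$ratio))^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_stat <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(r$anova_p, pf(f_stat, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("required currents match the reported dose arithmetic", {
  expect_equal(required_current(0.85, 1), 1.2)
  expect_equal(required_current(0.20, 1), 5.0)
  expect_equal(required_current(1, 1), 1.0)
  expect_equal(required_current(dose_slope_reference()[["SES"]]), 1.2)
  expect_equal(required_current(dose_slope_reference()[["TES"]]), 5.0)
  expect_error(required_current(0), "> 0")
})

test_that("frequency trends report Spearman rank and percent change", {
  mk <- function(f, e) as_field_measurements(
    data.frame(condition = "x", intensity_mA = 1, frequency_hz = f,
               field_mV_mm = e))
  dec <- frequency_trend(mk(c(20, 50, 100, 500, 1000, 2000),
                            c(1.0, 0.95, 0.92, 0.88, 0.85, 0.80)))
  expect_equal(dec$spearman_r, -1)
  expect_equal(dec$percent_change, -20)

  const <- frequency_trend(mk(c(20, 100, 1000), rep(1, 3)))
  expect_equal(const$spearman_r, 0)
  expect_true(const$tied)

  # synthetic ~20% linear decline with small noise
  set.seed(17)
  f <- c(20, 50, 100, 500, 1000, 2000)
  e <- seq(1, 0.8, length.out = 6) * (1 + rnorm(6, sd = 0.01))
  tr <- frequency_trend(mk(f, e))
  expect_lt(tr$spearman_r, 0)
  expect_lt(abs(tr$percent_change - (-20)), 5)

  expect_error(frequency_trend(mk(c(20, 100), c(1, 1))), ">= 3")
})

test_that("correlation and t statistics agree with hand-computed formulas", {
  x <- c(1, 2, 4, 7); y <- c(2, 3, 9, 11)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  lin <- lapply(seq_along(x), function(i) structure(
    list(summary_mV_mm = y[i], pair_fields_mV_mm = y[i],
         intensity_mA = x[i], frequency_hz = x[i],
         condition = "x", montage_id = NA), class = "field_measurement"))
  expect_equal(per_milliamp_slope(lin)$pearson_r, r_hand, tolerance = 1e-12)

  # Spearman from explicit rank correlation
  e <- c(3.1, 2.9, 3.0, 2.5, 2.2)
  f <- c(20, 50, 100, 500, 1000)
  ms <- lapply(seq_along(f), function(i) structure(
    list(summary_mV_mm = e[i], pair_fields_mV_mm = e[i],
         intensity_mA = 1, frequency_hz = f[i],
         condition = "x", montage_id = NA), class = "field_measurement"))
  rho_hand <- cor(rank(f), rank(e))
  expect_equal(frequency_trend(ms)$spearman_r, rho_hand, tolerance = 1e-12)
})
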