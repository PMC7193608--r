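#' Strip recording epochs
#'
#' A recording epoch holds a channels-by-samples matrix of subdural strip
#' potentials (mV) under sinusoidal stimulation, with its stimulus
#' metadata. The default acquisition emulated throughout is 20 kHz
#' sampling for 3 s epochs.
#'
#' @param data numeric matrix, channels x samples, in mV.
#' @param fs_hz sampling rate (Hz).
#' @param intensity_mA stimulus intensity.
#' @param frequency_hz stimulus frequency; the sampling rate must be at
#'   least 10 times this.
#' @param condition one of `"TES"`, `"SES-removed"`, `"SES-closed"` (or a
#'   free label).
#' @param montage_id optional identifier for pooling.
#' @return A `recording_epoch` object.
#' @export
recording_epoch <- function(data, fs_hz, intensity_mA, frequency_hz,
                            condition = "TES", montage_id = NA_character_) {
  data <- as.matrix(data)
  if (ncol(data) < 1) stop("epoch has zero duration", call. = FALSE)
  if (fs_hz < 10 * frequency_hz)
    stop("sampling rate must be >= 10 x stimulus frequency", call. = FALSE)
  structure(list(data = data, fs_hz = fs_hz, intensity_mA = intensity_mA,
                 frequency_hz = frequency_hz, condition = condition,
                 montage_id = montage_id),
            class = "recording_epoch")
}

#' @export
print.recording_epoch <- function(x, ...) {
  cat(sprintf("Recording epoch: %d ch x %d samples @ %g Hz | %s, %g mA, %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$condition,
              x$intensity_mA, x$frequency_hz))
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Butterworth band selection applied forward and backward
#' (`signal::filtfilt`), so the passband is flat and phase is preserved.
#' Narrow bands (`high/low < 4`) use a single Butterworth bandpass so the
#' band center keeps unit gain. Wide bands are realized as a cascade of
#' an order-`order` high-pass at `low_hz` and low-pass at `high_hz`: a
#' single transfer-function bandpass spanning band edges that are a tiny
#' fraction of the sampling rate (e.g. 5-80 Hz at 20 kHz) is numerically
#' unstable, while the cascade stays well conditioned and leaves a
#' decade-wide interior untouched.
#'
#' @param epoch a [recording_epoch()].
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order filter order per stage (default 4).
#' @return The filtered epoch (same shape and metadata).
#' @export
bandpass <- function(epoch, low_hz, high_hz, order = 4) {
  stopifnot(inherits(epoch, "recording_epoch"))
  nyq <- epoch$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  if (high_hz / low_hz < 4) {
    bp <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
    run <- function(ch) signal::filtfilt(bp, ch)
  } else {
    hp <- signal::butter(order, low_hz / nyq, type = "high")
    lp <- signal::butter(order, high_hz / nyq, type = "low")
    run <- function(ch) signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }
  out <- t(apply(epoch$data, 1, run))
  if (!all(is.finite(out)))
    stop("band-pass filter is numerically unstable for this band/rate ",
         "combination; widen the band", call. = FALSE)
  epoch$data <- out
  epoch
}

#' Average whole stimulus cycles into a single-cycle template
#'
#' Folds the epoch at the stimulus period and averages, discarding the
#' trailing incomplete cycle. Averaging N cycles reduces additive noise
#' variance by about 1/N while leaving the locked sinusoid untouched.
#'
#' @param epoch a [recording_epoch()].
#' @param frequency_hz stimulus frequency; defaults to the epoch's.
#' @return Matrix channels x samples-per-cycle.
#' @export
cycle_average <- function(epoch, frequency_hz = epoch$frequency_hz) {
  stopifnot(inherits(epoch, "recording_epoch"))
  spc <- floor(epoch$fs_hz / frequency_hz)   # samples per cycle
  ncyc <- floor(ncol(epoch$data) / spc)
  if (ncyc < 10)
    stop("need >= 10 whole stimulus cycles, got ", ncyc, call. = FALSE)
  used <- epoch$data[, seq_len(ncyc * spc), drop = FALSE]
  out <- matrix(0, nrow(used), spc)
  for (c in seq_len(ncyc))
    out <- out + used[, ((c - 1) * spc + 1):(c * spc), drop = FALSE]
  out / ncyc
}

#' Peak-to-peak amplitude per channel
#'
#' @param template matrix channels x samples (or a vector for one
#'   channel), mV.
#' @return Numeric vector of `max - min` per channel.
#' @export
peak_to_peak <- function(template) {
  if (is.null(dim(template))) template <- matrix(template, nrow = 1)
  if (ncol(template) == 0) stop("empty template", call. = FALSE)
  apply(template, 1, function(ch) max(ch) - min(ch))
}

#' Adjacent-contact field gradients from peak-to-peak amplitudes
#'
#' The induced field between adjacent contacts is the absolute
#' peak-to-peak potential difference divided by the contact spacing.
#' The per-epoch summary value is the maximum over pairs (the pair under
#' the active electrode dominates); every pair value is retained.
#'
#' @param p2p_mV per-channel peak-to-peak amplitudes (mV).
#' @param spacing_mm contact spacing (default 5).
#' @param epoch optional [recording_epoch()] supplying metadata.
#' @return A `field_measurement`: list with `pair_fields_mV_mm`,
#'   `summary_mV_mm` (max over pairs), `p2p_mV` and epoch metadata.
#' @export
strip_gradient <- function(p2p_mV, spacing_mm = 5, epoch = NULL) {
  p2p_mV <- as.numeric(p2p_mV)
  if (length(p2p_mV) < 2)
    stop("need at least 2 channels to form a gradient", call. = FALSE)
  if (spacing_mm <= 0) stop("spacing must be positive", call. = FALSE)
  pairs <- abs(diff(p2p_mV)) / spacing_mm
  meta <- if (!is.null(epoch))
    list(intensity_mA = epoch$intensity_mA, frequency_hz = epoch$frequency_hz,
         condition = epoch$condition, montage_id = epoch$montage_id)
  else list(intensity_mA = NA_real_, frequency_hz = NA_real_,
            condition = NA_character_, montage_id = NA_character_)
  structure(c(list(pair_fields_mV_mm = pairs,
                   summary_mV_mm = max(pairs), p2p_mV = p2p_mV), meta),
            class = "field_measurement")
}

#' Full measurement chain for one epoch
#'
#' Bandpass -> cycle average -> peak-to-peak -> gradient, the processing
#' applied to each recorded strip epoch.
#'
#' @param epoch a [recording_epoch()].
#' @param band bandpass edges in Hz; default spans the stimulus
#'   frequencies used (20-2000 Hz), clipped below Nyquist.
#' @param order Butterworth order.
#' @param spacing_mm contact spacing.
#' @return A `field_measurement`.
#' @export
measure_epoch <- function(epoch, band = NULL, order = 4, spacing_mm = 5) {
  if (is.null(band)) {
    lo <- max(epoch$frequency_hz / 4, 1)
    hi <- min(epoch$frequency_hz * 4, epoch$fs_hz / 2 * 0.95)
    band <- c(lo, hi)
  }
  filtered <- bandpass(epoch, band[1], band[2], order = order)
  tmpl <- cycle_average(filtered)
  strip_gradient(peak_to_peak(tmpl), spacing_mm = spacing_mm, epoch = epoch)
}

#' Per-milliamp field slope over a set of intensities
#'
#' Summarizes dose linearity: per-epoch field/intensity ratios with
#' median and IQR, an origin-constrained least-squares slope, and the
#' Pearson correlation of field against intensity.
#'
#' @param measurements list of `field_measurement` objects at two or more
#'   distinct intensities.
#' @return List with `ratios_mV_mm_per_mA`, `median_ratio`, `iqr_ratio`
#'   (length-2 quartiles), `slope_mV_mm_per_mA` (through-origin LS),
#'   `pearson_r`, `p_value`, `n`.
#' @export
per_milliamp_slope <- function(measurements) {
  E <- vapply(measurements, `[[`, numeric(1), "summary_mV_mm")
  I <- vapply(measurements, `[[`, numeric(1), "intensity_mA")
  if (length(unique(I)) < 2)
    stop("need >= 2 distinct intensities", call. = FALSE)
  ratios <- E / I
  ct <- stats::cor.test(I, E, method = "pearson")
  list(ratios_mV_mm_per_mA = ratios,
       median_ratio = stats::median(ratios),
       iqr_ratio = unname(stats::quantile(ratios, c(0.25, 0.75))),
       mean_ratio = mean(ratios),
       slope_mV_mm_per_mA = sum(E * I) / sum(I^2),
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(E))
}

#' Shunting ratio between skull-applied and scalp-applied stimulation
#'
#' Pairs SES and TES field measurements by intensity or frequency and
#' forms per-pair ratios `E_ses / E_tes`. The aggregate is the mean of
#' per-pair ratios (not the ratio of means). When pairing by frequency,
#' a one-way ANOVA across frequency groups (with Bonferroni-corrected
#' pairwise tests) checks whether the ratio depends on frequency.
#'
#' @param ses,tes lists of `field_measurement` objects.
#' @param pairing `"intensity"` or `"frequency"`.
#' @param anova if `TRUE` and pairing is by frequency with >= 2 ratios
#'   per group, adds the ANOVA table.
#' @return List with `pairs` (data frame: key, e_ses, e_tes, ratio),
#'   `mean_ratio`, `sd_ratio`, and optionally `anova_p`,
#'   `pairwise_p_bonferroni`.
#' @export
shunting_ratio <- function(ses, tes, pairing = c("intensity", "frequency"),
                           anova = FALSE) {
  pairing <- match.arg(pairing)
  key <- if (pairing == "intensity") "intensity_mA" else "frequency_hz"
  ks <- vapply(ses, `[[`, numeric(1), key)
  kt <- vapply(tes, `[[`, numeric(1), key)
  es <- vapply(ses, `[[`, numeric(1), "summary_mV_mm")
  et <- vapply(tes, `[[`, numeric(1), "summary_mV_mm")
  # pair in order within each key value
  pairs <- NULL
  for (k in sort(unique(ks))) {
    i <- which(ks == k); j <- which(kt == k)
    m <- min(length(i), length(j))
    if (m == 0) next
    pairs <- rbind(pairs, data.frame(key = k, e_ses = es[i[seq_len(m)]],
                                     e_tes = et[j[seq_len(m)]]))
  }
  if (is.null(pairs) || !nrow(pairs))
    stop("no pairable measurements under pairing by ", pairing, call. = FALSE)
  pairs$ratio <- pairs$e_ses / pairs$e_tes
  out <- list(pairs = pairs, mean_ratio = mean(pairs$ratio),
              sd_ratio = stats::sd(pairs$ratio), pairing = pairing)
  if (anova && length(unique(pairs$key)) >= 2 &&
      all(table(pairs$key) >= 2)) {
    fit <- stats::aov(ratio ~ factor(key), data = pairs)
    out$anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    out$pairwise_p_bonferroni <- stats::pairwise.t.test(
      pairs$ratio, factor(pairs$key), p.adjust.method = "bonferroni")$p.value
  }
  out
}

#' Current required to reach a target field
#'
#' @param slope_mV_mm_per_mA per-milliamp field slope.
#' @param target_mV_mm target field (default 1 mV/mm, the commonly cited
#'   threshold for direct neuronal effects).
#' @param digits reporting precision (default one decimal).
#' @return Required current in mA.
#' @export
required_current <- function(slope_mV_mm_per_mA, target_mV_mm = 1,
                             digits = 1) {
  if (slope_mV_mm_per_mA <= 0) stop("slope must be > 0", call. = FALSE)
  round(target_mV_mm / slope_mV_mm_per_mA, digits)
}

#' Monotonic trend of field against stimulus frequency
#'
#' Spearman rank correlation of the field magnitudes against frequency,
#' plus the relative change from the lowest to the highest frequency.
#' With constant values the correlation is undefined (all ties) and is
#' reported as 0 with `tied = TRUE`.
#'
#' @param measurements list of `field_measurement` objects at three or
#'   more frequencies.
#' @return List with `spearman_r`, `p_value`, `percent_change`
#'   (`(E_last - E_first)/E_first * 100`, frequencies sorted ascending),
#'   `tied`.
#' @export
frequency_trend <- function(measurements) {
  f <- vapply(measurements, `[[`, numeric(1), "frequency_hz")
  E <- vapply(measurements, `[[`, numeric(1), "summary_mV_mm")
  if (length(unique(f)) < 3) stop("need >= 3 frequencies", call. = FALSE)
  o <- order(f)
  f <- f[o]; E <- E[o]
  tied <- stats::sd(E) == 0
  if (tied) {
    r <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::cor.test(f, E, method = "spearman"))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(spearman_r = r, p_value = p,
       percent_change = (E[length(E)] - E[1]) / E[1] * 100, tied = tied)
}
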