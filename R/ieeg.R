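#' Stimulation-session iEEG container
#'
#' One stimulation session is 30 s pre-stimulation, 50 s stimulation and
#' 20 s post-stimulation, recorded at 512 Hz. Only the pre and post
#' phases enter spectral analysis; the stimulation phase carries the
#' pulse artifact and is excluded.
#'
#' @param trace numeric vector (single channel, µV).
#' @param fs_hz sampling rate (default 512).
#' @param phases named numeric vector of phase durations in seconds
#'   (default `c(pre = 30, stim = 50, post = 20)`).
#' @param condition `"TES"`, `"SES"` or `"baseline"`.
#' @param intensity_mA stimulus intensity.
#' @return An `ieeg_session` object.
#' @export
ieeg_session <- function(trace, fs_hz = 512,
                         phases = c(pre = 30, stim = 50, post = 20),
                         condition = "baseline", intensity_mA = 0) {
  trace <- as.numeric(trace)
  n_expect <- round(sum(phases) * fs_hz)
  if (length(trace) != n_expect)
    stop("trace length ", length(trace), " does not match phase durations (",
         n_expect, " samples)", call. = FALSE)
  structure(list(trace = trace, fs_hz = fs_hz, phases = phases,
                 condition = condition, intensity_mA = intensity_mA),
            class = "ieeg_session")
}

#' Extract one phase of a session
#'
#' @param session an [ieeg_session()].
#' @param phase `"pre"`, `"stim"` or `"post"`.
#' @return Numeric vector with the phase samples.
#' @export
session_phase <- function(session, phase = c("pre", "stim", "post")) {
  phase <- match.arg(phase)
  fs <- session$fs_hz
  edges <- round(cumsum(c(0, session$phases)) * fs)
  i <- match(phase, names(session$phases))
  if (edges[i + 1] <= edges[i]) return(numeric(0))
  session$trace[(edges[i] + 1):edges[i + 1]]
}

#' Preprocess an iEEG session
#'
#' Zero-phase Butterworth bandpass (default 1-100 Hz) plus a zero-phase
#' Butterworth notch (default 58-62 Hz band-stop) to suppress mains
#' interference. Phase boundaries are preserved.
#'
#' @param session an [ieeg_session()].
#' @param low_hz,high_hz bandpass edges.
#' @param notch_hz mains frequency to notch out (NULL skips the notch).
#' @param notch_halfwidth_hz half-width of the stop band.
#' @param order Butterworth order per stage.
#' @return The filtered session.
#' @export
preprocess_ieeg <- function(session, low_hz = 1, high_hz = 100,
                            notch_hz = 60, notch_halfwidth_hz = 2,
                            order = 4) {
  stopifnot(inherits(session, "ieeg_session"))
  nyq <- session$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  x <- session$trace
  # high-pass/low-pass cascade: stable even for edges far below Nyquist
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  x <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  if (!is.null(notch_hz)) {
    if (notch_hz + notch_halfwidth_hz >= nyq)
      stop("notch band outside Nyquist", call. = FALSE)
    nf <- signal::butter(2, c(notch_hz - notch_halfwidth_hz,
                              notch_hz + notch_halfwidth_hz) / nyq,
                         type = "stop")
    x <- signal::filtfilt(nf, x)
  }
  session$trace <- x
  session
}

#' Welch power spectral density with Hamming windows
#'
#' Averaged periodogram of Hamming-windowed segments with 50% overlap,
#' normalized as a one-sided density so that `sum(psd) * df` recovers the
#' signal variance (Parseval, up to window loss which the normalization
#' corrects in expectation).
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate.
#' @param window_s window length in seconds (default 2 s, i.e. 1024
#'   samples at 512 Hz, giving 0.5 Hz resolution).
#' @param overlap fractional overlap (default 0.5).
#' @return A `psd` object: list with `freq_hz`, `psd` (power per Hz),
#'   `df_hz`, `n_windows`.
#' @export
welch_psd <- function(x, fs_hz, window_s = 2, overlap = 0.5) {
  nwin <- round(window_s * fs_hz)
  step <- max(1, round(nwin * (1 - overlap)))
  if (length(x) < nwin + step)
    stop("segment too short: need at least 2 windows", call. = FALSE)
  starts <- seq(1, length(x) - nwin + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  U <- sum(w^2)                       # window power normalization
  nfreq <- nwin %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)] * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / (fs_hz * U)
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist for even nwin)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  structure(list(freq_hz = seq(0, by = fs_hz / nwin, length.out = nfreq),
                 psd = psd, df_hz = fs_hz / nwin, n_windows = length(starts)),
            class = "psd")
}

#' Band-integrated power from a PSD
#'
#' @param spec a `psd` object.
#' @param low_hz,high_hz band edges; power is integrated over
#'   `[low, high)`.
#' @return Band power (same units as signal variance).
#' @export
band_power <- function(spec, low_hz, high_hz) {
  sel <- spec$freq_hz >= low_hz & spec$freq_hz < high_hz
  sum(spec$psd[sel]) * spec$df_hz
}

#' Canonical EEG band definitions
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz.
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Per-bin spectral change between two phases
#'
#' Bin-integrated power difference (post minus pre) over contiguous
#' 2-Hz bins tiling 2-30 Hz. Antisymmetric: swapping pre and post negates
#' every bin.
#'
#' @param pre,post `psd` objects on the same frequency grid.
#' @param bin_edges bin edges in Hz (default `seq(2, 30, by = 2)`).
#' @return Data frame with `bin_low_hz`, `bin_high_hz`, `bin_center_hz`,
#'   `pre_power`, `post_power`, `change`.
#' @export
psd_change <- function(pre, post, bin_edges = seq(2, 30, by = 2)) {
  if (!isTRUE(all.equal(pre$freq_hz, post$freq_hz)))
    stop("pre and post PSDs are on different frequency grids", call. = FALSE)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  pp <- vapply(seq_along(lo), function(i) band_power(pre, lo[i], hi[i]),
               numeric(1))
  qp <- vapply(seq_along(lo), function(i) band_power(post, lo[i], hi[i]),
               numeric(1))
  data.frame(bin_low_hz = lo, bin_high_hz = hi, bin_center_hz = (lo + hi) / 2,
             pre_power = pp, post_power = qp, change = qp - pp)
}

#' Band-power change of a session, optionally normalized to baseline
#'
#' Computes per-band (post - pre) power changes. If a baseline session's
#' change is supplied, also reports the ratio of each band change to the
#' magnitude of the baseline change in that band.
#'
#' @param session an [ieeg_session()] (preprocessed or raw).
#' @param bands band definition list (default [eeg_bands()]).
#' @param window_s,overlap Welch parameters.
#' @param baseline_change optional named vector of baseline band changes
#'   (same bands) to normalize against.
#' @return List with `pre_power`, `post_power`, `change` (named per
#'   band), and `ratio_to_baseline` when a baseline is given.
#' @export
band_change <- function(session, bands = eeg_bands(), window_s = 2,
                        overlap = 0.5, baseline_change = NULL) {
  pre <- session_phase(session, "pre")
  post <- session_phase(session, "post")
  if (!length(post)) stop("empty post segment", call. = FALSE)
  spre <- welch_psd(pre, session$fs_hz, window_s, overlap)
  spost <- welch_psd(post, session$fs_hz, window_s, overlap)
  bp <- function(s) vapply(bands, function(b) band_power(s, b[1], b[2]),
                           numeric(1))
  pre_p <- bp(spre); post_p <- bp(spost)
  out <- list(pre_power = pre_p, post_power = post_p,
              change = post_p - pre_p)
  if (!is.null(baseline_change)) {
    out$ratio_to_baseline <- out$change / abs(baseline_change[names(bands)])
  }
  out
}

#' Compare per-band spectral changes across conditions
#'
#' Paired two-sided t-tests of the per-session band changes between
#' condition pairs, aligned by repetition index, with Bonferroni
#' correction across bands. Zero-variance differences are reported as
#' p = 1 with a flag rather than NaN.
#'
#' @param changes named list of matrices (one per condition), each
#'   `repetitions x bands` of band-power changes. Build with
#'   [band_change()] over sessions.
#' @param alpha significance level applied to the corrected p-values.
#' @return Data frame with one row per (comparison, band): raw p,
#'   Bonferroni-corrected p, t statistic, significance flag, and a
#'   `zero_variance` flag.
#' @export
compare_conditions <- function(changes, alpha = 0.05) {
  stopifnot(is.list(changes), length(changes) >= 2, !is.null(names(changes)))
  conds <- names(changes)
  bands <- colnames(changes[[1]])
  out <- NULL
  combos <- utils::combn(conds, 2)
  for (k in seq_len(ncol(combos))) {
    a <- changes[[combos[1, k]]]
    b <- changes[[combos[2, k]]]
    if (nrow(a) != nrow(b))
      stop("conditions have different repetition counts", call. = FALSE)
    for (band in bands) {
      d <- a[, band] - b[, band]
      if (stats::sd(d) == 0) {
        p <- 1; tval <- 0; zv <- TRUE
      } else {
        tt <- stats::t.test(a[, band], b[, band], paired = TRUE)
        p <- tt$p.value; tval <- unname(tt$statistic); zv <- FALSE
      }
      out <- rbind(out, data.frame(
        comparison = paste(combos[1, k], "vs", combos[2, k]),
        band = band, t = tval, p = p, zero_variance = zv))
    }
  }
  out$p_bonferroni <- pmin(out$p * length(bands), 1)
  out$significant <- out$p_bonferroni < alpha
  out
}
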