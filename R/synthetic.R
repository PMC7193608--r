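#' Stimulus waveform synthesis
#'
#' Generates the two stimulus shapes used throughout: a plain sinusoid,
#' and a charge-balanced biphasic pulse train (one full sine cycle per
#' pulse, positive phase then exactly negated second phase, so the net
#' charge per pulse is zero to machine precision).
#'
#' @param shape `"sinusoidal"` or `"biphasic"`.
#' @param amplitude_mA peak amplitude.
#' @param frequency_hz sinusoid frequency, or pulse repetition rate for
#'   the biphasic shape (default 1 Hz).
#' @param pulse_width_ms per-phase width of the biphasic pulse (default
#'   0.5 ms).
#' @param fs_hz sampling rate; must resolve the pulse
#'   (`fs >= 10 / width`).
#' @param duration_s total duration.
#' @return Numeric vector of current samples (mA), with attributes
#'   `fs_hz` and `shape`.
#' @export
make_stimulus <- function(shape = c("sinusoidal", "biphasic"),
                          amplitude_mA = 1, frequency_hz = 1,
                          pulse_width_ms = 0.5, fs_hz = 20000,
                          duration_s = 3) {
  shape <- match.arg(shape)
  n <- round(fs_hz * duration_s)
  t <- seq_len(n) / fs_hz
  if (shape == "sinusoidal") {
    out <- amplitude_mA * sin(2 * pi * frequency_hz * t)
  } else {
    width_s <- pulse_width_ms / 1000
    if (fs_hz < 10 / width_s)
      stop("sampling rate too low to resolve the pulse width (need fs >= ",
           10 / width_s, " Hz)", call. = FALSE)
    k <- round(width_s * fs_hz)              # samples per phase
    half <- amplitude_mA * sin(pi * (seq_len(k) - 0.5) / k)
    pulse <- c(half, -half)                  # exact charge balance
    out <- numeric(n)
    starts <- round(seq(0, duration_s - 1 / frequency_hz,
                        by = 1 / frequency_hz) * fs_hz) + 1L
    for (s in starts) {
      idx <- s:min(s + length(pulse) - 1, n)
      out[idx] <- out[idx] + pulse[seq_along(idx)]
    }
  }
  attr(out, "fs_hz") <- fs_hz
  attr(out, "shape") <- shape
  out
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Synthesize a subdural strip recording epoch
#'
#' Builds contact potentials whose peak-to-peak adjacent differences
#' reproduce the requested pair fields: contact amplitudes are the
#' cumulative pair fields times the contact spacing (halved, since the
#' measurement chain reports peak-to-peak values), modulated by a
#' sinusoidal stimulus and overlaid with i.i.d. Gaussian DAQ noise.
#'
#' @param pair_fields_mV_mm adjacent-pair field magnitudes (mV/mm),
#'   length `n_contacts - 1`; e.g. from [strip_pair_fields()] of a
#'   forward solution.
#' @param intensity_mA,frequency_hz stimulus metadata (the waveform is
#'   synthesized at unit relative amplitude; fields already include the
#'   intensity).
#' @param duration_s,fs_hz epoch length and sampling rate (defaults 3 s,
#'   20 kHz).
#' @param noise_sd_mV additive Gaussian noise SD.
#' @param spacing_mm contact spacing.
#' @param condition condition label.
#' @param seed RNG seed (restores the global RNG state afterwards).
#' @return A [recording_epoch()].
#' @export
make_strip_recording <- function(pair_fields_mV_mm, intensity_mA = 1,
                                 frequency_hz = 1000, duration_s = 3,
                                 fs_hz = 20000, noise_sd_mV = 0,
                                 spacing_mm = 5, condition = "TES",
                                 seed = NULL) {
  stopifnot(noise_sd_mV >= 0, duration_s > 0)
  amps <- cumsum(c(0, pair_fields_mV_mm)) * spacing_mm / 2   # mV
  n <- round(fs_hz * duration_s)
  s <- sin(2 * pi * frequency_hz * seq_len(n) / fs_hz)
  data <- outer(amps, s)
  if (noise_sd_mV > 0)
    data <- data + with_seed(seed,
      matrix(stats::rnorm(length(data), sd = noise_sd_mV), nrow(data)))
  recording_epoch(data, fs_hz, intensity_mA, frequency_hz, condition)
}

# Gaussian trace with a prescribed power spectrum, in one FFT: the
# two-sided spectral shape of every component (1/f background + one
# Gaussian bump per oscillator) is summed with each component scaled so
# its expected variance equals rms^2, then colored complex Gaussian
# noise is transformed back. Component amplitudes are therefore
# stochastic (chi-square band powers), as in real EEG.
synth_spectrum_trace <- function(n, fs, components) {
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  S <- numeric(n)
  for (comp in components) {
    shape <- comp$shape(f)
    shape[1] <- 0                            # no DC
    tot <- sum(shape)
    if (tot > 0) S <- S + comp$rms^2 * shape / tot
  }
  Z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  Re(stats::fft(Z * n * sqrt(S), inverse = TRUE)) / n
}

#' Synthesize an iEEG stimulation session
#'
#' A 1/f Gaussian background plus one narrowband oscillator per EEG band
#' (defaults at 2, 6, 10 and 20 Hz), generated independently per phase.
#' For the `"SES"` condition the post-phase amplitudes of the affected
#' bands (default alpha and beta) are multiplied by `effect_multiplier`;
#' `"TES"` and `"baseline"` use multiplier 1. The stimulation phase
#' optionally carries a 1 Hz biphasic pulse-artifact train scaled by the
#' stimulus intensity.
#'
#' @param condition `"SES"`, `"TES"` or `"baseline"`.
#' @param effect_multiplier post-phase amplitude multiplier applied to
#'   `affected_bands` under `"SES"` (default 2).
#' @param affected_bands character, bands whose oscillators are boosted.
#' @param oscillators data frame with columns `band`, `center_hz`,
#'   `bandwidth_hz`, `rms_uV`.
#' @param background_rms_uV RMS of the 1/f background.
#' @param background_exponent spectral exponent chi of the `1/f^chi`
#'   background (default 1).
#' @param fs_hz sampling rate (default 512).
#' @param phases phase durations in seconds.
#' @param intensity_mA stimulus intensity (drives only the artifact
#'   amplitude in the excluded stim phase).
#' @param include_artifact add the pulse artifact to the stim phase.
#' @param seed RNG seed.
#' @return An [ieeg_session()].
#' @export
make_ieeg_session <- function(condition = c("baseline", "TES", "SES"),
                              effect_multiplier = 2,
                              affected_bands = c("alpha", "beta"),
                              oscillators = default_oscillators(),
                              background_rms_uV = 10,
                              background_exponent = 1,
                              fs_hz = 512,
                              phases = c(pre = 30, stim = 50, post = 20),
                              intensity_mA = 1,
                              include_artifact = TRUE,
                              seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(effect_multiplier > 0, all(phases > 0))
  with_seed(seed, {
    make_phase <- function(dur, boost) {
      n <- round(dur * fs_hz)
      comps <- list(list(
        shape = function(f) ifelse(f > 0, f^(-background_exponent), 0),
        rms = background_rms_uV))
      for (i in seq_len(nrow(oscillators))) {
        o <- oscillators[i, ]
        mult <- if (boost && o$band %in% affected_bands) effect_multiplier else 1
        comps <- c(comps, list(list(
          shape = local({ c0 <- o$center_hz; bw <- o$bandwidth_hz
            function(f) exp(-(f - c0)^2 / (2 * bw^2)) }),
          rms = o$rms_uV * mult)))
      }
      synth_spectrum_trace(n, fs_hz, comps)
    }
    boost_post <- condition == "SES"
    pre <- make_phase(phases[["pre"]], FALSE)
    stim <- make_phase(phases[["stim"]], FALSE)
    if (include_artifact && condition != "baseline") {
      # the 0.5 ms biphasic pulse is sub-sample at 512 Hz: represent each
      # pulse as a charge-balanced +/- two-sample spike at the 1 Hz rate
      nst <- round(phases[["stim"]] * fs_hz)
      art <- numeric(nst)
      at <- round(seq(0, phases[["stim"]] - 1) * fs_hz) + 1L
      art[at] <- 1; art[pmin(at + 1L, nst)] <- -1
      stim <- stim + art * intensity_mA * 100   # µV per mA
    }
    post <- make_phase(phases[["post"]], boost_post)
    ieeg_session(c(pre, stim, post), fs_hz = fs_hz, phases = phases,
                 condition = condition, intensity_mA = intensity_mA)
  })
}

#' @rdname make_ieeg_session
#' @export
default_oscillators <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             center_hz = c(2, 6, 10, 20),
             bandwidth_hz = c(0.6, 1, 1, 2),
             rms_uV = c(5, 5, 5, 5),
             stringsAsFactors = FALSE)
}

#' Synthesize a conductivity-calibration dataset
#'
#' Forward-solves the given montages on a shell model whose scalp and
#' skull conductivities are set to a known truth, samples the subdural
#' strip, and perturbs the pair fields with multiplicative Gaussian noise
#' (gain-like measurement error). The truth is carried in a sealed
#' `truth` field for test audits only; the calibration itself never
#' reads it.
#'
#' @param model a shell `tissue_model` template (its scalp/skull values
#'   are overridden by the truth).
#' @param truth_sigma_scalp,truth_sigma_skull ground-truth conductivities
#'   (S/m); may deliberately lie outside the search bounds.
#' @param montages list of `montage` objects on `model` (or on the
#'   matching entry of `models`).
#' @param strip a [strip_spec()] (e.g. [strip_on_inner_surface()]).
#' @param models optional per-montage model variants (e.g. a
#'   scalp-removed shell model for the skull-exposed condition); passed
#'   through to [calibration_problem()].
#' @param noise_frac relative noise SD (0.02 = 2%).
#' @param seed RNG seed.
#' @param n_max series truncation for the forward solves.
#' @return A [calibration_problem()] with `measured` filled in.
#' @export
make_calibration_dataset <- function(model, truth_sigma_scalp = 4e-4,
                                     truth_sigma_skull = 4e-3,
                                     montages, strip, models = NULL,
                                     noise_frac = 0, seed = NULL,
                                     n_max = 200) {
  stopifnot(model$kind == "shells",
            truth_sigma_scalp > 0, truth_sigma_skull > 0)
  if (is.null(models)) models <- rep(list(model), length(montages))
  truth_models <- lapply(models, set_free_conductivities,
                         truth_sigma_scalp, truth_sigma_skull)
  measured <- with_seed(seed, Map(function(tm, m) {
    sol <- solve_potential(tm, m, n_max = n_max)
    f <- strip_pair_fields(field_along_strip(sol, strip), strip$spacing_mm)
    if (noise_frac > 0)
      f <- f * (1 + stats::rnorm(length(f), sd = noise_frac))
    f
  }, truth_models, montages))
  prob <- calibration_problem(model, montages, measured, strip,
                              models = models)
  prob$truth <- c(sigma_scalp = truth_sigma_scalp,
                  sigma_skull = truth_sigma_skull)
  prob
}
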