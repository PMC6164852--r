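#' Default P-QRS-T wave morphology
#'
#' Amplitudes, Gaussian widths and temporal offsets (relative to the R peak)
#' of the five characteristic ECG waves used by the synthesizer. Values give
#' a plausible adult sinus-rhythm beat with a 1 mV R peak.
#'
#' @return A tibble with columns `wave`, `amp_mV`, `width_s`, `offset_s`.
#' @export
default_wave_params <- function() {
  tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amp_mV = c(0.12, -0.10, 1.00, -0.15, 0.30),
    width_s = c(0.025, 0.010, 0.012, 0.010, 0.045),
    offset_s = c(-0.170, -0.026, 0.000, 0.026, 0.240)
  )
}

#' Synthesis parameters for the ECG generator
#'
#' Bundles everything the generator needs: duration, heart-rate statistics,
#' per-wave morphology, the two structured noise sources the preprocessing
#' stage targets (sub-0.67 Hz respiratory baseline drift and powerline
#' interference above 45 Hz), broadband sensor noise, and the seed.
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 200).
#' @param hr_mean_bpm Mean heart rate in beats/min (> 0).
#' @param hr_sd_bpm Beat-to-beat heart-rate standard deviation in beats/min.
#' @param wave_params Morphology table as in [default_wave_params()].
#' @param baseline_amp_mV,baseline_freq_hz Respiratory baseline-drift
#'   sinusoid; the frequency must stay below 0.67 Hz.
#' @param powerline_amp_mV,powerline_freq_hz Powerline interference sinusoid;
#'   the frequency must exceed 45 Hz (50 Hz default, set 60 for US mains).
#' @param white_noise_sd_mV Standard deviation of white Gaussian sensor noise.
#' @param adc_gain_per_mV Digitizer gain in counts per millivolt. Long-term
#'   Holter recordings are stored as integer ADC counts (about 5 uV per
#'   least-significant bit, i.e. 200 counts/mV, the default); the rendered
#'   millivolt waveform is multiplied by this gain and rounded to integer
#'   counts, which is the amplitude scale entropy extraction was designed
#'   for. Set to 1 to synthesize un-digitized millivolt floats.
#' @param seed Integer seed; identical parameters give bit-identical records.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration_s,
                         fs = 200,
                         hr_mean_bpm = 75,
                         hr_sd_bpm = 5,
                         wave_params = default_wave_params(),
                         baseline_amp_mV = 0.10,
                         baseline_freq_hz = 0.30,
                         powerline_amp_mV = 0.02,
                         powerline_freq_hz = 50,
                         white_noise_sd_mV = 0.05,
                         adc_gain_per_mV = 200,
                         seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  check_number(hr_mean_bpm, "hr_mean_bpm", min = 0, strict_min = TRUE)
  check_number(hr_sd_bpm, "hr_sd_bpm", min = 0)
  check_number(baseline_amp_mV, "baseline_amp_mV", min = 0)
  check_number(baseline_freq_hz, "baseline_freq_hz", min = 0)
  if (baseline_freq_hz >= 0.67) {
    abort_param("`baseline_freq_hz` must be below 0.67 Hz (respiratory band).")
  }
  check_number(powerline_amp_mV, "powerline_amp_mV", min = 0)
  check_number(powerline_freq_hz, "powerline_freq_hz", min = 0)
  if (powerline_freq_hz <= 45) {
    abort_param("`powerline_freq_hz` must be above 45 Hz (mains band).")
  }
  check_number(white_noise_sd_mV, "white_noise_sd_mV", min = 0)
  check_number(adc_gain_per_mV, "adc_gain_per_mV", min = 0, strict_min = TRUE)
  wp <- tibble::as_tibble(wave_params)
  need <- c("wave", "amp_mV", "width_s", "offset_s")
  if (!all(need %in% names(wp))) {
    abort_param("`wave_params` must have columns wave, amp_mV, width_s, offset_s.")
  }
  if (any(wp$width_s <= 0)) abort_param("wave widths must be positive.")
  structure(
    list(duration_s = duration_s, fs = fs,
         hr_mean_bpm = hr_mean_bpm, hr_sd_bpm = hr_sd_bpm,
         wave_params = wp,
         baseline_amp_mV = baseline_amp_mV,
         baseline_freq_hz = baseline_freq_hz,
         powerline_amp_mV = powerline_amp_mV,
         powerline_freq_hz = powerline_freq_hz,
         white_noise_sd_mV = white_noise_sd_mV,
         adc_gain_per_mV = adc_gain_per_mV,
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf(
    "<synth_params> %.0f s @ %g Hz, HR %g +/- %g bpm, noise(baseline %g mV @ %g Hz, mains %g mV @ %g Hz, white sd %g mV), seed %d\n",
    x$duration_s, x$fs, x$hr_mean_bpm, x$hr_sd_bpm,
    x$baseline_amp_mV, x$baseline_freq_hz,
    x$powerline_amp_mV, x$powerline_freq_hz, x$white_noise_sd_mV, x$seed))
  invisible(x)
}

# RR interval physiologic truncation bounds (seconds): excludes absurd beats
# and keeps one-beat windowing well defined.
RR_MIN_S <- 0.3
RR_MAX_S <- 2.0

#' Draw a beat-to-beat RR interval series
#'
#' RR intervals are independent draws from a normal distribution with mean
#' `60 / hr_mean_bpm` seconds and standard deviation
#' `60 * hr_sd_bpm / hr_mean_bpm^2` (the first-order propagation of the
#' heart-rate spread to the interval scale), truncated to the physiologic
#' range 0.3-2.0 s by rejection. Intervals are drawn until their sum reaches
#' the requested duration.
#'
#' @param params A [synth_params()] object.
#' @return Numeric vector of RR intervals in seconds whose sum is at least
#'   `params$duration_s`. Identical parameters (including seed) give an
#'   identical series.
#' @export
generate_rr_series <- function(params) {
  if (!inherits(params, "synth_params")) {
    abort_param("`params` must be a synth_params object.")
  }
  withr::with_seed(params$seed, generate_rr_impl(params))
}

generate_rr_impl <- function(params) {
  mean_rr <- 60 / params$hr_mean_bpm
  sd_rr <- 60 * params$hr_sd_bpm / params$hr_mean_bpm^2
  if (mean_rr < RR_MIN_S || mean_rr > RR_MAX_S) {
    abort_param(sprintf(
      "Mean RR %.3f s falls outside the physiologic range [%.1f, %.1f] s.",
      mean_rr, RR_MIN_S, RR_MAX_S))
  }
  if (sd_rr == 0) {
    n <- ceiling(params$duration_s / mean_rr)
    return(rep(mean_rr, n))
  }
  rr <- numeric(0)
  total <- 0
  while (total < params$duration_s) {
    need <- max(16L, ceiling((params$duration_s - total) / mean_rr * 1.1))
    draw <- rnorm(need, mean_rr, sd_rr)
    draw <- draw[draw >= RR_MIN_S & draw <= RR_MAX_S]
    rr <- c(rr, draw)
    total <- sum(rr)
  }
  rr[seq_len(which(cumsum(rr) >= params$duration_s)[1])]
}

#' Synthesize a ground-truth-annotated ECG record
#'
#' Each beat is rendered as the sum of five Gaussian bumps (P, Q, R, S, T)
#' positioned relative to the beat's R time, an ECGSYN-like construction that
#' is smooth and maps directly onto the five characteristic points of the
#' waveform. Respiration-band baseline drift and powerline interference are
#' added as sinusoids with seeded random phases, plus white Gaussian sensor
#' noise. The true R-peak sample indices are returned as annotations.
#'
#' @param params A [synth_params()] object.
#' @return An [ecg_record()] of `round(duration_s * fs)` samples.
#' @export
synthesize_ecg <- function(params) {
  if (!inherits(params, "synth_params")) {
    abort_param("`params` must be a synth_params object.")
  }
  withr::with_seed(params$seed, {
    rr <- generate_rr_impl(params)
    n <- round(params$duration_s * params$fs)
    r_times <- cumsum(rr)
    r_idx <- round(r_times * params$fs) + 1L
    r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
    wp <- params$wave_params
    x <- .render_beats_c(n, params$fs, as.integer(r_idx),
                         wp$amp_mV, wp$width_s, wp$offset_s)
    tvec <- (seq_len(n) - 1) / params$fs
    phases <- stats::runif(2, 0, 2 * pi)
    if (params$baseline_amp_mV > 0) {
      x <- x + params$baseline_amp_mV *
        sin(2 * pi * params$baseline_freq_hz * tvec + phases[1])
    }
    if (params$powerline_amp_mV > 0) {
      x <- x + params$powerline_amp_mV *
        sin(2 * pi * params$powerline_freq_hz * tvec + phases[2])
    }
    if (params$white_noise_sd_mV > 0) {
      x <- x + rnorm(n, 0, params$white_noise_sd_mV)
    }
    if (params$adc_gain_per_mV != 1) {
      x <- round(x * params$adc_gain_per_mV)
    }
    ecg_record(x, fs = params$fs,
               subject_id = sprintf("synthetic-seed%d", params$seed),
               annotations = r_idx)
  })
}
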