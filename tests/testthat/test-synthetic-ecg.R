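test_that("RR series reduces to 60/hr with zero heart-rate variability", {
  p60 <- synth_params(duration_s = 30, hr_mean_bpm = 60, hr_sd_bpm = 0)
  expect_true(all(generate_rr_series(p60) == 1.0))
  p100 <- synth_params(duration_s = 30, hr_mean_bpm = 100, hr_sd_bpm = 0)
  expect_true(all(generate_rr_series(p100) == 0.6))
})

test_that("RR series follows the truncated normal it is drawn from", {
  p <- synth_params(duration_s = 8000, hr_mean_bpm = 75, hr_sd_bpm = 5,
                    seed = 11)
  rr <- generate_rr_series(p)
  expect_gt(length(rr), 9000)
  expect_true(all(rr >= 0.3 & rr <= 2.0))
  # law of large numbers: sample mean within 1% of 60/75 = 0.8 s
  expect_lt(abs(mean(rr) - 0.8), 0.008)
  expect_gte(sum(rr), p$duration_s)
  # identical seed, identical draw
  expect_identical(rr, generate_rr_series(p))
})

test_that("synthesis is deterministic under a fixed seed", {
  p <- synth_params(duration_s = 20, seed = 4)
  r1 <- synthesize_ecg(p)
  r2 <- synthesize_ecg(p)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- synthesize_ecg(synth_params(duration_s = 20, seed = 5))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("a noiseless fixed-rate record is exactly periodic", {
  rec <- synthesize_ecg(noiseless_params(60, hr_bpm = 60))
  period <- 200L  # round(fs * RR)
  core <- 401:(length(rec$samples) - 401 - period)
  expect_identical(rec$samples[core], rec$samples[core + period])
  expect_true(all(diff(rec$annotations) == period))
})

test_that("the global maximum of each beat sits at the annotated R index", {
  rec <- synthesize_ecg(noiseless_params(120, hr_bpm = 72, seed = 9))
  half <- round(0.4 * rec$fs)
  hits <- vapply(rec$annotations, function(a) {
    lo <- max(1L, a - half); hi <- min(length(rec$samples), a + half)
    lo + which.max(rec$samples[lo:hi]) - 1L == a
  }, logical(1))
  expect_true(all(hits))
})

test_that("annotations are recoverable by local-max search under sensor noise", {
  # noiseless: exact; at 10% of the R amplitude the argmax can shift by one
  # sample (the noise sd is comparable to the peak curvature), so near-exact
  # recovery is the attainable property
  recover_offsets <- function(rec, tol_s = 0.05) {
    tol <- round(tol_s * rec$fs)
    vapply(rec$annotations, function(a) {
      lo <- max(1L, a - tol); hi <- min(length(rec$samples), a + tol)
      abs(lo + which.max(rec$samples[lo:hi]) - 1L - a)
    }, numeric(1))
  }
  clean <- synthesize_ecg(noiseless_params(120, hr_bpm = 70, seed = 2))
  expect_true(all(recover_offsets(clean) == 0))
  noisy <- synthesize_ecg(synth_params(duration_s = 300, seed = 5,
                                       white_noise_sd_mV = 0.1))
  off <- recover_offsets(noisy)
  expect_gte(mean(off <= 1), 0.97)
})

test_that("noise sources live in their stated spectral bands", {
  base <- noiseless_params(200, hr_bpm = 75, seed = 8)
  quiet <- synthesize_ecg(base)
  power_below <- function(noise, fs, f_cut) {
    spec <- Mod(fft(noise))^2
    n <- length(noise)
    freq <- (seq_len(n) - 1) / n * fs
    keep <- freq <= fs / 2
    sum(spec[keep & freq < f_cut]) / sum(spec[keep])
  }
  # baseline drift only
  pb <- synth_params(duration_s = 200, hr_mean_bpm = 75, hr_sd_bpm = 0,
                     baseline_amp_mV = 0.1, powerline_amp_mV = 0,
                     white_noise_sd_mV = 0, seed = 8)
  nb <- synthesize_ecg(pb)$samples - quiet$samples
  expect_gte(power_below(nb, 200, 0.67), 0.99)
  # powerline only: power concentrates at 50 Hz
  pp <- synth_params(duration_s = 200, hr_mean_bpm = 75, hr_sd_bpm = 0,
                     baseline_amp_mV = 0, powerline_amp_mV = 0.05,
                     white_noise_sd_mV = 0, seed = 8)
  np <- synthesize_ecg(pp)$samples - quiet$samples
  spec <- Mod(fft(np))^2
  n <- length(np)
  freq <- (seq_len(n) - 1) / n * 200
  keep <- freq <= 100
  at_mains <- abs(freq - 50) < 0.5
  expect_gte(sum(spec[keep & at_mains]) / sum(spec[keep]), 0.95)
})

test_that("invalid synthesis parameters are rejected", {
  expect_error(synth_params(duration_s = -5), class = "cardiorng_param_error")
  expect_error(synth_params(duration_s = 10, hr_mean_bpm = 0),
               class = "cardiorng_param_error")
  expect_error(synth_params(duration_s = 10, hr_sd_bpm = -1),
               class = "cardiorng_param_error")
  expect_error(synth_params(duration_s = 10, baseline_freq_hz = 0.8),
               class = "cardiorng_param_error")
  expect_error(synth_params(duration_s = 10, powerline_freq_hz = 30),
               class = "cardiorng_param_error")
})

test_that("record constructor enforces its invariants", {
  expect_error(ecg_record(numeric(0)), class = "cardiorng_input_error")
  expect_error(ecg_record(1:10, fs = 0), class = "cardiorng_param_error")
  expect_error(ecg_record(1:10, annotations = c(3, 3)),
               class = "cardiorng_input_error")
  expect_error(ecg_record(1:10, annotations = c(5, 11)),
               class = "cardiorng_input_error")
})
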