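test_that("fractional-mode quantization matches hand arithmetic", {
  cfg <- extractor_config(frac_mode = "fractional")
  expect_identical(quantize_coefficients(0.0, cfg), 0L)
  # f = 0.2345 -> z = 2345 -> 2345 mod 256 = 41
  expect_identical(quantize_coefficients(1.2345, cfg), 41L)
  # negative coefficient: |c| first; f = 0.9999 -> z = 9999 -> 15
  expect_identical(quantize_coefficients(-3.9999, cfg), 15L)
  expect_identical(quantize_coefficients(c(0, 1.2345, -3.9999), cfg),
                   c(0L, 41L, 15L))
})

test_that("scaled-mode quantization folds the integer part into the low bits", {
  cfg <- extractor_config()  # scaled is the default
  expect_identical(cfg$frac_mode, "scaled")
  expect_identical(quantize_coefficients(0.0, cfg), 0L)
  # z = 12345 -> 12345 mod 256 = 57
  expect_identical(quantize_coefficients(1.2345, cfg), 57L)
  # z = 39999 -> 39999 mod 256 = 63
  expect_identical(quantize_coefficients(-3.9999, cfg), 63L)
  # both modes agree for |c| < 1
  frac <- extractor_config(frac_mode = "fractional")
  withr::with_seed(2, v <- runif(100))
  expect_identical(quantize_coefficients(v, cfg), quantize_coefficients(v, frac))
})

test_that("the 24-bit right-shift variant exists and zeroes small values", {
  cfg <- extractor_config(frac_mode = "fractional", shift24 = TRUE)
  # any z bounded by the scale (10^4 < 2^24) shifts to zero
  expect_identical(quantize_coefficients(c(0.1, 0.5, 0.9999), cfg),
                   c(0L, 0L, 0L))
})

test_that("quantizer rejects bad input and bad configuration", {
  expect_error(quantize_coefficients(c(1, NaN), extractor_config()),
               "position 2", class = "cardiorng_data_error")
  expect_error(quantize_coefficients(Inf, extractor_config()),
               class = "cardiorng_data_error")
  expect_error(quantize_coefficients(numeric(0), extractor_config()),
               class = "cardiorng_input_error")
  expect_error(extractor_config(scale = 100, bits_out = 8),
               class = "cardiorng_config_error")
})

test_that("stream assembly is a per-window pass-through of coefficient counts", {
  wcfg <- wavelet_config("daubechies-4", L = 3)
  win <- list(rnorm(184))
  s <- extract_stream(win, wcfg)
  expect_length(s$bytes, 23)
  expect_identical(s$meta$window_bytes, 23L)
  # two identical windows give two identical byte segments
  s2 <- extract_stream(c(win, win), wcfg)
  expect_identical(s2$bytes[1:23], s2$bytes[24:46])
  expect_identical(s2$bytes[1:23], s$bytes)
  expect_error(extract_stream(list(), wcfg), class = "cardiorng_input_error")
  expect_error(extract_stream(list(rnorm(4)), wavelet_config("haar", 4)),
               class = "cardiorng_input_error")
})

test_that("stream length follows the per-window ceiling law on real windows", {
  rec <- synthesize_ecg(noiseless_params(180, hr_bpm = 60, seed = 3))
  cleaned <- preprocess_ecg(rec)
  w <- split_windows(cleaned, detect_r_peaks(cleaned), discard_each_end = 50)
  s <- extract_stream(w, wavelet_config("daubechies-4", 3))
  expect_identical(s$meta$window_bytes,
                   vapply(w$samples, function(x) ceiling(length(x) / 8L),
                          double(1)) |> as.integer())
  expect_length(s$bytes, sum(s$meta$window_bytes))
})

test_that("extraction end to end is deterministic", {
  rec <- synthesize_ecg(synth_params(duration_s = 150, seed = 12))
  s1 <- extract_ecg(rec)
  s2 <- extract_ecg(rec)
  expect_identical(s1$bytes, s2$bytes)
  expect_identical(s1$meta$wf, "daubechies-4")
  expect_identical(s1$meta$L, 4L)
})

test_that("streams round-trip through the raw binary format", {
  s <- random_stream(ref_bytes(1000, 3), subject_id = "s1",
                     wf = "daubechies-4", L = 4L,
                     window_bytes = rep(10L, 100L))
  path <- withr::local_tempfile(fileext = ".bin")
  write_stream(s, path)
  back <- read_stream(path)
  expect_identical(back$bytes, s$bytes)
  expect_identical(back$meta$subject_id, "s1")
  expect_identical(back$meta$n_windows, 100L)
  expect_identical(file.size(path), 1000)
  expect_error(random_stream(c(1L, 999L)), class = "cardiorng_input_error")
})
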