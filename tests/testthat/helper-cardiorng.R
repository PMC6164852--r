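# Reference byte stream from R's own generator: the null model against which
# the ENT-style statistics and the distinctiveness analysis are calibrated.
ref_bytes <- function(n, seed) {
  withr::with_seed(seed, sample.int(256L, n, replace = TRUE) - 1L)
}

# Independent brute-force oracle for one periodized analysis step: build the
# full analysis matrices row by row (filter taps placed with wraparound,
# shifted by two per row) and multiply. Odd-length inputs are extended by
# repeating the last sample, as the transform under test defines.
oracle_dwt_step <- function(x, fb) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, x[n])
  ne <- length(x)
  m <- ne %/% 2L
  L <- length(fb$g)
  A <- matrix(0, m, ne)
  D <- matrix(0, m, ne)
  for (k in seq_len(m)) {
    for (j in seq_len(L)) {
      col <- ((2L * (k - 1L) + 1L - (j - 1L)) %% ne) + 1L
      A[k, col] <- A[k, col] + fb$g[j]
      D[k, col] <- D[k, col] + fb$h[j]
    }
  }
  list(approx = as.numeric(A %*% x), detail = as.numeric(D %*% x))
}

# Iterated oracle for the level-L approximation.
oracle_multilevel_approx <- function(x, fb, levels) {
  for (lev in seq_len(levels)) x <- oracle_dwt_step(x, fb)$approx
  x
}

# Quiet synthetic record with every stochastic term disabled.
noiseless_params <- function(duration_s, hr_bpm = 60, seed = 1, ...) {
  synth_params(duration_s = duration_s, hr_mean_bpm = hr_bpm, hr_sd_bpm = 0,
               baseline_amp_mV = 0, powerline_amp_mV = 0,
               white_noise_sd_mV = 0, seed = seed, ...)
}

all_families <- c("haar", "daubechies-4", "coiflet-3", "symlet-4",
                  "discrete-meyer", "biorthogonal-3.3")
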