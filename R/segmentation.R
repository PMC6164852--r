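#' Detect R peaks in a cleaned ECG
#'
#' Pan-Tompkins-style detection chain: five-point derivative, squaring,
#' moving-window integration (150 ms), adaptive signal/noise thresholds with a
#' 0.25 s refractory period and half-threshold search-back for missed beats.
#' Accepted candidates are refined to the local maximum of the cleaned signal
#' within +/- 100 ms, so on low-noise records the returned index is the R
#' sample itself.
#'
#' @param record A cleaned (DC-free, bandpassed) [ecg_record()].
#' @param refractory_s Minimum spacing between successive peaks in seconds.
#' @return Integer vector of strictly increasing 1-based R-peak sample
#'   indices; empty when the record contains no beats.
#' @export
detect_r_peaks <- function(record, refractory_s = 0.25) {
  if (!inherits(record, "ecg_record")) abort_input("`record` must be an ecg_record.")
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (n < 2 * fs) {
    abort_input("Record shorter than 2 s: too little data for R-peak detection.")
  }
  if (all(x == x[1])) return(integer(0))
  # five-point derivative emphasising QRS slopes
  der <- stats::filter(x, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  refr <- max(1L, round(refractory_s * fs))
  cand <- .pt_scan_c(integ, refr, 0.25, 0.25, 1.66)
  if (length(cand) == 0L) return(integer(0))
  # refine to the local maximum of the cleaned waveform
  half <- round(0.100 * fs)
  peaks <- vapply(cand, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; enforce the refractory period
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) >= refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= refr)
    }
  }
  peaks
}

#' One-beat windows around detected R peaks
#'
#' The record is partitioned at the midpoints between adjacent R peaks, so
#' every window contains exactly one peak and window length tracks the local
#' RR interval. The first and last `discard_each_end` windows are dropped to
#' guarantee the signal is properly registered before any bits are extracted.
#'
#' @param record The cleaned [ecg_record()] the peaks were detected in.
#' @param peaks Integer vector of strictly increasing R-peak indices.
#' @param discard_each_end Number of windows dropped at each end (default 50).
#' @return A tibble of class `beat_windows` with one row per retained window:
#'   `start`, `end` (1-based inclusive sample range), `r_idx`, and a
#'   list-column `samples`.
#' @export
split_windows <- function(record, peaks, discard_each_end = 50) {
  if (!inherits(record, "ecg_record")) abort_input("`record` must be an ecg_record.")
  peaks <- as.integer(peaks)
  if (length(peaks) && any(diff(peaks) <= 0L)) {
    abort_input("`peaks` must be strictly increasing.")
  }
  discard_each_end <- as.integer(discard_each_end)
  need <- 2L * discard_each_end + 1L
  if (length(peaks) < need) {
    abort_input(sprintf(
      "Too few beats: %d detected but at least %d are required (discarding %d windows at each end).",
      length(peaks), need, discard_each_end))
  }
  n <- length(record$samples)
  k <- length(peaks)
  mids <- (peaks[-k] + peaks[-1]) %/% 2L
  starts <- c(1L, mids + 1L)
  ends <- c(mids, n)
  keep <- seq.int(discard_each_end + 1L, k - discard_each_end)
  out <- tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    r_idx = peaks[keep],
    samples = purrr::map2(starts[keep], ends[keep],
                          function(s, e) record$samples[s:e])
  )
  class(out) <- c("beat_windows", class(out))
  attr(out, "fs") <- record$fs
  attr(out, "subject_id") <- record$subject_id
  out
}

#' Score detected peaks against ground-truth annotations
#'
#' Greedy one-to-one matching within a time tolerance, reporting sensitivity
#' (fraction of true beats found) and positive predictivity (fraction of
#' detections that are true beats).
#'
#' @param detected Integer vector of detected R indices.
#' @param truth Integer vector of annotated R indices.
#' @param fs Sampling rate in Hz.
#' @param tol_s Matching tolerance in seconds (default 0.05).
#' @return A tibble with `n_true`, `n_detected`, `matched`, `sensitivity`,
#'   `ppv`.
#' @export
score_detection <- function(detected, truth, fs, tol_s = 0.05) {
  tol <- round(tol_s * fs)
  matched <- 0L
  j <- 1L
  for (tr in truth) {
    while (j <= length(detected) && detected[j] < tr - tol) j <- j + 1L
    if (j <= length(detected) && abs(detected[j] - tr) <= tol) {
      matched <- matched + 1L
      j <- j + 1L
    }
  }
  tibble::tibble(
    n_true = length(truth),
    n_detected = length(detected),
    matched = matched,
    sensitivity = if (length(truth)) matched / length(truth) else NA_real_,
    ppv = if (length(detected)) matched / length(detected) else NA_real_
  )
}

#' Write detected peaks as CSV
#'
#' @param peaks Integer vector of R-peak indices.
#' @param fs Sampling rate in Hz.
#' @param path Output path; columns `index` and `time_s`.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, fs, path) {
  readr::write_csv(tibble::tibble(index = as.integer(peaks),
                                  time_s = (peaks - 1) / fs), path)
  invisible(path)
}
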