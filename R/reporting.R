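# Truncate a throughput value toward zero at the precision such figures are
# conventionally printed with: integers at >= 100 bits/s, two decimals in
# [10, 100), one decimal below 10. The quotient is kept exact (integer
# arithmetic) until this final truncation.
truncate_printed <- function(num, den) {
  v <- num / den
  digits <- if (v >= 100) 0L else if (v >= 10) 2L else 1L
  (num * 10^digits) %/% den / 10^digits
}

#' Throughput of the extractor across heart rates
#'
#' Mean per-beat output size and the implied bit rate at given heart rates.
#' `bytes_per_beat` is total bytes over total windows; the bit rate at `R`
#' beats/min is `bytes_per_beat * 8 * R / 60`, truncated at the printed
#' precision after exact rational arithmetic.
#'
#' @param streams A list of `random_stream` objects whose metadata carries
#'   window counts, or a single `random_stream`.
#' @param rates_bpm Heart rates (beats per minute) to report bit rates at.
#' @return An object of class `throughput_report`: `mean_bytes_per_beat`,
#'   `bits_per_second` (tibble of `rate_bpm`, `bits_per_s`),
#'   `per_subject` (tibble of `subject_id`, `n_bytes`, `n_windows`,
#'   `bytes_per_beat`).
#' @export
throughput_report <- function(streams, rates_bpm = c(60, 100)) {
  if (inherits(streams, "random_stream")) streams <- list(streams)
  if (!is.list(streams) || length(streams) == 0L) {
    abort_input("`streams` must be one or more random_stream objects.")
  }
  nb <- vapply(streams, function(s) length(s$bytes), numeric(1))
  nw <- vapply(streams, function(s) {
    w <- s$meta$n_windows
    if (is.null(w) || is.na(w)) NA_real_ else as.numeric(w)
  }, numeric(1))
  if (anyNA(nw) || any(nw <= 0)) {
    abort_input("Every stream needs a positive window count in its metadata.")
  }
  ids <- vapply(streams, function(s) s$meta$subject_id %||% "unknown",
                character(1))
  total_bytes <- sum(nb)
  total_windows <- sum(nw)
  bits <- vapply(rates_bpm, function(r) {
    truncate_printed(total_bytes * 8 * r, 60 * total_windows)
  }, numeric(1))
  structure(
    list(mean_bytes_per_beat = total_bytes / total_windows,
         bits_per_second = tibble::tibble(rate_bpm = rates_bpm,
                                          bits_per_s = bits),
         per_subject = tibble::tibble(subject_id = ids, n_bytes = nb,
                                      n_windows = nw,
                                      bytes_per_beat = nb / nw)),
    class = "throughput_report"
  )
}

#' @export
print.throughput_report <- function(x, ...) {
  cat(sprintf("<throughput_report> %.4g bytes/heart-beat over %d subject(s)\n",
              x$mean_bytes_per_beat, nrow(x$per_subject)))
  for (i in seq_len(nrow(x$bits_per_second))) {
    cat(sprintf("  %g bpm: %g bits/second\n",
                x$bits_per_second$rate_bpm[i], x$bits_per_second$bits_per_s[i]))
  }
  invisible(x)
}

#' @describeIn throughput_report Tidy the per-rate bit rates.
#' @param x A `throughput_report`.
#' @param ... Unused.
#' @export
tidy.throughput_report <- function(x, ...) {
  dplyr::mutate(x$bits_per_second,
                mean_bytes_per_beat = x$mean_bytes_per_beat)
}

#' Plot per-subject extraction efficiency
#'
#' @param object A `throughput_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.throughput_report <- function(object, ...) {
  df <- object$per_subject
  df$subject_id <- factor(df$subject_id, levels = df$subject_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id,
                                   y = .data$bytes_per_beat)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_bytes_per_beat,
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "bytes per heart-beat") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-subject chi-square bias summary
#'
#' Runs the 256-cell chi-square on each subject's stream and summarizes the
#' spread: for an unbiased generator the values scatter around 256 and the
#' interquartile range is narrow.
#'
#' @param streams A list of at least two `random_stream` objects (or byte
#'   vectors), each long enough for [chi_square()].
#' @return An object of class `bias_summary`: `per_subject` (tibble with
#'   `subject_id`, `chi_square`, `exceed_pct`), `q1`, `median`, `q3`, `mean`.
#' @export
bias_summary <- function(streams) {
  if (!is.list(streams) || length(streams) < 2L) {
    abort_input("At least two subject streams are required for a bias summary.")
  }
  ids <- vapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    if (inherits(s, "random_stream")) s$meta$subject_id %||% sprintf("subject-%d", i)
    else sprintf("subject-%d", i)
  }, character(1))
  cs <- lapply(seq_along(streams), function(i) {
    tryCatch(chi_square(streams[[i]]),
             cardiorng_error = function(e) {
               abort_input(sprintf("Subject '%s': %s", ids[i], conditionMessage(e)))
             })
  })
  vals <- vapply(cs, `[[`, numeric(1), "statistic")
  qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(per_subject = tibble::tibble(
           subject_id = ids,
           chi_square = vals,
           exceed_pct = vapply(cs, `[[`, numeric(1), "exceed_pct")),
         q1 = qs[1], median = qs[2], q3 = qs[3], mean = mean(vals)),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "<bias_summary> %d subjects: chi-square mean %.2f, quartiles [%.2f, %.2f, %.2f] (optimal 256)\n",
    nrow(x$per_subject), x$mean, x$q1, x$median, x$q3))
  invisible(x)
}

#' @describeIn bias_summary Tidy the per-subject chi-square values.
#' @param x A `bias_summary`.
#' @param ... Unused.
#' @export
tidy.bias_summary <- function(x, ...) x$per_subject

#' Box plot of per-subject chi-square values
#'
#' @param object A `bias_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_subject,
                  ggplot2::aes(x = "", y = .data$chi_square)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "blue",
                          size = 2) +
    ggplot2::geom_hline(yintercept = 256, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "chi-square (255 df)",
                  title = "Per-subject bias (optimal value 256)")
}

#' Wavelet family / decomposition level experiment matrix
#'
#' Runs the full extraction pipeline and the ENT-style battery over the cross
#' product of wavelet families and decomposition levels, pooling the streams
#' of all supplied records per cell.
#'
#' @param records A list of raw [ecg_record()] objects (or a single record).
#' @param families Character vector of wavelet family names.
#' @param levels Integer vector of decomposition levels.
#' @param pcfg,ecfg Preprocess and extractor configurations.
#' @param discard_each_end Windows discarded at each record end.
#' @return A tibble with one row per (family, level): the six ENT statistics
#'   plus `n_bytes` and `bytes_per_beat`.
#' @export
family_matrix <- function(records,
                          families = WAVELET_FAMILIES,
                          levels = 1:4,
                          pcfg = preprocess_config(),
                          ecfg = extractor_config(),
                          discard_each_end = 50) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (!length(records) || !length(families) || !length(levels)) {
    abort_input("`records`, `families` and `levels` must all be non-empty.")
  }
  # clean and window once; the wavelet stage is the only thing that varies
  prepared <- lapply(records, function(rec) {
    cleaned <- preprocess_ecg(rec, pcfg)
    peaks <- detect_r_peaks(cleaned)
    split_windows(cleaned, peaks, discard_each_end = discard_each_end)
  })
  grid <- tidyr::expand_grid(family = families, level = as.integer(levels))
  rows <- purrr::pmap(grid, function(family, level) {
    wcfg <- wavelet_config(wf = family, L = level)
    streams <- lapply(prepared, extract_stream, wcfg = wcfg, ecfg = ecfg)
    bytes <- unlist(lapply(streams, `[[`, "bytes"), use.names = FALSE)
    nwin <- sum(vapply(streams, function(s) s$meta$n_windows, integer(1)))
    rep_ <- ent_report(bytes)
    dplyr::bind_cols(
      tibble::tibble(family = normalize_family(family), level = level,
                     bytes_per_beat = length(bytes) / nwin),
      glance(rep_)
    )
  })
  dplyr::bind_rows(rows)
}
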