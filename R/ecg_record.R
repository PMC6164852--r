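#' Construct an ECG record
#'
#' An `ecg_record` holds a uniformly sampled single-lead voltage series
#' together with its sampling rate and provenance metadata. Synthetic records
#' additionally carry ground-truth R-peak annotations (1-based sample
#' indices), which real recordings never have.
#'
#' @param samples Numeric vector of voltages in millivolt.
#' @param fs Sampling rate in Hz (must be positive).
#' @param subject_id Opaque label for the source subject.
#' @param annotations Optional integer vector of true R-peak sample indices,
#'   strictly increasing and within `[1, length(samples)]`.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs = 200, subject_id = "anonymous",
                       annotations = NULL) {
  if (length(samples) == 0L || !is.numeric(samples)) {
    abort_input("`samples` must be a non-empty numeric vector.")
  }
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  if (!is.null(annotations)) {
    annotations <- as.integer(annotations)
    if (any(diff(annotations) <= 0L) ||
        any(annotations < 1L) || any(annotations > length(samples))) {
      abort_input("`annotations` must be strictly increasing sample indices inside the record.")
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.character(subject_id), annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject '%s': %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$annotations)) ""
              else sprintf(", %d annotated beats", length(x$annotations))))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Tabulate an ECG record
#'
#' @param x An [ecg_record()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `mV` (and `is_r_peak` when the
#'   record carries annotations).
#' @export
as_tibble.ecg_record <- function(x, ...) {
  out <- tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs,
    mV = x$samples
  )
  if (!is.null(x$annotations)) {
    out$is_r_peak <- FALSE
    out$is_r_peak[x$annotations] <- TRUE
  }
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot an ECG record
#'
#' @param object An [ecg_record()].
#' @param max_seconds Plot at most this many seconds from the start.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, max_seconds = 10, ...) {
  n <- min(length(object$samples), ceiling(max_seconds * object$fs))
  df <- tibble::tibble(
    time_s = (seq_len(n) - 1) / object$fs,
    mV = object$samples[seq_len(n)]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "voltage [mV]",
                  title = sprintf("ECG record '%s'", object$subject_id))
  ann <- object$annotations
  ann <- ann[ann <= n]
  if (length(ann)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time_s = (ann - 1) / object$fs,
                            mV = object$samples[ann]),
      colour = "red", size = 1
    )
  }
  p
}

#' @importFrom rlang .data
NULL

#' Write an ECG record to CSV
#'
#' The file has a header row and two columns, `time_s` and `mV`. When the
#' record carries R-peak annotations they are written next to it as
#' `<path minus .csv>_annotations.csv` with columns `index` and `time_s`.
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path.
#' @param write_annotations Also write the annotation sidecar when present.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, write_annotations = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  df <- tibble::tibble(
    time_s = (seq_along(record$samples) - 1) / record$fs,
    mV = record$samples
  )
  readr::write_csv(df, path)
  if (write_annotations && !is.null(record$annotations)) {
    ann_path <- sub("\\.csv$", "", path)
    ann_path <- paste0(ann_path, "_annotations.csv")
    readr::write_csv(
      tibble::tibble(index = record$annotations,
                     time_s = (record$annotations - 1) / record$fs),
      ann_path
    )
  }
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Expects the two-column format written by [write_ecg_csv()]: a header row
#' followed by `time_s,mV` rows. The sampling rate is inferred from the time
#' column unless given explicitly.
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param subject_id Label for the returned record; defaults to the file name.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) abort_input(sprintf("No such file: '%s'", path))
  raw <- utils::read.csv(path, colClasses = "character")
  if (ncol(raw) < 2L) abort_data("ECG CSV must have columns time_s and mV.")
  num <- suppressWarnings(vapply(raw[[2]], as.numeric, numeric(1),
                                 USE.NAMES = FALSE))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    abort_data(sprintf("Non-numeric sample value at line %d of '%s'.",
                       bad + 1L, path))  # +1 for the header row
  }
  tvec <- suppressWarnings(as.numeric(raw[[1]]))
  if (anyNA(tvec)) {
    bad <- which(is.na(tvec))[1]
    abort_data(sprintf("Non-numeric time value at line %d of '%s'.",
                       bad + 1L, path))
  }
  if (is.null(fs)) {
    dt <- diff(tvec)
    if (length(dt) == 0L || any(dt <= 0)) {
      abort_data("Cannot infer sampling rate from time column.")
    }
    fs <- 1 / stats::median(dt)
    fs <- round(fs, 6)
  }
  ecg_record(num, fs = fs,
             subject_id = subject_id %||% basename(path))
}
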