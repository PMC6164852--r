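stream_bytes <- function(stream) {
  if (inherits(stream, "random_stream")) stream$bytes
  else if (is.numeric(stream)) as.integer(stream)
  else abort_input("Expected a random_stream or an integer vector of bytes.")
}

#' Shannon entropy of a byte stream
#'
#' Empirical entropy over the 256 byte values, in bits per byte. A perfectly
#' uniform source yields 8.
#'
#' @param stream A `random_stream` or integer vector of bytes.
#' @return Entropy in bits per byte, in `[0, 8]`.
#' @export
shannon_entropy <- function(stream) {
  b <- stream_bytes(stream)
  if (length(b) == 0L) abort_input("Empty stream.")
  p <- tabulate(b + 1L, 256L) / length(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Optimum compression percentage
#'
#' The percentage by which an ideal entropy coder could shrink the stream,
#' `floor((8 - entropy) / 8 * 100)`, reported as an integer percent the way
#' the classic byte-stream battery prints it.
#'
#' @param entropy_bits_per_byte Entropy in `[0, 8]`.
#' @return Integer percent.
#' @export
optimum_compression <- function(entropy_bits_per_byte) {
  check_number(entropy_bits_per_byte, "entropy_bits_per_byte", min = 0, max = 8)
  floor((8 - entropy_bits_per_byte) / 8 * 100)
}

# chi-square needs >= 10 expected counts per cell
CHISQ_MIN_BYTES <- 2560L

#' Chi-square uniformity statistic of a byte stream
#'
#' 256-cell goodness-of-fit statistic against the uniform distribution
#' (255 degrees of freedom; expected value 256 for random data) together with
#' the upper-tail exceedance probability: the percentage of the time a truly
#' random sequence would exceed the observed statistic.
#'
#' @param stream A `random_stream` or integer vector of bytes (>= 2560, so
#'   every cell has at least 10 expected counts).
#' @return A list with `statistic` and `exceed_pct`.
#' @export
chi_square <- function(stream) {
  b <- stream_bytes(stream)
  if (length(b) < CHISQ_MIN_BYTES) {
    abort_input(sprintf(
      "Stream of %d bytes is too short for the 256-cell chi-square (minimum %d).",
      length(b), CHISQ_MIN_BYTES))
  }
  obs <- tabulate(b + 1L, 256L)
  expd <- length(b) / 256
  statistic <- sum((obs - expd)^2) / expd
  list(statistic = statistic,
       exceed_pct = pchisq(statistic, df = 255, lower.tail = FALSE) * 100)
}

#' Arithmetic mean of byte values
#'
#' @param stream A `random_stream` or integer vector of bytes.
#' @return The mean; 127.5 for a uniform source.
#' @export
arithmetic_mean <- function(stream) {
  b <- stream_bytes(stream)
  if (length(b) == 0L) abort_input("Empty stream.")
  mean(b)
}

#' Monte-Carlo estimate of pi from a byte stream
#'
#' Consecutive non-overlapping 6-byte groups form a point: the first three
#' bytes are a 24-bit big-endian x coordinate, the next three the
#' y coordinate. A point is inside the quarter circle when
#' `x^2 + y^2 <= (2^24 - 1)^2`, and pi is estimated as four times the inside
#' fraction. Trailing bytes that do not fill a group are ignored.
#'
#' @param stream A `random_stream` or integer vector of bytes (>= 6).
#' @return The pi estimate.
#' @export
monte_carlo_pi <- function(stream) {
  b <- stream_bytes(stream)
  m <- length(b) %/% 6L
  if (m == 0L) abort_input("At least 6 bytes are needed for one Monte-Carlo point.")
  g <- matrix(as.numeric(b[seq_len(6L * m)]), nrow = 6L)
  x <- g[1, ] * 65536 + g[2, ] * 256 + g[3, ]
  y <- g[4, ] * 65536 + g[5, ] * 256 + g[6, ]
  r2 <- (2^24 - 1)^2
  4 * sum(x * x + y * y <= r2) / m
}

#' Serial correlation coefficient of a byte stream
#'
#' Pearson correlation between the byte sequence and its one-step circular
#' shift; near zero for independent bytes.
#'
#' @param stream A `random_stream` or integer vector of bytes (>= 3,
#'   non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
serial_correlation <- function(stream) {
  b <- stream_bytes(stream)
  if (length(b) < 3L) abort_input("At least 3 bytes are needed.")
  if (all(b == b[1])) {
    abort_data("Serial correlation is undefined for a constant stream (zero variance).")
  }
  x <- as.numeric(b)
  cor(x, c(x[-1], x[1]))
}

#' ENT-style randomness report
#'
#' Computes the six classic byte-stream statistics: entropy, optimum
#' compression, chi-square (with exceedance percentage), arithmetic mean,
#' Monte-Carlo pi and serial correlation.
#'
#' @param stream A `random_stream` or integer vector of bytes (long enough
#'   for every statistic, i.e. >= 2560).
#' @return An object of class `ent_report`.
#' @export
ent_report <- function(stream) {
  b <- stream_bytes(stream)
  H <- shannon_entropy(b)
  cs <- chi_square(b)
  structure(
    list(entropy_bits_per_byte = H,
         optimum_compression_pct = optimum_compression(H),
         chi_square = cs$statistic,
         chi_square_exceed_pct = cs$exceed_pct,
         arithmetic_mean = arithmetic_mean(b),
         monte_carlo_pi = monte_carlo_pi(b),
         serial_correlation = serial_correlation(b),
         n_bytes = length(b)),
    class = "ent_report"
  )
}

#' @export
print.ent_report <- function(x, ...) {
  cat(sprintf("ENT-style report over %d bytes\n", x$n_bytes))
  cat(sprintf("  Entropy                  %.6f bits/byte (optimal 8)\n",
              x$entropy_bits_per_byte))
  cat(sprintf("  Optimum compression      %d%%\n", x$optimum_compression_pct))
  cat(sprintf("  Chi square               %.2f (%.2f%%)  (optimal 256)\n",
              x$chi_square, x$chi_square_exceed_pct))
  cat(sprintf("  Arithmetic mean          %.4f (optimal 127.5)\n",
              x$arithmetic_mean))
  cat(sprintf("  Monte Carlo pi           %.9f (pi %.5f)\n",
              x$monte_carlo_pi, pi))
  cat(sprintf("  Serial correlation       %.6f (optimal 0)\n",
              x$serial_correlation))
  invisible(x)
}

#' @describeIn ent_report Tidy the report into one row per statistic with its
#'   optimal value.
#' @param x An `ent_report`.
#' @param ... Unused.
#' @export
tidy.ent_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("entropy_bits_per_byte", "optimum_compression_pct",
                  "chi_square", "chi_square_exceed_pct", "arithmetic_mean",
                  "monte_carlo_pi", "serial_correlation"),
    value = c(x$entropy_bits_per_byte, x$optimum_compression_pct,
              x$chi_square, x$chi_square_exceed_pct, x$arithmetic_mean,
              x$monte_carlo_pi, x$serial_correlation),
    optimal = c(8, 0, 256, NA, 127.5, pi, 0)
  )
}

#' @describeIn ent_report One-row summary suitable for binding across runs.
#' @export
glance.ent_report <- function(x, ...) {
  tibble::tibble(
    n_bytes = x$n_bytes,
    entropy = x$entropy_bits_per_byte,
    compression_pct = x$optimum_compression_pct,
    chi_square = x$chi_square,
    chi_exceed_pct = x$chi_square_exceed_pct,
    mean = x$arithmetic_mean,
    monte_carlo_pi = x$monte_carlo_pi,
    serial_correlation = x$serial_correlation
  )
}
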