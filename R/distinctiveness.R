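#' Binomial probability mass function
#'
#' `p(k) = C(n,k) p^k (1-p)^(n-k)`, the reference model for the Hamming
#' distance between words of two independent uniform bit streams (with
#' `p = 1/2` its mean is `n/2`).
#'
#' @param n Word size in bits.
#' @param p Success probability in `[0, 1]`.
#' @param k Integer count(s) in `[0, n]`.
#' @return Probability (vectorized over `k`).
#' @export
binomial_pmf <- function(n, p, k) {
  check_number(n, "n", min = 1)
  check_number(p, "p", min = 0, max = 1)
  k <- as.integer(k)
  if (any(k < 0L) || any(k > n)) {
    abort_input(sprintf("`k` must lie in [0, %d].", as.integer(n)))
  }
  dbinom(k, size = n, prob = p)
}

# byte -> number of set bits
POPCOUNT <- vapply(0:255, function(v) sum(bitwAnd(v, bitwShiftL(1L, 0:7)) > 0L),
                   integer(1))

#' Pairwise Hamming-distance distribution between streams
#'
#' Streams are truncated to the shortest, grouped into non-overlapping
#' `word_bits`-bit words from the start, and every unordered pair of streams
#' is compared positionally: the histogram of the Hamming distance (popcount
#' of the XOR) over all pairs and word positions is accumulated. For streams
#' from independent uniform sources the distribution follows
#' `Binomial(word_bits, 1/2)` with mean `word_bits / 2`, so distinctiveness
#' holds when no stream predicts another beyond chance.
#'
#' @param streams A list of at least two `random_stream` objects (or integer
#'   byte vectors), each at least one word long after truncation.
#' @param word_bits Word size: 8, 16, 32 or 64.
#' @return An object of class `hamming_report`: `word_bits`, `histogram`
#'   (tibble with `k`, `count`, `expected_pmf`), `mean_k`, `expected_mean`,
#'   `n_pairs`, `n_words`.
#' @export
hamming_distribution <- function(streams, word_bits = 32) {
  if (!is.list(streams) || length(streams) < 2L) {
    abort_input("At least two streams are required for a distinctiveness analysis.")
  }
  if (!word_bits %in% c(8L, 16L, 32L, 64L)) {
    abort_config("`word_bits` must be one of 8, 16, 32, 64.")
  }
  word_bits <- as.integer(word_bits)
  byte_list <- lapply(streams, stream_bytes)
  bpw <- word_bits %/% 8L
  min_len <- min(lengths(byte_list))
  n_words <- min_len %/% bpw
  if (n_words == 0L) {
    abort_input(sprintf(
      "Streams must contain at least one %d-bit word (%d bytes).", word_bits, bpw))
  }
  nb <- n_words * bpw
  byte_list <- lapply(byte_list, function(b) b[seq_len(nb)])
  grp <- rep(seq_len(n_words), each = bpw)
  counts <- integer(word_bits + 1L)
  total_k <- 0
  n_streams <- length(byte_list)
  for (i in seq_len(n_streams - 1L)) {
    for (j in seq.int(i + 1L, n_streams)) {
      bit_diff <- POPCOUNT[bitwXor(byte_list[[i]], byte_list[[j]]) + 1L]
      k <- rowsum(bit_diff, grp, reorder = FALSE)[, 1]
      counts <- counts + tabulate(k + 1L, word_bits + 1L)
      total_k <- total_k + sum(k)
    }
  }
  n_pairs <- n_streams * (n_streams - 1L) / 2L
  structure(
    list(word_bits = as.integer(word_bits),
         histogram = tibble::tibble(
           k = 0:word_bits,
           count = counts,
           expected_pmf = dbinom(0:word_bits, word_bits, 0.5)),
         mean_k = total_k / (n_pairs * n_words),
         expected_mean = word_bits / 2,
         n_pairs = n_pairs,
         n_words = n_words),
    class = "hamming_report"
  )
}

#' @export
print.hamming_report <- function(x, ...) {
  cat(sprintf(
    "<hamming_report> %d-bit words, %d pairs x %d words: mean k = %.4f (expected %g)\n",
    x$word_bits, x$n_pairs, x$n_words, x$mean_k, x$expected_mean))
  invisible(x)
}

#' @describeIn hamming_distribution Tidy the histogram (one row per Hamming
#'   distance, with observed counts and the binomial reference).
#' @param x A `hamming_report`.
#' @param ... Unused.
#' @export
tidy.hamming_report <- function(x, ...) {
  n_total <- sum(x$histogram$count)
  dplyr::mutate(x$histogram,
                observed_pmf = .data$count / n_total,
                expected_count = .data$expected_pmf * n_total)
}

#' Goodness-of-fit of a Hamming histogram to the binomial model
#'
#' Chi-square test of the observed Hamming-distance histogram against
#' `Binomial(word_bits, 1/2)`, pooling tail cells until every expected count
#' is at least five.
#'
#' @param report A `hamming_report`.
#' @return A tibble with `statistic`, `df`, `p_value`, `n_cells`.
#' @export
hamming_gof <- function(report) {
  stopifnot(inherits(report, "hamming_report"))
  obs <- report$histogram$count
  expd <- report$histogram$expected_pmf * sum(obs)
  # pool from both tails until expected >= 5
  lo <- 1L
  hi <- length(obs)
  while (hi > lo + 1L && expd[lo] < 5) {
    obs[lo + 1L] <- obs[lo + 1L] + obs[lo]
    expd[lo + 1L] <- expd[lo + 1L] + expd[lo]
    lo <- lo + 1L
  }
  while (hi > lo + 1L && expd[hi] < 5) {
    obs[hi - 1L] <- obs[hi - 1L] + obs[hi]
    expd[hi - 1L] <- expd[hi - 1L] + expd[hi]
    hi <- hi - 1L
  }
  o <- obs[lo:hi]
  e <- expd[lo:hi]
  statistic <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  tibble::tibble(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 n_cells = length(o))
}

#' Plot a Hamming-distance histogram against the binomial reference
#'
#' @param object A `hamming_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hamming_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_pmf), fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_pmf), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_pmf),
                        colour = "red", size = 0.8) +
    ggplot2::labs(
      x = sprintf("Hamming distance k (%d-bit words)", object$word_bits),
      y = "probability",
      title = sprintf("Observed vs Binomial(%d, 1/2); mean k = %.4f",
                      object$word_bits, object$mean_k))
}
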