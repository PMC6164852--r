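test_that("entropy matches closed forms", {
  expect_identical(shannon_entropy(rep(7L, 100)), 0)
  expect_equal(shannon_entropy(0:255), 8)
  expect_equal(shannon_entropy(rep(c(3L, 200L), 50)), 1)
  expect_error(shannon_entropy(integer(0)), class = "cardiorng_input_error")
})

test_that("optimum compression is the floored percentage of wasted bits", {
  expect_identical(optimum_compression(8), 0)
  expect_identical(optimum_compression(4), 50)
  expect_identical(optimum_compression(7.957724), 0)
  expect_error(optimum_compression(9), class = "cardiorng_param_error")
})

test_that("chi-square agrees with brute-force and the survival-function oracle", {
  # perfect uniformity
  expect_equal(chi_square(rep(0:255, 20))$statistic, 0)
  # two-value stream, validated against a direct 256-cell sum
  b <- rep(c(0L, 1L), 2560)
  got <- chi_square(b)$statistic
  obs <- tabulate(b + 1L, 256L)
  expd <- length(b) / 256
  expect_equal(got, sum((obs - expd)^2 / expd))
  # exceedance percentage against an independent numerical-integration oracle
  ex <- chi_square(ref_bytes(25600, 5))  # statistic in the central range
  oracle <- integrate(function(x) dchisq(x, 255), ex$statistic, Inf,
                      rel.tol = 1e-10)$value * 100
  expect_equal(ex$exceed_pct, oracle, tolerance = 1e-4)
  # a statistic exactly at 255 exceeds in ~48.8% of random sequences
  oracle255 <- integrate(function(x) dchisq(x, 255), 255, Inf,
                         rel.tol = 1e-10)$value * 100
  expect_equal(pchisq(255, 255, lower.tail = FALSE) * 100, oracle255,
               tolerance = 1e-4)
  expect_equal(oracle255, 48.822252, tolerance = 1e-5)
  expect_error(chi_square(0:99), "2560", class = "cardiorng_input_error")
})

test_that("arithmetic mean handles the boundary streams", {
  expect_equal(arithmetic_mean(0:255), 127.5)
  expect_equal(arithmetic_mean(rep(255L, 9)), 255)
  expect_equal(arithmetic_mean(rep(0L, 9)), 0)
})

test_that("Monte-Carlo pi treats 6-byte groups as 24-bit coordinates", {
  expect_equal(monte_carlo_pi(rep(0L, 60)), 4)
  expect_equal(monte_carlo_pi(rep(255L, 60)), 0)
  # trailing remainder bytes are ignored
  expect_equal(monte_carlo_pi(c(rep(0L, 6), 255L, 255L)), 4)
  expect_error(monte_carlo_pi(rep(0L, 5)), class = "cardiorng_input_error")
  # convergence on the reference generator at ~1e6 points
  expect_lt(abs(monte_carlo_pi(ref_bytes(6e6, 17)) - pi), 0.02)
})

test_that("serial correlation matches closed forms and the null bound", {
  expect_equal(serial_correlation(rep(c(0L, 255L), 50)), -1)
  expect_error(serial_correlation(rep(9L, 50)), class = "cardiorng_data_error")
  expect_lt(abs(serial_correlation(ref_bytes(1e6, 23))), 0.005)
})

test_that("the battery behaves as the null model on a reference generator", {
  b <- ref_bytes(1e6, 31)
  r <- ent_report(b)
  expect_gte(r$entropy_bits_per_byte, 7.99)
  expect_identical(r$optimum_compression_pct, 0)
  expect_lt(abs(r$arithmetic_mean - 127.5), 0.25)
  expect_lt(abs(r$serial_correlation), 0.01)
  # chi-square lands in the central range for nearly all seeds
  in_range <- vapply(1:10, function(s) {
    cs <- chi_square(ref_bytes(1e6, 100 + s))$statistic
    cs >= 180 && cs <= 340
  }, logical(1))
  expect_gte(mean(in_range), 0.95)
})

test_that("statistics are order-sensitive exactly where they should be", {
  b <- ref_bytes(6000, 41)
  perm <- withr::with_seed(42, sample(b))
  expect_equal(shannon_entropy(perm), shannon_entropy(b))
  expect_equal(chi_square(perm)$statistic, chi_square(b)$statistic)
  expect_equal(arithmetic_mean(perm), arithmetic_mean(b))
  expect_false(isTRUE(all.equal(serial_correlation(perm), serial_correlation(b))))
  expect_false(isTRUE(all.equal(monte_carlo_pi(perm), monte_carlo_pi(b))))
})

test_that("tidy and glance expose the report as tibbles", {
  r <- ent_report(rep(0:255, 20))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 7L)
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$entropy, 8)
  expect_equal(gl$chi_square, 0)
})
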