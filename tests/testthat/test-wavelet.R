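test_that("filter banks satisfy their structural identities", {
  haar <- make_filter_bank("haar")
  expect_equal(haar$g, c(1, 1) / sqrt(2))
  expect_equal(haar$h, c(-1, 1) / sqrt(2))
  db4 <- make_filter_bank("daubechies-4")
  expect_equal(sum(db4$g), sqrt(2), tolerance = 1e-12)
  for (fam in setdiff(all_families, "biorthogonal-3.3")) {
    fb <- make_filter_bank(fam)
    L <- length(fb$g)
    # high-pass is the alternating-sign reverse of the low-pass
    expect_equal(fb$h, rev(fb$g) * (-1)^seq_len(L), info = fam)
    # orthonormality: even-lag autocorrelation is a unit impulse
    for (lag in seq(0, L - 2, by = 2)) {
      ip <- sum(fb$g[seq_len(L - lag)] * fb$g[seq_len(L - lag) + lag])
      expect_equal(ip, as.numeric(lag == 0), tolerance = 1e-8,
                   info = sprintf("%s lag %d", fam, lag))
    }
  }
  expect_error(make_filter_bank("gaussian"), "upported",
               class = "cardiorng_config_error")
})

test_that("a single analysis step matches closed forms and length laws", {
  haar <- make_filter_bank("haar")
  st <- dwt_step(rep(3.5, 8), haar)
  expect_equal(st$approx, rep(3.5 * sqrt(2), 4))
  expect_equal(st$detail, rep(0, 4))
  # periodization halves (rounding up) for every family
  for (fam in all_families) {
    fb <- make_filter_bank(fam)
    expect_length(dwt_step(rnorm(184), fb)$approx, 92)
    expect_length(dwt_step(rnorm(185), fb)$approx, 93)
  }
  expect_error(dwt_step(1, haar), class = "cardiorng_input_error")
})

test_that("orthogonal families conserve energy (Parseval)", {
  for (fam in setdiff(all_families, "biorthogonal-3.3")) {
    fb <- make_filter_bank(fam)
    # impulse input
    x <- c(1, rep(0, 63))
    st <- dwt_step(x, fb)
    expect_equal(sum(st$approx^2) + sum(st$detail^2), 1, tolerance = 1e-8,
                 info = fam)
    # random input
    withr::with_seed(7, y <- rnorm(128))
    st2 <- dwt_step(y, fb)
    expect_equal(sum(st2$approx^2) + sum(st2$detail^2), sum(y^2),
                 tolerance = 1e-8 * sum(y^2), info = fam)
  }
})

test_that("analysis agrees with the brute-force matrix oracle", {
  withr::with_seed(21, {
    for (fam in all_families) {
      fb <- make_filter_bank(fam)
      for (n in c(8, 9, 16, 23, 31, 64)) {
        x <- rnorm(n)
        got <- dwt_step(x, fb)
        want <- oracle_dwt_step(x, fb)
        expect_equal(got$approx, want$approx, tolerance = 1e-12,
                     info = sprintf("%s n=%d", fam, n))
        expect_equal(got$detail, want$detail, tolerance = 1e-12)
        # multilevel agrees too
        lev <- if (n >= 16) 3L else 2L
        cs <- multilevel_approx(x, wavelet_config(fam, lev))
        expect_equal(cs$approx, oracle_multilevel_approx(x, fb, lev),
                     tolerance = 1e-12, info = sprintf("%s n=%d L=%d", fam, n, lev))
      }
    }
  })
})

test_that("perfect reconstruction holds for every family at < 1e-8", {
  withr::with_seed(13, {
    for (fam in all_families) {
      for (n in c(8, 16, 37, 64, 181, 512)) {
        x <- rnorm(n)
        cs <- multilevel_approx(x, wavelet_config(fam, L = 2))
        xr <- multilevel_reconstruct(cs)
        expect_lt(max(abs(xr - x)), 1e-8)
      }
    }
  })
})

test_that("multilevel approximation follows the iterated count law", {
  fb_cfg <- wavelet_config("daubechies-4", L = 3)
  cs <- multilevel_approx(rnorm(184), fb_cfg)
  expect_length(cs$approx, 23)  # 184 -> 92 -> 46 -> 23
  expect_identical(lengths(cs$details), c(92L, 46L, 23L))
  # N = ceiling(n / 2^L) across lengths and levels
  withr::with_seed(5, {
    for (n in c(16, 100, 145, 200, 257)) {
      for (L in 1:4) {
        cs <- multilevel_approx(rnorm(n), wavelet_config("symlet-4", L))
        expect_length(cs$approx, ceiling(n / 2^L))
      }
    }
  })
  # L = 1 is a single analysis step
  x <- rnorm(64)
  one <- multilevel_approx(x, wavelet_config("haar", 1))
  st <- dwt_step(x, make_filter_bank("haar"))
  expect_equal(one$approx, st$approx)
  expect_equal(one$details[[1]], st$detail)
  expect_error(multilevel_approx(rnorm(8), wavelet_config("haar", 4)),
               class = "cardiorng_input_error")
})

test_that("symmetric extension is available as an alternative boundary rule", {
  fb <- make_filter_bank("daubechies-4")
  st <- dwt_step(rnorm(64), fb, ext_mode = "symmetric")
  expect_length(st$approx, (64 + length(fb$g) - 1) %/% 2)
  cfg <- wavelet_config("daubechies-4", L = 2, ext_mode = "symmetric")
  expect_gt(length(multilevel_approx(rnorm(64), cfg)$approx),
            length(multilevel_approx(rnorm(64), wavelet_config("daubechies-4", 2))$approx))
})
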