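# Decomposition low-pass taps of the supported wavelet families. These are
# the standard published filter coefficients, transcribed at full double
# precision. High-pass and reconstruction taps of the orthogonal families are
# derived from the quadrature-mirror relations.

TAPS_HAAR <- c(0.7071067811865476, 0.7071067811865476)

TAPS_DB4 <- c(
  -0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
  0.7148465705529157, 0.2303778133088965)

TAPS_COIF3 <- c(
  -3.459977319727278e-05, -7.0983302506379e-05, 0.0004662169598204029,
  0.0011175187708306303, -0.0025745176881367972, -0.009007976136730624,
  0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
  -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
  0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
  0.023452696142077168, 0.007782596425672746, -0.003793512864380802)

TAPS_SYM4 <- c(
  -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
  0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
  -0.012603967262037833, 0.0322231006040427)

# 62-tap FIR approximation of the Meyer scaling filter (frequency-sampled
# construction). Only approximately orthogonal as published; see
# refine_orthogonal() below.
TAPS_DMEY_RAW <- c(
  0.0, -1.009999956941423e-12, 8.519459636796214e-09, -1.111944952595278e-08,
  -1.0798819539621958e-08, 6.066975741351135e-08, -1.0866516536735883e-07,
  8.200680650386481e-08, 1.1783004497663934e-07, -5.506340565252278e-07,
  1.1307947017916706e-06, -1.489549216497156e-06, 7.367572885903746e-07,
  3.20544191334478e-06, -1.6312699734552807e-05, 6.554305930575149e-05,
  -0.0006011502343516092, -0.002704672124643725, 0.002202534100911002,
  0.006045814097323304, -0.006387718318497156, -0.011061496392513451,
  0.015270015130934803, 0.017423434103729693, -0.03213079399021176,
  -0.024348745906078023, 0.0637390243228016, 0.030655091960824263,
  -0.13284520043622938, -0.035087555656258346, 0.44459300275757724,
  0.7445855923188063, 0.44459300275757724, -0.035087555656258346,
  -0.13284520043622938, 0.030655091960824263, 0.0637390243228016,
  -0.024348745906078023, -0.03213079399021176, 0.017423434103729693,
  0.015270015130934803, -0.011061496392513451, -0.006387718318497156,
  0.006045814097323304, 0.002202534100911002, -0.002704672124643725,
  -0.0006011502343516092, 6.554305930575149e-05, -1.6312699734552807e-05,
  3.20544191334478e-06, 7.367572885903746e-07, -1.489549216497156e-06,
  1.1307947017916706e-06, -5.506340565252278e-07, 1.1783004497663934e-07,
  8.200680650386481e-08, -1.0866516536735883e-07, 6.066975741351135e-08,
  -1.0798819539621958e-08, -1.111944952595278e-08, 8.519459636796214e-09,
  -1.009999956941423e-12)

# Biorthogonal 3.3 spline pair: analysis and synthesis taps differ.
BIOR33_DEC_LO <- c(
  0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
  0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
  -0.1988737822087165, 0.06629126073623882)
BIOR33_DEC_HI <- c(
  0.0, 0.0, -0.1767766952966369, 0.5303300858899106,
  -0.5303300858899106, 0.1767766952966369, 0.0, 0.0)
BIOR33_REC_LO <- c(
  0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
  0.5303300858899106, 0.1767766952966369, 0.0, 0.0)
BIOR33_REC_HI <- c(
  0.06629126073623882, 0.1988737822087165, -0.15467960838455727,
  -0.9943689110435825, 0.9943689110435825, 0.15467960838455727,
  -0.1988737822087165, -0.06629126073623882)

# quadrature-mirror high-pass: h[j] = (-1)^(j+1) g[L-1-j]
qmf_highpass <- function(g) {
  L <- length(g)
  rev(g) * (-1)^(seq_len(L))
}

# Restore numerical orthogonality of a nearly-orthogonal scaling filter by
# Newton iteration on the spectral normalization G <- G * (3 - A) / 2, where
# A(w) = |G(w)|^2 + |G(w + pi)|^2 is the even-lag autocorrelation polynomial.
# Two steps take the published Meyer approximation from ~2e-3 deviation to
# ~1e-10; the result is truncated at |tap| > 1e-12 with even-parity alignment
# so the filter phase convention is preserved.
refine_orthogonal <- function(g, steps = 2) {
  for (s in seq_len(steps)) {
    L <- length(g)
    acf <- as.numeric(stats::convolve(g, g, type = "open"))  # lags -(L-1)..L-1
    lags <- seq(-(L - 1), L - 1)
    a <- ifelse(lags %% 2 == 0, acf, 0)
    cc <- -a / 2
    cc[L] <- cc[L] + 1.5
    g <- as.numeric(stats::convolve(g, rev(cc), type = "open"))
  }
  keep <- which(abs(g) > 1e-12)
  i0 <- min(keep); i1 <- max(keep)
  if ((i0 - 1L) %% 2L == 1L) i0 <- i0 - 1L
  if ((i1 - i0 + 1L) %% 2L == 1L) i1 <- i1 + 1L
  g[i0:i1]
}

the_dmey_cache <- new.env(parent = emptyenv())

dmey_taps <- function() {
  if (is.null(the_dmey_cache$g)) {
    the_dmey_cache$g <- refine_orthogonal(TAPS_DMEY_RAW)
  }
  the_dmey_cache$g
}

WAVELET_FAMILIES <- c("haar", "daubechies-4", "coiflet-3", "symlet-4",
                      "discrete-meyer", "biorthogonal-3.3")

normalize_family <- function(family_name) {
  aliases <- c(
    haar = "haar", db4 = "daubechies-4", "daubechies-4" = "daubechies-4",
    coif3 = "coiflet-3", "coiflet-3" = "coiflet-3",
    sym4 = "symlet-4", "symlet-4" = "symlet-4",
    dmey = "discrete-meyer", "discrete-meyer" = "discrete-meyer",
    bior3.3 = "biorthogonal-3.3", "biorthogonal-3.3" = "biorthogonal-3.3",
    "biorthogonal-3.x" = "biorthogonal-3.3")
  key <- tolower(as.character(family_name))
  if (!key %in% names(aliases)) {
    abort_config(sprintf(
      "Unknown wavelet family '%s'. Supported families: %s.",
      family_name, paste(WAVELET_FAMILIES, collapse = ", ")))
  }
  unname(aliases[key])
}

#' Build a two-channel analysis/synthesis filter bank
#'
#' Returns the decomposition and reconstruction taps of the requested wavelet
#' family. For orthogonal families the high-pass is the alternating-sign
#' reverse of the low-pass and the reconstruction taps are the time-reversed
#' decomposition taps; the biorthogonal 3.3 spline family carries distinct
#' synthesis taps. The discrete Meyer family uses the published 62-tap FIR
#' approximation refined by spectral-normalization Newton steps so that the
#' filter bank is orthogonal to machine precision (perfect reconstruction
#' error below 1e-8).
#'
#' @param family_name One of `"haar"`, `"daubechies-4"`, `"coiflet-3"`,
#'   `"symlet-4"`, `"discrete-meyer"`, `"biorthogonal-3.3"` (short aliases
#'   `db4`, `coif3`, `sym4`, `dmey`, `bior3.3` are accepted).
#' @return An object of class `filter_bank` with elements `family`, `g`
#'   (low-pass decomposition), `h` (high-pass decomposition), `g_rec`,
#'   `h_rec`, and `orthogonal`.
#' @export
make_filter_bank <- function(family_name) {
  family <- normalize_family(family_name)
  if (family == "biorthogonal-3.3") {
    fb <- list(family = family,
               g = BIOR33_DEC_LO, h = BIOR33_DEC_HI,
               g_rec = BIOR33_REC_LO, h_rec = BIOR33_REC_HI,
               orthogonal = FALSE)
    return(structure(fb, class = "filter_bank"))
  }
  g <- switch(family,
    "haar" = TAPS_HAAR,
    "daubechies-4" = TAPS_DB4,
    "coiflet-3" = TAPS_COIF3,
    "symlet-4" = TAPS_SYM4,
    "discrete-meyer" = dmey_taps())
  h <- qmf_highpass(g)
  structure(
    list(family = family, g = g, h = h, g_rec = rev(g), h_rec = rev(h),
         orthogonal = TRUE),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s: %d taps, %s\n", x$family, length(x$g),
              if (x$orthogonal) "orthogonal" else "biorthogonal"))
  invisible(x)
}

#' Wavelet decomposition configuration
#'
#' @param wf Wavelet family name (see [make_filter_bank()]).
#' @param L Decomposition level, an integer in 1..4 by convention (any
#'   level >= 1 is accepted as long as windows are long enough).
#' @param ext_mode Boundary extension: `"periodization"` (default; each level
#'   yields exactly `ceiling(n/2)` coefficients) or `"symmetric"`.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(wf = "daubechies-4", L = 4,
                           ext_mode = c("periodization", "symmetric")) {
  ext_mode <- match.arg(ext_mode)
  check_number(L, "L", min = 1)
  structure(
    list(wf = normalize_family(wf), L = as.integer(L), ext_mode = ext_mode),
    class = "wavelet_config"
  )
}

mode_code <- function(ext_mode) if (ext_mode == "periodization") 0L else 1L

#' One analysis step of the filter bank
#'
#' Convolves the signal with the low- and high-pass decomposition taps and
#' downsamples by two. Under periodization both outputs have length
#' `ceiling(n/2)` (odd-length inputs are extended by repeating the final
#' sample).
#'
#' @param x Numeric signal of length >= 2.
#' @param fb A [make_filter_bank()] object.
#' @param ext_mode Boundary extension mode.
#' @return A list with numeric vectors `approx` and `detail`.
#' @export
dwt_step <- function(x, fb, ext_mode = "periodization") {
  if (!inherits(fb, "filter_bank")) abort_config("`fb` must be a filter_bank.")
  if (length(x) < 2L) abort_input("Signal must have at least 2 samples.")
  .dwt_step_c(as.numeric(x), fb$g, fb$h, mode_code(match.arg(ext_mode, c("periodization", "symmetric"))))
}

#' One synthesis step (periodization only)
#'
#' Inverts [dwt_step()] for even-length periodized signals using the
#' reconstruction taps.
#'
#' @param approx,detail Coefficient vectors from [dwt_step()].
#' @param fb The same [make_filter_bank()].
#' @param n Length of the reconstructed signal (`2 * length(approx)`).
#' @return Numeric vector of length `n`.
#' @export
idwt_step <- function(approx, detail, fb, n = 2L * length(approx)) {
  if (!inherits(fb, "filter_bank")) abort_config("`fb` must be a filter_bank.")
  .idwt_step_c(as.numeric(approx), as.numeric(detail),
               rev(fb$g_rec), rev(fb$h_rec), as.integer(n))
}

#' Multilevel approximation coefficients of a beat window
#'
#' Applies [dwt_step()] `L` times to successive approximations and returns
#' the level-`L` approximation coefficients (the entropy source of the
#' extractor) together with the per-level detail coefficients, which are kept
#' only so reconstruction can be verified.
#'
#' @param window A numeric vector, or one row of a [split_windows()] result.
#' @param cfg A [wavelet_config()].
#' @return A list of class `coefficient_set`: `approx`, `details` (list,
#'   level 1 first), `n_input`, `cfg`.
#' @export
multilevel_approx <- function(window, cfg = wavelet_config()) {
  x <- if (is.list(window) && !is.null(window$samples)) {
    unlist(window$samples, use.names = FALSE)
  } else {
    as.numeric(window)
  }
  if (!inherits(cfg, "wavelet_config")) abort_config("`cfg` must be a wavelet_config.")
  if (length(x) < 2^cfg$L) {
    abort_input(sprintf(
      "Window of %d samples is too short for a level-%d decomposition (needs >= %d).",
      length(x), cfg$L, 2^cfg$L))
  }
  fb <- make_filter_bank(cfg$wf)
  details <- vector("list", cfg$L)
  cur <- x
  for (lev in seq_len(cfg$L)) {
    st <- .dwt_step_c(cur, fb$g, fb$h, mode_code(cfg$ext_mode))
    details[[lev]] <- st$detail
    cur <- st$approx
  }
  structure(
    list(approx = cur, details = details, n_input = length(x), cfg = cfg),
    class = "coefficient_set"
  )
}

#' Reconstruct a signal from a coefficient set (periodization)
#'
#' Odd-length levels are handled the same way the analysis extends them
#' (repeat the last sample): the even-length extension is reconstructed
#' exactly and truncated, so perfect reconstruction holds for any length.
#'
#' @param cs A `coefficient_set` from [multilevel_approx()] computed with
#'   periodization.
#' @return Numeric vector of length `cs$n_input`.
#' @export
multilevel_reconstruct <- function(cs) {
  stopifnot(inherits(cs, "coefficient_set"))
  if (cs$cfg$ext_mode != "periodization") {
    abort_config("Reconstruction is implemented for periodization only.")
  }
  fb <- make_filter_bank(cs$cfg$wf)
  lens <- integer(cs$cfg$L)
  n <- cs$n_input
  for (lev in seq_len(cs$cfg$L)) {
    lens[lev] <- n
    n <- ceiling(n / 2)
  }
  cur <- cs$approx
  for (lev in rev(seq_len(cs$cfg$L))) {
    ne <- lens[lev] + lens[lev] %% 2L
    cur <- idwt_step(cur, cs$details[[lev]], fb, n = ne)
    cur <- cur[seq_len(lens[lev])]
  }
  cur
}
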