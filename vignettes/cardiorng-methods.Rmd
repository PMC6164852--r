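---
title: "Extracting randomness from the electrocardiogram: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting randomness from the electrocardiogram: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiorng)
```

## The entropy source

A heartbeat is electrically stereotyped — P wave, QRS complex, T wave — but
never identical twice: autonomic regulation jitters the beat-to-beat (RR)
interval, respiration and electrode motion modulate the baseline, and the
sensor adds broadband noise. `cardiorng` treats the fine structure of every
beat as a physical entropy source. The pipeline is:

1. **Cleaning.** Remove the sample mean, then bandpass 0.67–45 Hz with a
   zero-phase filter. The lower cut suppresses respiratory drift, the upper
   cut powerline interference.
2. **Beat windowing.** Detect R peaks; split the record at RR midpoints so
   each window holds one full beat and window length tracks the local RR
   interval. Fifty windows at each end of a record are dropped so transient
   or poorly registered signal never reaches the extractor.
3. **Multilevel DWT.** Iterate the analysis filter bank $(g, h)$ with
   dyadic downsampling $L$ times per window and keep the level-$L$
   approximation coefficients.
4. **Quantization.** Scale each coefficient magnitude by $10^4$, round to an
   integer, keep the 8 least-significant bits.

The low bits of a scaled coefficient sit far below the morphological signal:
they are driven by sensor noise and beat-to-beat physiologic variability,
which is what makes them uniform and unpredictable while the waveform itself
stays perfectly recognizable.

## Why the quantizer works — and its one structural subtlety

Write $T = 2^8/10^4 = 0.0256$ signal units for the quantizer's wrap period:
two coefficients whose magnitudes differ by $T$ produce the same byte. A
byte stream is uniform exactly when the distribution of $|c| \bmod T$ is
flat. Wrapping a distribution with a smooth density of scale $\sigma$ flattens
it at rate $\exp(-2\pi^2\sigma^2/T^2)$, so coefficients only need a spread of
a few cells. Two practical consequences shaped the defaults:

* **Signal scale matters.** Approximation coefficients of a zero-mean,
  bandpassed ECG cluster near zero, and folding $|c|$ leaves a density kink
  at the origin. If the record is stored in millivolt floats (R peak
  $\approx 1$), the coefficient spread in flat segments is only a couple of
  cells and the wrapped distribution measurably tilts toward low bytes.
  Long-term Holter recorders, however, store integer ADC counts at roughly
  5 µV per level — 200 counts/mV — which multiplies the coefficient scale,
  and with it $\sigma/T$, by two orders of magnitude. The synthesizer
  therefore digitizes at `adc_gain_per_mV = 200` by default (set 1 for raw
  millivolt floats; the extraction pipeline itself is scale-agnostic).
* **Bounding the integer by the scale is harmful.** If only the fractional
  part is scaled, $z = \mathrm{round}((|c| \bmod 1)\cdot 10^4) \in
  \{0,\dots,10^4\}$, and since $10^4 = 39 \cdot 256 + 16$ the byte cells are
  hit 40-vs-39 unevenly: an irreducible $+\,{\sim}40$ chi-square excess and
  $-0.19$ mean shift per megabyte *even for perfectly uniform fractions*.
  Scaling the whole magnitude, $z = \mathrm{round}(|c| \cdot 10^4)$, lets
  $z$ range over millions of values and the aliasing vanishes (the integer
  part folds in as $10^4 k \equiv 16k \bmod 256$). The scaled form is the
  default (`extractor_config(frac_mode = "scaled")`); the fractional form is
  retained as `frac_mode = "fractional"` for comparison, as is the
  always-zero 24-bit right-shift reading (`shift24 = TRUE`).

Rounding is round-half-even throughout, so decimal test values such as
$0.9999 \times 10^4$ land on their intended integer rather than one ULP
below. The magnitude $|c|$ is used because the coefficient sign encodes
morphology polarity, not entropy, and signed modular arithmetic is
implementation-defined. Non-finite coefficients abort with the offending
position. The quantizer is deliberately *not* translation invariant —
shifting a window changes its bytes — which is expected and untested.

## Filter design

The cleaning bandpass is realized as a cascade of a 4th-order elliptic
high-pass at 0.67 Hz and a 4th-order elliptic low-pass at 45 Hz
(0.11 dB passband ripple, 18 dB stopband), each applied forward-backward.
Zero phase matters because segmentation takes QRS timing from the filtered
signal. An elliptic design was chosen over the more customary Butterworth
because the contract includes real rejection at 50 Hz with a 45 Hz corner:
a 4th-order zero-phase Butterworth leaves 22% of a 50 Hz tone, while the
elliptic cascade leaves 7% and still keeps band-interior gain above 0.95
(both verified numerically in the tests). A Butterworth realization remains
available via `preprocess_config(filter_type = "butter")`.

Boundary handling: the input is demeaned (DC is outside the passband by
definition and otherwise drives the slow low-cut transient), reflect-padded
by about twelve time constants of the low cut (~3600 samples at 200 Hz),
filtered, and trimmed. Residual edge effects are irrelevant downstream
because the pipeline independently discards 50 windows at each record end.

## R-peak detection and windowing

Detection follows the Pan–Tompkins recipe: five-point derivative, squaring,
150 ms moving-window integration, adaptive signal/noise thresholds with a
0.25 s refractory period and a half-threshold search-back when an expected
beat is missed. Accepted candidates are refined to the local maximum of the
cleaned waveform within ±100 ms. On noiseless synthetic records this
recovers annotated peaks exactly; under white noise at 10% of the R
amplitude, sensitivity and positive predictivity stay above 99% at ±50 ms
(both are tested). Note that *sample-exact* recovery under 10% noise is not
attainable by any argmax rule — the noise standard deviation is comparable
to the peak's curvature per sample — so the fidelity property is stated as
exact recovery in the noiseless case and ±1 sample in 99%+ of beats under
noise.

Windows span midpoint-to-midpoint between adjacent peaks (record edges for
the terminal beats). This tiles the retained region with no gaps or
overlaps, puts exactly one beat in each window, and makes the per-beat byte
count $\lceil m/2^L \rceil$ track the RR interval, consistent with
throughput depending on heart rate. All indices are 1-based inclusive, R's
native convention.

## The wavelet layer

No wavelet package ships with this R stack, and the iterated filter bank is
the heart of the method, so the transform is implemented here (in C++ via
Rcpp) with the standard published taps for Haar, Daubechies-4, Coiflet-3,
Symlet-4, discrete Meyer, and biorthogonal 3.3. For orthogonal families the
high-pass is the alternating-sign reverse of the low-pass and reconstruction
taps are the time-reversed analysis taps; the spline family carries its own
synthesis pair.

Periodization is the default boundary mode: it is the only convention whose
coefficient count is exactly $\lceil m/2 \rceil$ per step, which is what
makes ~23 bytes/beat at 200 Hz and level 3 an identity rather than an
approximation. Odd-length inputs are extended by repeating the last sample;
reconstruction reproduces the extension and truncates, so perfect
reconstruction holds at every length (tested to $<10^{-8}$ against a
brute-force matrix oracle for all six families). Symmetric (half-point)
extension is available as an option for comparison; it emits more
coefficients per window and is not used by the default pipeline.

One numerical construction deserves note: the conventional 62-tap FIR
"discrete Meyer" filter is only approximately orthogonal (its filter bank
reconstructs to ~$10^{-2}$, since the true Meyer filter has infinite
support). The package refines those taps with two Newton steps of the
spectral normalization $G \leftarrow G\,(3 - A)/2$, where $A(\omega) =
|G(\omega)|^2 + |G(\omega+\pi)|^2$, truncating at $|g_j| > 10^{-12}$
(144 taps). The result is orthogonal to ~$10^{-10}$, so the Meyer family
meets the same perfect-reconstruction contract as the rest.

## The synthetic generator: what it does and does not emulate

`synthesize_ecg()` renders each beat as five Gaussian bumps — an ECGSYN-like
sum-of-kernels model whose parameters map one-to-one onto the P, Q, R, S, T
characteristic points (defaults: 0.12, −0.10, 1.00, −0.15, 0.30 mV;
widths 25/10/12/10/45 ms; offsets −170/−26/0/26/240 ms from R). RR
intervals are i.i.d. truncated normal with mean $60/\mathrm{HR}$ and
standard deviation $60 \cdot \mathrm{sd_{HR}}/\mathrm{HR}^2$ (first-order
delta method), truncated to the physiologic 0.3–2.0 s; defaults 75 ± 5 bpm.
Noise comprises a 0.30 Hz baseline sinusoid (0.10 mV), a 50 Hz mains
sinusoid (0.02 mV; set 60 Hz for US mains), and white Gaussian sensor noise
(0.05 mV), with seeded random phases. Samples are digitized at 200 counts/mV
and 200 Hz to match long-term Holter storage. Everything is driven by one
integer seed: identical parameters give bit-identical records, and the true
R-peak indices ride along as annotations.

What this emulates well: beat morphology, heart-rate variability, the two
structured noise bands the preprocessing targets, sensor noise, and the
amplitude scale of stored clinical recordings. What it does not emulate:
arrhythmia and ectopy (the method targets healthy sinus rhythm), multi-lead
geometry, electrode-motion artifacts, heteroscedastic or colored sensor
noise, and long-range heart-rate structure (circadian trends, respiratory
sinus arrhythmia). Passing the null-model tests on synthetic data therefore
shows the pipeline is a sound extractor of its stated noise sources — it
does not certify any particular real recording, whose entropy content must
be judged on real data.

## Evaluation statistics

The six-statistic battery follows the classic byte-stream conventions so
results are comparable with the external binary: entropy over the 256-cell
empirical distribution; optimum compression $\lfloor (8-H)/8 \cdot 100
\rfloor$; the 256-cell chi-square with its upper-tail exceedance probability
(255 degrees of freedom — expected statistic 256 for random data); plain
byte mean (optimal 127.5); Monte-Carlo $\pi$ from non-overlapping 6-byte
points read as two big-endian 24-bit coordinates with inclusive radius
$(2^{24}-1)^2$; and the Pearson correlation between the stream and its
one-step circular shift. The circular shift (rather than a truncated lag)
keeps the two-value alternating stream at exactly $-1$ and is
indistinguishable from the open-ended version at any realistic length.
Degenerate inputs fail loudly: empty streams, streams under 2560 bytes for
the chi-square (10 expected counts per cell), constant streams for the
serial correlation.

Distinctiveness groups equal-truncated streams into non-overlapping
$n$-bit words ($n \in \{8,16,32,64\}$) compared positionally across every
unordered pair of subjects; the Hamming histogram is tested against
$\mathrm{Binomial}(n, 1/2)$ with tail cells pooled to an expected count of
five. Positional alignment from the stream start is the simplest
reproducible convention; word-position correlations within a pair average
out rather than accumulate because independent uniform words are exchangeable.

Throughput keeps the byte/window quotient as exact integer arithmetic and
truncates toward zero only at the printed precision (integers at
≥ 100 bits/s, two decimals in [10, 100), one decimal below 10), so the
conventional table cells (184, 306, 2, 3.3, 8, 13.33 bits/s) are reproduced
exactly rather than re-rounded.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to what the
statistics need rather than more: deterministic identities (throughput,
counts, closed-form streams) run on ~100-beat records in milliseconds;
null-model checks of the full pipeline use 1 MiB of extracted bytes
(about 24 h of synthetic ECG, built as twelve independently seeded 2-h
records — a few dozen seconds of compute), at which point the 3-sigma bands
are ±68 on the chi-square, ±0.22 on the mean, and ±0.01 on Monte-Carlo
$\pi$; distinctiveness uses ten subjects at ~0.1 MB each, i.e. over a
million 32-bit word comparisons. Every random quantity in the package flows
from explicit integer seeds through R's RNG (`withr::with_seed`), so all
results — including the acceptance JSON — are bit-reproducible given the
seed.

## Known limitations

* Randomness quality on *real* ECG depends on the recorder's noise floor and
  gain; the synthetic results bound the method's behavior only under the
  generator's noise model.
* The quantizer's uniformity argument needs coefficient spread of several
  wrap cells ($T = 256/\mathrm{scale}$ signal units). Feeding millivolt
  floats (or any data whose approximation coefficients have sub-$T$ spread)
  biases low bytes; use the digitized scale, or raise `scale`.
* R detection is tuned for 200 Hz adult sinus rhythm; heavily pathological
  rhythms are out of scope.
* No cryptographic post-conditioning is applied — the output is a raw
  entropy stream, not a vetted key-derivation function. External NIST /
  DIEHARDER batteries consume the exported binary streams for certification.
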