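#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render P-QRS-T morphology as sums of Gaussian bumps, one set per beat.
// r_idx is 1-based sample index of each R peak; amp/width/offset are per-wave
// (mV, seconds, seconds relative to R). Waves are evaluated on +/- 4 sigma
// support and accumulated additively, so overlapping beats remain well-defined.
// [[Rcpp::export(name = ".render_beats_c", rng = false)]]
NumericVector render_beats_c(int n, double fs, IntegerVector r_idx,
                             NumericVector amp, NumericVector width,
                             NumericVector offset) {
  NumericVector out(n);
  int nw = amp.size();
  for (int b = 0; b < r_idx.size(); ++b) {
    double rc = (double)(r_idx[b] - 1);  // 0-based sample of R
    for (int w = 0; w < nw; ++w) {
      if (amp[w] == 0.0) continue;
      double c = rc + offset[w] * fs;
      double s = width[w] * fs;
      int lo = (int)std::ceil(c - 4.0 * s);
      int hi = (int)std::floor(c + 4.0 * s);
      if (lo < 0) lo = 0;
      if (hi > n - 1) hi = n - 1;
      for (int i = lo; i <= hi; ++i) {
        double u = (i - c) / s;
        out[i] += amp[w] * std::exp(-0.5 * u * u);
      }
    }
  }
  return out;
}

static inline int mod(int a, int m) {
  int r = a % m;
  return r < 0 ? r + m : r;
}

// One analysis step of the two-channel filter bank.
// mode 0 = periodization: y[k] = sum_j f[j] * x[(2k+1-j) mod n] (x extended by
// repeating the last sample when n is odd); output length ceil(n/2).
// mode 1 = symmetric (half-point) extension; output length floor((n+L-1)/2).
// [[Rcpp::export(name = ".dwt_step_c", rng = false)]]
List dwt_step_c(NumericVector x, NumericVector lo, NumericVector hi, int mode) {
  int n = x.size();
  int L = lo.size();
  if (mode == 0) {
    int ne = n + (n % 2);
    int m = ne / 2;
    NumericVector a(m), d(m);
    for (int k = 0; k < m; ++k) {
      double sa = 0.0, sd = 0.0;
      for (int j = 0; j < L; ++j) {
        int idx = mod(2 * k + 1 - j, ne);
        double v = (idx == n) ? x[n - 1] : x[idx];  // odd-length: repeat last
        sa += lo[j] * v;
        sd += hi[j] * v;
      }
      a[k] = sa;
      d[k] = sd;
    }
    return List::create(_["approx"] = a, _["detail"] = d);
  }
  // symmetric half-point extension: ... x2 x1 | x1 ... xn | xn xn-1 ...
  int m = (n + L - 1) / 2;
  NumericVector a(m), d(m);
  for (int k = 0; k < m; ++k) {
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < L; ++j) {
      int idx = 2 * k + 1 - j;  // index into conceptually extended signal
      // reflect until inside [0, n)
      while (idx < 0 || idx >= n) {
        if (idx < 0) idx = -idx - 1;
        if (idx >= n) idx = 2 * n - idx - 1;
      }
      sa += lo[j] * x[idx];
      sd += hi[j] * x[idx];
    }
    a[k] = sa;
    d[k] = sd;
  }
  return List::create(_["approx"] = a, _["detail"] = d);
}

// Synthesis step for the periodized transform: the adjoint of the analysis
// operator, applied with the (reversed) reconstruction taps.
// [[Rcpp::export(name = ".idwt_step_c", rng = false)]]
NumericVector idwt_step_c(NumericVector a, NumericVector d,
                          NumericVector rlo_rev, NumericVector rhi_rev, int n) {
  int L = rlo_rev.size();
  NumericVector x(n);
  for (int k = 0; k < a.size(); ++k) {
    for (int j = 0; j < L; ++j) {
      int idx = mod(2 * k + 1 - j, n);
      x[idx] += rlo_rev[j] * a[k] + rhi_rev[j] * d[k];
    }
  }
  return x;
}

// Iterated level-L approximation for a batch of windows stored in one
// concatenated vector (starts are 1-based). Returns the concatenated level-L
// approximation coefficients plus the per-window coefficient counts.
// [[Rcpp::export(name = ".multilevel_batch_c", rng = false)]]
List multilevel_batch_c(NumericVector x, IntegerVector starts,
                        IntegerVector lens, NumericVector lo, NumericVector hi,
                        int levels, int mode) {
  int nwin = starts.size();
  IntegerVector counts(nwin);
  std::vector<double> out;
  out.reserve(x.size() / (1 << levels) + nwin * levels);
  std::vector<double> cur, nxt;
  int L = lo.size();
  for (int w = 0; w < nwin; ++w) {
    cur.assign(x.begin() + (starts[w] - 1), x.begin() + (starts[w] - 1) + lens[w]);
    for (int lev = 0; lev < levels; ++lev) {
      int n = cur.size();
      int m;
      if (mode == 0) {
        int ne = n + (n % 2);
        m = ne / 2;
        nxt.assign(m, 0.0);
        for (int k = 0; k < m; ++k) {
          double sa = 0.0;
          for (int j = 0; j < L; ++j) {
            int idx = mod(2 * k + 1 - j, ne);
            sa += lo[j] * ((idx == n) ? cur[n - 1] : cur[idx]);
          }
          nxt[k] = sa;
        }
      } else {
        m = (n + L - 1) / 2;
        nxt.assign(m, 0.0);
        for (int k = 0; k < m; ++k) {
          double sa = 0.0;
          for (int j = 0; j < L; ++j) {
            int idx = 2 * k + 1 - j;
            while (idx < 0 || idx >= n) {
              if (idx < 0) idx = -idx - 1;
              if (idx >= n) idx = 2 * n - idx - 1;
            }
            sa += lo[j] * cur[idx];
          }
          nxt[k] = sa;
        }
      }
      cur.swap(nxt);
    }
    counts[w] = cur.size();
    out.insert(out.end(), cur.begin(), cur.end());
  }
  return List::create(_["approx"] = NumericVector(out.begin(), out.end()),
                      _["counts"] = counts);
}

// Adaptive-threshold scan over the moving-window-integrated energy signal
// (Pan-Tompkins style). Returns 1-based indices of accepted candidate peaks
// in the integrated signal. refr = refractory period in samples; search-back
// at half threshold is applied when more than miss_factor * running RR
// estimate elapses without an accepted peak.
// [[Rcpp::export(name = ".pt_scan_c", rng = false)]]
IntegerVector pt_scan_c(NumericVector integ, int refr, double init_frac,
                        double thr_frac, double miss_factor) {
  int n = integ.size();
  std::vector<int> cand;   // local maxima positions
  std::vector<double> camp;
  for (int i = 1; i + 1 < n; ++i) {
    if (integ[i] > integ[i - 1] && integ[i] >= integ[i + 1]) {
      cand.push_back(i);
      camp.push_back(integ[i]);
    }
  }
  if (cand.empty()) return IntegerVector(0);
  // initialize running signal/noise estimates from the first two seconds
  double spki = 0.0, npki = 0.0;
  int init_end = std::min(n, 2 * refr * 8);  // ~2 s when refr = 0.25 s
  for (int i = 0; i < init_end; ++i) spki = std::max(spki, integ[i]);
  spki *= init_frac;
  if (spki <= 0.0) return IntegerVector(0);
  double thr = npki + thr_frac * (spki - npki);
  std::vector<int> acc;
  double rr_est = 0.0;
  int last = -1;
  size_t last_ci = 0;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int pos = cand[ci];
    double amp = camp[ci];
    if (last >= 0 && pos - last < refr) {
      if (!acc.empty() && amp > integ[acc.back() - 1]) {
        // taller peak inside refractory window: replace
        acc.back() = pos + 1;
        last = pos;
        spki = 0.125 * amp + 0.875 * spki;
        thr = npki + thr_frac * (spki - npki);
        last_ci = ci;
      }
      continue;
    }
    if (amp >= thr) {
      acc.push_back(pos + 1);
      if (last >= 0) {
        double rr = pos - last;
        rr_est = (rr_est == 0.0) ? rr : 0.875 * rr_est + 0.125 * rr;
      }
      last = pos;
      last_ci = ci;
      spki = 0.125 * amp + 0.875 * spki;
    } else {
      npki = 0.125 * amp + 0.875 * npki;
      // search-back: if we have gone too long without a beat, take the
      // tallest skipped candidate above half threshold
      if (last >= 0 && rr_est > 0.0 && pos - last > miss_factor * rr_est) {
        int best = -1;
        double bamp = thr * 0.5;
        for (size_t cj = last_ci + 1; cj <= ci; ++cj) {
          if (cand[cj] - last < refr) continue;
          if (camp[cj] > bamp) {
            bamp = camp[cj];
            best = (int)cj;
          }
        }
        if (best >= 0) {
          acc.push_back(cand[best] + 1);
          double rr = cand[best] - last;
          rr_est = 0.875 * rr_est + 0.125 * rr;
          last = cand[best];
          last_ci = best;
          spki = 0.25 * camp[best] + 0.75 * spki;
        }
      }
    }
    thr = npki + thr_frac * (spki - npki);
  }
  return IntegerVector(acc.begin(), acc.end());
}
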