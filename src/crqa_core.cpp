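#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cross-recurrence metrics computed directly from two scalar window series.
// Embedding, the recurrence matrix and the diagonal/vertical line-structure
// scans all happen here: the permutation-specificity layer calls this once
// per session per permutation, so the whole computation stays in C++.
//
// Conventions (shared with the R reference implementation crqa_metrics()):
//  - rows index series a (child), columns series b (adult);
//  - diagonal lines run along (i+1, j+1), including the main diagonal
//    (no Theiler window: the two series are distinct systems);
//  - vertical lines are runs down a column (i varying, j fixed);
//  - L, Lmax, TT, ENTR, V-ENTR are computed over lines of length >= lmin
//    (resp. vmin); entropies are Shannon entropies in nats.

static void add_run(std::vector<double>& hist, int len) {
  if (len <= 0) return;
  if ((int)hist.size() < len + 1) hist.resize(len + 1, 0.0);
  hist[len] += 1.0;
}

// [[Rcpp::export(name = ".crqa_core")]]
NumericVector crqa_core(NumericVector x, NumericVector y, int m, int tau,
                        double eps, int lmin, int vmin) {
  const int nx = x.size(), ny = y.size();
  const int span = (m - 1) * tau;
  const int nr = nx - span, nc = ny - span;
  if (nr < 1 || ny - span < 1)
    stop("series too short for embedding: need at least %d points", span + 1);

  const double eps2 = eps * eps;
  std::vector<unsigned char> M((size_t)nr * nc);
  double sumM = 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = x[i + k * tau] - y[j + k * tau];
        d2 += d * d;
      }
      const unsigned char hit = d2 <= eps2 ? 1 : 0;
      M[(size_t)j * nr + i] = hit;
      sumM += hit;
    }
  }

  std::vector<double> dhist, vhist;
  // diagonal runs over all nr + nc - 1 diagonals
  for (int d = -(nr - 1); d <= nc - 1; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    for (; i < nr && j < nc; ++i, ++j) {
      if (M[(size_t)j * nr + i]) {
        ++run;
      } else {
        add_run(dhist, run);
        run = 0;
      }
    }
    add_run(dhist, run);
  }
  // vertical runs within each column
  for (int j = 0; j < nc; ++j) {
    int run = 0;
    for (int i = 0; i < nr; ++i) {
      if (M[(size_t)j * nr + i]) {
        ++run;
      } else {
        add_run(vhist, run);
        run = 0;
      }
    }
    add_run(vhist, run);
  }

  auto line_stats = [](const std::vector<double>& hist, int minlen,
                       double& points, double& nlines, double& lmean,
                       double& lmax, double& entr) {
    points = 0.0; nlines = 0.0; lmax = 0.0;
    for (int l = minlen; l < (int)hist.size(); ++l) {
      if (hist[l] > 0) {
        points += (double)l * hist[l];
        nlines += hist[l];
        lmax = l;
      }
    }
    if (nlines > 0) {
      lmean = points / nlines;
      entr = 0.0;
      for (int l = minlen; l < (int)hist.size(); ++l) {
        if (hist[l] > 0) {
          const double p = hist[l] / nlines;
          entr -= p * std::log(p);
        }
      }
    } else {
      lmean = NA_REAL; lmax = NA_REAL; entr = NA_REAL;
    }
  };

  double dpoints, dlines, l_mean, l_max, entr;
  line_stats(dhist, lmin, dpoints, dlines, l_mean, l_max, entr);
  double vpoints, vlines, tt, v_max, v_entr;
  line_stats(vhist, vmin, vpoints, vlines, tt, v_max, v_entr);

  const double denom = (double)nr * (double)nc;
  const double rec = sumM / denom;
  const double det = sumM > 0 ? dpoints / sumM : NA_REAL;
  const double lam = sumM > 0 ? vpoints / sumM : NA_REAL;
  const double det_rec = (sumM > 0 && rec > 0) ? det / rec : NA_REAL;
  const double lam_det = (sumM > 0 && !ISNA(det) && det > 0) ? lam / det
                                                             : NA_REAL;
  const bool unstable = !(rec > 0) || ISNA(det) || !(det > 0);

  return NumericVector::create(
      _["rec"] = rec, _["det"] = det, _["lam"] = lam,
      _["det_rec"] = det_rec, _["lam_det"] = lam_det,
      _["l_mean"] = l_mean, _["l_max"] = l_max, _["tt"] = tt,
      _["entr"] = entr, _["v_entr"] = v_entr,
      _["unstable"] = unstable ? 1.0 : 0.0);
}
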