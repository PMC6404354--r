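#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Positive-unlabelled averaged n-dependence estimator scoring kernel.
//
// For a fixed dependence order `norder`, sums over all size-n parent
// attribute subsets S with delta(x_S) = 1 (the parent tuple occurs in the
// training data) the term
//     P(y, x_S) * prod_{m not in S} P(x_m | y, x_S)
// in log space (log-sum-exp across subsets).
//
// Probabilities are estimated from the PU data under the selected-completely-
// at-random assumption:
//   * positive-class tables come from the labelled rows (m-estimate
//     smoothing, uniform base);
//   * marginal tables come from all rows;
//   * negative-class tables are obtained per conditioning context by
//     mixture inversion  P(v|0) = (P(v) - a P(v|1)) / (1 - a)  at the raw
//     (unsmoothed) level, with the context-specific positive fraction
//     a = alpha P(ctx|1) / P(ctx); negative raw values are clipped to `eps`
//     and the context distribution renormalized, then m-estimate smoothing
//     is applied with effective sample size n_ctx (1 - a).
//
// Returns per-test-row log scores for y = 0 and y = 1 (log-sum-exp over
// subsets), the number of subsets with delta = 1, and the clip count.

static inline double smooth_log(double pseudo_count, double pseudo_n,
                                double m, double arity) {
  double denom = pseudo_n + m;
  if (denom <= 0.0) return R_NegInf;
  double num = pseudo_count + (arity > 0 ? m / arity : 0.0);
  if (num <= 0.0) return R_NegInf;
  return std::log(num) - std::log(denom);
}

// [[Rcpp::export]]
List pande_kernel(IntegerMatrix X, IntegerVector s, IntegerMatrix Xt,
                  IntegerVector arity, int norder, double alpha,
                  double m, double eps) {
  const int n = X.nrow(), k = X.ncol(), t = Xt.nrow();
  if (alpha <= 0.0 || alpha >= 1.0)
    stop("alpha must lie strictly between 0 and 1");
  if (norder > k) stop("dependence order exceeds attribute count");
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (s[i] == 1) ++n1;
  if (n1 == 0) stop("dataset has no labelled positives");

  // attribute value offsets into the stacked value axis
  std::vector<int> off(k + 1, 0);
  for (int j = 0; j < k; ++j) off[j + 1] = off[j] + arity[j];
  const int totb = off[k];

  NumericMatrix run_max(t, 2), run_sum(t, 2);
  std::fill(run_max.begin(), run_max.end(), R_NegInf);
  std::fill(run_sum.begin(), run_sum.end(), 0.0);
  IntegerVector ndelta(t, 0);
  long clip_events = 0;

  // precomputed encoded value offsets (row-major) for fast counting/scoring
  std::vector<int> V((size_t)n * k), Vt((size_t)t * k);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) V[(size_t)i * k + j] = off[j] + X(i, j) - 1;
    for (int i = 0; i < t; ++i) Vt[(size_t)i * k + j] = off[j] + Xt(i, j) - 1;
  }

  // subset enumeration state (lexicographic combinations)
  std::vector<int> comb(std::max(norder, 1));
  for (int j = 0; j < norder; ++j) comb[j] = j;
  bool done = false;

  std::vector<int> cc(n), cct(t);
  std::vector<char> inS(k, 0);
  while (!done) {
    for (int jj = 0; jj < norder; ++jj) inS[comb[jj]] = 1;
    // context size and codes for this subset
    int CS = 1;
    for (int j = 0; j < norder; ++j) CS *= arity[comb[j]];
    if (CS > 1000000) stop("parent context too large");
    std::fill(cc.begin(), cc.end(), 0);
    std::fill(cct.begin(), cct.end(), 0);
    for (int j = 0; j < norder; ++j) {
      const int col = comb[j];
      for (int i = 0; i < n; ++i) cc[i] = cc[i] * arity[col] + (X(i, col) - 1);
      for (int i = 0; i < t; ++i) cct[i] = cct[i] * arity[col] + (Xt(i, col) - 1);
    }

    std::vector<double> cAllS(CS, 0.0), cPosS(CS, 0.0);
    std::vector<double> jointAll((size_t)CS * totb, 0.0);
    std::vector<double> jointPos((size_t)CS * totb, 0.0);
    for (int i = 0; i < n; ++i) {
      const int c = cc[i];
      cAllS[c] += 1.0;
      double *ja = &jointAll[(size_t)c * totb];
      const int *vi = &V[(size_t)i * k];
      if (s[i] == 1) {
        cPosS[c] += 1.0;
        double *jp = &jointPos[(size_t)c * totb];
        for (int j = 0; j < k; ++j) { ja[vi[j]] += 1.0; jp[vi[j]] += 1.0; }
      } else {
        for (int j = 0; j < k; ++j) ja[vi[j]] += 1.0;
      }
    }

    // parent-set joint P(y, x_S): positive from labelled rows, negative by
    // global mixture inversion with clipping and renormalization
    std::vector<double> p0S_raw(CS, 0.0);
    double p0_sum = 0.0;
    for (int c = 0; c < CS; ++c) {
      double pS = cAllS[c] / n;
      double p1 = cPosS[c] / n1;
      double raw = (pS - alpha * p1) / (1.0 - alpha);
      if (raw < 0.0) { raw = eps; ++clip_events; }
      p0S_raw[c] = raw;
      p0_sum += raw;
    }

    // per-context log joint and conditional tables, then score test rows
    std::vector<double> L1(totb), L0(totb);
    std::vector<double> q0(totb);
    std::vector<double> lj1(CS), lj0(CS);
    for (int r = 0; r < t; ++r)
      if (cAllS[cct[r]] > 0.0) ndelta[r] += 1;   // delta(x_S) = 1
    // order test rows by context so each context's tables are built once
    std::vector<int> ord(t);
    for (int r = 0; r < t; ++r) ord[r] = r;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return cct[a] < cct[b];
    });
    int last_ctx = -1;
    for (int rr = 0; rr < t; ++rr) {
      const int r = ord[rr];
      const int c = cct[r];
      if (cAllS[c] <= 0.0) continue;
      if (c != last_ctx) {
        last_ctx = c;
        const double nallc = cAllS[c], n1c = cPosS[c];
        const double pS_raw = nallc / n, p1S_rawv = n1c / n1;
        // joint over (y, x_S)
        double p1S = (cPosS[c] + (norder > 0 ? m / CS : 0.0)) /
                     (n1 + (norder > 0 ? m : 0.0));
        if (norder == 0) p1S = 1.0;  // empty parent tuple
        double p0S;
        if (norder == 0) p0S = 1.0;
        else {
          double p0n = p0S_raw[c] / p0_sum;  // renormalized raw
          double n0 = n * (1.0 - alpha);
          p0S = (n0 * p0n + m / CS) / (n0 + m);
        }
        lj1[c] = std::log(alpha) + std::log(p1S);
        lj0[c] = std::log(1.0 - alpha) + std::log(p0S);
        // context positive fraction
        double a_c = (pS_raw > 0.0) ? alpha * p1S_rawv / pS_raw : 0.0;
        if (a_c > 1.0 - 1e-9) a_c = 1.0 - 1e-9;
        if (a_c < 0.0) a_c = 0.0;
        const double *ja = &jointAll[(size_t)c * totb];
        const double *jp = &jointPos[(size_t)c * totb];
        const double n0c = nallc * (1.0 - a_c);
        for (int j = 0; j < k; ++j) {
          const int b = arity[j];
          // raw conditionals and inversion, per attribute block
          double blk_sum = 0.0;
          for (int v = 0; v < b; ++v) {
            double q = ja[off[j] + v] / nallc;
            double q1 = (n1c > 0.0) ? jp[off[j] + v] / n1c : 0.0;
            double raw = (q - a_c * q1) / (1.0 - a_c);
            if (raw < 0.0) { raw = eps; ++clip_events; }
            q0[off[j] + v] = raw;
            blk_sum += raw;
          }
          for (int v = 0; v < b; ++v) {
            double q0n = (blk_sum > 0.0) ? q0[off[j] + v] / blk_sum : 0.0;
            L0[off[j] + v] = smooth_log(n0c * q0n, n0c, m, b);
            L1[off[j] + v] = smooth_log(jp[off[j] + v], n1c, m, b);
          }
        }
      }
      double t1 = lj1[c], t0 = lj0[c];
      const int *vr = &Vt[(size_t)r * k];
      for (int j = 0; j < k; ++j) {
        if (inS[j]) continue;
        t1 += L1[vr[j]]; t0 += L0[vr[j]];
      }
      // streaming log-sum-exp accumulation
      const double terms[2] = {t0, t1};
      for (int y = 0; y < 2; ++y) {
        const double term = terms[y];
        if (!std::isfinite(term) && term < 0) continue;
        if (term > run_max(r, y)) {
          run_sum(r, y) = run_sum(r, y) *
            std::exp(run_max(r, y) - term) + 1.0;
          run_max(r, y) = term;
        } else {
          run_sum(r, y) += std::exp(term - run_max(r, y));
        }
      }
    }

    // next combination
    for (int jj = 0; jj < norder; ++jj) inS[comb[jj]] = 0;
    if (norder == 0) break;
    int j = norder - 1;
    while (j >= 0 && comb[j] == k - norder + j) --j;
    if (j < 0) done = true;
    else {
      ++comb[j];
      for (int jj = j + 1; jj < norder; ++jj) comb[jj] = comb[jj - 1] + 1;
    }
  }

  NumericMatrix logs(t, 2);
  for (int r = 0; r < t; ++r)
    for (int y = 0; y < 2; ++y)
      logs(r, y) = (run_sum(r, y) > 0.0)
        ? run_max(r, y) + std::log(run_sum(r, y)) : R_NegInf;
  return List::create(_["logs"] = logs, _["ndelta"] = ndelta,
                      _["nclip"] = (double)clip_events);
}
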