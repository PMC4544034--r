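#include <Rcpp.h>
using namespace Rcpp;

// Damped affinity-propagation message passing over a similarity matrix whose
// diagonal already holds the preference. Returns the final responsibility and
// availability matrices plus convergence bookkeeping; exemplar extraction and
// tie handling happen on the R side.
//
// All scans walk columns (contiguous in R's column-major storage): the
// per-row maxima needed by the responsibility update are accumulated across
// column sweeps instead of being computed row by row.
// [[Rcpp::export(name = ".ap_messages")]]
List ap_messages(NumericMatrix s_, double lambda, int max_iter, int conv_iter) {
  const int g = s_.nrow();
  const double keep = lambda, upd = 1.0 - lambda;
  NumericMatrix r_(g, g), a_(g, g);
  const double* s = s_.begin();
  double* r = r_.begin();
  double* a = a_.begin();
  std::vector<double> m1(g), m2(g), cs(g);
  std::vector<int> k1(g);
  std::vector<char> ex_prev(g, 0), ex_cur(g, 0);
  int stable_for = 0, iter = 0;
  bool have_prev = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // pass 1: per-row top-two of (a + s), accumulated column-wise
    std::fill(m1.begin(), m1.end(), R_NegInf);
    std::fill(m2.begin(), m2.end(), R_NegInf);
    for (int k = 0; k < g; ++k) {
      const double* ak = a + (size_t)k * g;
      const double* sk = s + (size_t)k * g;
      for (int i = 0; i < g; ++i) {
        double v = ak[i] + sk[i];
        if (v > m1[i]) { m2[i] = m1[i]; m1[i] = v; k1[i] = k; }
        else if (v > m2[i]) { m2[i] = v; }
      }
    }
    // pass 2: responsibilities r(i,k) = s(i,k) - max_{k' != k}(a + s)(i,k')
    for (int k = 0; k < g; ++k) {
      double* rk = r + (size_t)k * g;
      const double* sk = s + (size_t)k * g;
      for (int i = 0; i < g; ++i) {
        double mx = (k == k1[i]) ? m2[i] : m1[i];
        rk[i] = keep * rk[i] + upd * (sk[i] - mx);
      }
    }
    // pass 3: column sums of max(0, r) with the diagonal kept as r(k,k)
    for (int k = 0; k < g; ++k) {
      const double* rk = r + (size_t)k * g;
      double tot = rk[k];
      for (int i = 0; i < g; ++i)
        if (i != k && rk[i] > 0) tot += rk[i];
      cs[k] = tot;
    }
    // pass 4: availabilities
    //   a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    //   a(k,k) = sum_{i' != k} max(0, r(i',k))
    for (int k = 0; k < g; ++k) {
      double* ak = a + (size_t)k * g;
      const double* rk = r + (size_t)k * g;
      const double csk = cs[k];
      for (int i = 0; i < g; ++i) {
        double an;
        if (i == k) {
          an = csk - rk[k];
        } else {
          an = csk - (rk[i] > 0 ? rk[i] : 0.0);
          if (an > 0) an = 0;
        }
        ak[i] = keep * ak[i] + upd * an;
      }
    }
    // exemplar-set stability (an empty set never counts as stable: under
    // degenerate symmetry the messages keep decaying toward the zero fixed
    // point long after the empty set stops changing)
    bool same = have_prev;
    int n_ex = 0;
    for (int k = 0; k < g; ++k) {
      size_t d = (size_t)k * g + k;
      ex_cur[k] = (r[d] + a[d] > 0) ? 1 : 0;
      n_ex += ex_cur[k];
      if (have_prev && ex_cur[k] != ex_prev[k]) same = false;
    }
    if (same && n_ex > 0) {
      if (++stable_for >= conv_iter) { ++iter; break; }
    } else {
      stable_for = 0;
    }
    std::swap(ex_prev, ex_cur);
    have_prev = true;
  }
  return List::create(_["r"] = r_, _["a"] = a_,
                      _["iterations"] = iter, _["stable_for"] = stable_for);
}
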