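#include <Rcpp.h>
using namespace Rcpp;

// Aggregated ("cohort") engine for the balanced E/I probabilistic
// integrate-and-fire network with zero leak.
//
// With mu = 0 and uniform all-to-all weights (W_EE = W_IE = J,
// W_II = W_EI = -g*J), every neuron that did not fire at step t carries the
// identical membrane potential V(t+1) = J * (nE(t) - g * nI(t)), while
// neurons that fired are reset to 0 by the refractory factor (1 - X).  The
// whole population therefore collapses onto two cohorts (refractory /
// eligible) and one step costs O(1) in N: eligible neurons fire
// independently with probability
//   pi = lam + (1 - lam) * clamp(Gamma * V, 0, 1),
// so per-step spike counts are binomial.  A tracked subset of f*N neurons is
// carried separately (counts always; identities only when a raster is
// recorded) so that subsampled observation is exact, not approximate.
//
// Returns per-step E/I population counts, tracked-subset counts, and
// optionally the tracked binary raster (neurons x steps, raw bytes).
// [[Rcpp::export(name = ".ei_cohort_engine")]]
List ei_cohort_engine(double NE, double NI, double J, double g, double Gamma,
                      double lam, int T, int trE, int trI,
                      bool record_raster) {
  RNGScope scope;
  IntegerVector nE_out(T), nI_out(T), nS_out(T);

  // untracked pools
  double uE = NE - trE, uI = NI - trI;
  double fuE = 0, fuI = 0;     // untracked neurons that fired last step
  int ftE = 0, ftI = 0;        // tracked neurons that fired last step

  int ntr = trE + trI;
  RawMatrix raster = record_raster ? RawMatrix(ntr, T) : RawMatrix(0, 0);
  // tracked state (only needed when identities matter)
  std::vector<char> fired(ntr, 0);
  std::vector<int> pool;
  if (record_raster) pool.reserve(ntr);

  for (int t = 0; t < T; ++t) {
    double nEprev = fuE + ftE, nIprev = fuI + ftI;
    double V = J * (nEprev - g * nIprev);
    double q = Gamma * V;
    if (q < 0) q = 0;
    if (q > 1) q = 1;
    double pi = lam + (1 - lam) * q;

    double newuE = R::rbinom(uE - fuE, pi);
    double newuI = R::rbinom(uI - fuI, pi);
    int newtE = (int)R::rbinom((double)(trE - ftE), pi);
    int newtI = (int)R::rbinom((double)(trI - ftI), pi);

    if (record_raster) {
      // choose which eligible tracked neurons fire, E then I
      for (int type = 0; type < 2; ++type) {
        int lo = type == 0 ? 0 : trE;
        int hi = type == 0 ? trE : ntr;
        int need = type == 0 ? newtE : newtI;
        pool.clear();
        for (int i = lo; i < hi; ++i)
          if (!fired[i]) pool.push_back(i);
        int m = (int)pool.size();
        for (int d = 0; d < need; ++d) {
          int pick = d + (int)(unif_rand() * (m - d));
          if (pick >= m) pick = m - 1;
          std::swap(pool[d], pool[pick]);
        }
        for (int i = lo; i < hi; ++i) fired[i] = 0;
        for (int d = 0; d < need; ++d) {
          fired[pool[d]] = 1;
          raster(pool[d], t) = 1;
        }
      }
    }

    fuE = newuE; fuI = newuI; ftE = newtE; ftI = newtI;
    nE_out[t] = (int)(fuE + ftE);
    nI_out[t] = (int)(fuI + ftI);
    nS_out[t] = ftE + ftI;
  }

  List out = List::create(_["n_e"] = nE_out, _["n_i"] = nI_out,
                          _["n_sampled"] = nS_out);
  if (record_raster) out["raster"] = raster;
  return out;
}

// Ordinal (rank-order) pattern codes for all length-D sliding windows of x.
// Ties are broken by temporal order: the earlier bin gets the lower rank.
// The code is sum_i rank_i * D^i, a bijection from permutations to integers
// in [0, D^D) (only D! of which occur).  has_zero / all_zero flag windows
// that touch, or consist entirely of, subthreshold (zero) bins.
// [[Rcpp::export(name = ".ordinal_codes")]]
List ordinal_codes(NumericVector x, int D) {
  int n = x.size() - D + 1;
  if (n < 1)
    return List::create(_["code"] = IntegerVector(0),
                        _["has_zero"] = LogicalVector(0),
                        _["all_zero"] = LogicalVector(0));
  IntegerVector code(n);
  LogicalVector has_zero(n), all_zero(n);
  std::vector<int> rk(D);
  for (int t = 0; t < n; ++t) {
    int nz = 0;
    for (int i = 0; i < D; ++i) {
      int r = 0;
      double xi = x[t + i];
      if (xi == 0.0) ++nz;
      for (int j = 0; j < D; ++j) {
        if (j == i) continue;
        double xj = x[t + j];
        if (xj < xi || (xj == xi && j < i)) ++r;
      }
      rk[i] = r;
    }
    int c = 0, pw = 1;
    for (int i = 0; i < D; ++i) { c += rk[i] * pw; pw *= D; }
    code[t] = c;
    has_zero[t] = nz > 0;
    all_zero[t] = nz == D;
  }
  return List::create(_["code"] = code, _["has_zero"] = has_zero,
                      _["all_zero"] = all_zero);
}
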