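#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Iterative relaxation core shared by the MinOver and Agmon-Motzkin solvers.
//
// Arguments (all validated on the R side):
//   Smask  M x N stoichiometric matrix with clamped metabolite rows zeroed,
//          so every update automatically conserves clamped potentials.
//   G      N x N Gram matrix crossprod(Smask): after a step along column r0
//          the constraint values change by a multiple of G[, r0], which keeps
//          each iteration O(N) instead of O(M N).
//   sigma  direction per reaction in {-1, 0, +1}; 0 = constraint absent.
//   offset per-reaction constant sigma_r * sum_{i clamped} S[i,r] mu[i]:
//          the (fixed) clamped-metabolite contribution to sigma_r * dG_r.
//   mu0    starting potentials (clamped entries at their fixed values).
//   lam    fixed MinOver step constant (kJ/mol).
//   eps    feasibility margin: satisfied means sigma * dG <= -eps.
//   alpha  relaxation factor in (0, 2) (mode 1 only).
//   max_iters, window  iteration cap and length of the stored r0 tail.
//   mode   0 = MinOver (fixed step), 1 = relaxation (violation-proportional).
//   recompute_every  full O(MN) refresh of the incrementally-updated
//          constraint values, to stop floating-point drift.
//
// Returns status 0 = FEASIBLE, 1 = MAX_ITERS, 2 = stall (least satisfied
// column touches only clamped metabolites, so no update can improve it).
// [[Rcpp::export(name = ".minover_core")]]
List minover_core(NumericMatrix Smask, NumericMatrix G, IntegerVector sigma,
                  NumericVector offset, NumericVector mu0, double lam,
                  double eps, double alpha, double max_iters, int window,
                  int mode, int recompute_every = 8192) {
  const int M = Smask.nrow(), N = Smask.ncol();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(N, R_NegInf);           // sigma_r * dG_r, -Inf if absent
  std::vector<int> constrained;
  constrained.reserve(N);
  for (int r = 0; r < N; ++r)
    if (sigma[r] != 0) constrained.push_back(r);

  auto refresh = [&]() {
    for (int r : constrained) {
      double s = 0.0;
      for (int i = 0; i < M; ++i) s += Smask(i, r) * mu[i];
      v[r] = sigma[r] * s + offset[r];
    }
  };
  refresh();

  std::vector<int> tail;               // circular buffer of r0 (0-based)
  tail.reserve(window > 0 ? window : 1);
  int tail_pos = 0;
  std::vector<double> counts_total(N, 0.0);

  double iters = 0.0;
  int status = 1;
  int since_refresh = 0;
  for (double t = 0.0; ; t += 1.0) {
    // argmax with lowest-index tie break
    int r0 = -1;
    double best = R_NegInf;
    for (int r : constrained)
      if (v[r] > best) { best = v[r]; r0 = r; }
    if (best <= -eps) { status = 0; iters = t; break; }
    if (t >= max_iters) { status = 1; iters = t; break; }

    double nrm2 = G(r0, r0);
    if (nrm2 <= 0.0) { status = 2; iters = t; tail.push_back(r0); break; }

    double coef;  // mu <- mu - coef * sigma_r0 * Smask[, r0]
    if (mode == 0) coef = lam;
    // relaxation aims past the satisfaction threshold (-eps) at -2 eps:
    // with alpha = 1 the constraint lands exactly at -2 eps (at eps = 0,
    // exactly at 0, the classical step), and under-relaxed iterates
    // (alpha < 1), which approach their target only asymptotically, still
    // cross -eps in finitely many visits
    else coef = alpha * (best + 2.0 * eps) / nrm2;

    const double s0 = (double)sigma[r0];
    for (int i = 0; i < M; ++i) {
      double sv = Smask(i, r0);
      if (sv != 0.0) mu[i] -= coef * s0 * sv;
    }
    ++since_refresh;
    if (since_refresh >= recompute_every) {
      refresh();
      since_refresh = 0;
    } else {
      for (int r : constrained)
        v[r] -= coef * s0 * (double)sigma[r] * G(r, r0);
    }

    counts_total[r0] += 1.0;
    if (window > 0) {
      if ((int)tail.size() < window) tail.push_back(r0);
      else { tail[tail_pos] = r0; tail_pos = (tail_pos + 1) % window; }
    }
    if (((long long)t) % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  refresh();  // exact final constraint values
  // unroll circular buffer into chronological order
  std::vector<int> tail_out;
  tail_out.reserve(tail.size());
  if ((int)tail.size() == window && window > 0)
    for (int k = 0; k < window; ++k)
      tail_out.push_back(tail[(tail_pos + k) % window]);
  else
    tail_out = tail;
  for (auto &r : tail_out) ++r;  // 1-based for R

  NumericVector viol(N, NA_REAL);
  for (int r : constrained) viol[r] = v[r];

  return List::create(_["status"] = status,
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["iterations"] = iters,
                      _["tail"] = IntegerVector(tail_out.begin(), tail_out.end()),
                      _["counts_total"] = NumericVector(counts_total.begin(),
                                                        counts_total.end()),
                      _["violations"] = viol);
}
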