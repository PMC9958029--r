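#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- circular binary segmentation ----------------------------------------
//
// Arc statistic: for an arc covering positions i+1..j (0 <= i < j <= n,
// k = j - i, 1 <= k <= n-1) the standardized mean-difference between the
// inside and outside of the arc is
//   Z(i,j) = |mean_in - mean_out| / sqrt(1/k + 1/(n-k)).
// The residual-scale factor is constant over arcs and over label
// permutations, so it cancels from both the argmax and the permutation
// p-value and is omitted.

static double max_arc(const std::vector<double>& S, int n,
                      int* best_i, int* best_j) {
  double best = -1.0;
  int bi = 0, bj = 1;
  const double total = S[n];
  for (int i = 0; i < n; ++i) {
    const double Si = S[i];
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k == n) continue;  // arc == whole segment: no split
      const double sum_in = S[j] - Si;
      const double mean_in = sum_in / k;
      const double mean_out = (total - sum_in) / (n - k);
      const double z = std::fabs(mean_in - mean_out) /
        std::sqrt(1.0 / k + 1.0 / (n - k));
      if (z > best + 1e-12) { best = z; bi = i; bj = j; }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

// One split decision for a single segment of ordered values.
// Permutation null: shuffle the values (R RNG), recompute the max arc
// statistic. Early termination once the exceedance count is large enough
// that p >= alpha is guaranteed (the decision, not the exact p, drives the
// recursion).
// [[Rcpp::export]]
List cpp_cbs_split(NumericVector x, int n_perm, double alpha) {
  const int n = x.size();
  if (n < 2) {
    return List::create(_["i"] = 0, _["j"] = n, _["z"] = 0.0,
                        _["p"] = 1.0, _["accept"] = false);
  }
  std::vector<double> S(n + 1, 0.0);
  for (int g = 0; g < n; ++g) S[g + 1] = S[g] + x[g];
  int bi, bj;
  const double z_obs = max_arc(S, n, &bi, &bj);

  // Curtailed sequential decision: stop as soon as the accept/reject
  // outcome at level alpha is settled.
  //  - reject early once count >= ceil(alpha*(1+n_perm)) (p >= alpha
  //    guaranteed);
  //  - accept early once count is still 0 after m_accept draws, where
  //    (1+0)/(1+m_accept) <= alpha/3 (conservative upper bound on p).
  const int stop_count = (int)std::ceil(alpha * (1 + n_perm));
  int m_accept = (int)std::ceil(3.0 / alpha);
  if (m_accept > n_perm) m_accept = n_perm;
  std::vector<double> perm(x.begin(), x.end());
  std::vector<double> Sp(n + 1, 0.0);
  int count = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle using R's RNG
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    for (int g = 0; g < n; ++g) Sp[g + 1] = Sp[g] + perm[g];
    const double z = max_arc(Sp, n, nullptr, nullptr);
    if (z >= z_obs - 1e-12) ++count;
    ++done;
    if (count >= stop_count) break;
    if (count == 0 && done >= m_accept) break;
  }
  // conservative p when stopped early (decision identical)
  const double p = (1.0 + count) / (1.0 + done);
  const bool accept = count < stop_count &&
    (1.0 + count) / (1.0 + (done < n_perm ? done : n_perm)) < alpha;
  return List::create(_["i"] = bi, _["j"] = bj, _["z"] = z_obs,
                      _["p"] = p, _["accept"] = accept);
}

// ---- permutation Welch t --------------------------------------------------

static inline double welch_t(const double* x, const int* ia, int na,
                             const int* ib, int nb) {
  double sa = 0, sb = 0;
  for (int k = 0; k < na; ++k) sa += x[ia[k]];
  for (int k = 0; k < nb; ++k) sb += x[ib[k]];
  const double ma = sa / na, mb = sb / nb;
  double va = 0, vb = 0;
  for (int k = 0; k < na; ++k) { const double d = x[ia[k]] - ma; va += d * d; }
  for (int k = 0; k < nb; ++k) { const double d = x[ib[k]] - mb; vb += d * d; }
  va /= (na - 1); vb /= (nb - 1);
  const double denom = std::sqrt(va / na + vb / nb);
  const double diff = ma - mb;
  if (denom == 0.0) {
    if (diff == 0.0) return 0.0;
    return diff > 0 ? R_PosInf : R_NegInf;
  }
  return diff / denom;
}

// Sampled permutation Welch t-test for a single gene.
// Returns t_obs and the exceedance count over n_perm label permutations
// drawn with R's RNG; p = (1 + count)/(1 + n_perm) is formed in R.
// [[Rcpp::export]]
List cpp_perm_welch(NumericVector a, NumericVector b, int n_perm) {
  const int na = a.size(), nb = b.size(), n = na + nb;
  std::vector<double> x(n);
  for (int k = 0; k < na; ++k) x[k] = a[k];
  for (int k = 0; k < nb; ++k) x[na + k] = b[k];
  std::vector<int> idx(n);
  for (int k = 0; k < n; ++k) idx[k] = k;
  const double t_obs = welch_t(x.data(), idx.data(), na, idx.data() + na, nb);
  const double abs_obs = std::fabs(t_obs);
  int count = 0;
  for (int bperm = 0; bperm < n_perm; ++bperm) {
    // partial Fisher-Yates: first na entries form group A
    for (int k = 0; k < na; ++k) {
      int r = k + (int)(unif_rand() * (n - k));
      if (r >= n) r = n - 1;
      std::swap(idx[k], idx[r]);
    }
    const double t = welch_t(x.data(), idx.data(), na, idx.data() + na, nb);
    if (std::fabs(t) >= abs_obs - 1e-12) ++count;
  }
  return List::create(_["t"] = t_obs, _["count"] = count);
}

// Gene-wise sampled permutation Welch t against a shared set of label
// permutations. X is genes x cells; ia/ib are 0-based cell indices.
// Returns a genes x 2 matrix: column 1 observed t, column 2 exceedance count.
// [[Rcpp::export]]
NumericMatrix cpp_perm_welch_matrix(NumericMatrix X, IntegerVector ia,
                                    IntegerVector ib, int n_perm) {
  const int ng = X.nrow();
  const int na = ia.size(), nb = ib.size(), n = na + nb;
  std::vector<int> cells(n);
  for (int k = 0; k < na; ++k) cells[k] = ia[k];
  for (int k = 0; k < nb; ++k) cells[na + k] = ib[k];

  NumericMatrix out(ng, 2);
  std::vector<double> xg(n), abs_obs(ng);
  std::vector<std::vector<double>> vals(ng, std::vector<double>(n));
  for (int g = 0; g < ng; ++g) {
    for (int k = 0; k < n; ++k) vals[g][k] = X(g, cells[k]);
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) idx[k] = k;
    const double t = welch_t(vals[g].data(), idx.data(), na,
                             idx.data() + na, nb);
    out(g, 0) = t;
    abs_obs[g] = std::fabs(t);
  }
  std::vector<int> idx(n);
  for (int k = 0; k < n; ++k) idx[k] = k;
  for (int bperm = 0; bperm < n_perm; ++bperm) {
    for (int k = 0; k < na; ++k) {
      int r = k + (int)(unif_rand() * (n - k));
      if (r >= n) r = n - 1;
      std::swap(idx[k], idx[r]);
    }
    for (int g = 0; g < ng; ++g) {
      const double t = welch_t(vals[g].data(), idx.data(), na,
                               idx.data() + na, nb);
      if (std::fabs(t) >= abs_obs[g] - 1e-12) out(g, 1) += 1.0;
    }
  }
  return out;
}
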