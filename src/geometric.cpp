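#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Geometric branch-and-bound over genotype count distributions.
//
// Individuals are pre-sorted by their normalized coordinate, so for any
// count vector c the likelihood-optimal configuration assigns contiguous
// blocks: the first c_0 individuals dosage 0, the next c_1 dosage 1, ...
// (swap argument: crossing assignments can always be uncrossed without
// changing c while increasing the likelihood). The search tree therefore
// runs over prefixes (c_0, ..., c_g) — depth m+1 instead of n.
//
// Node upper bound for a prefix ending at class g with a individuals
// assigned: log n! - sum_{j<=g} log c_j!  (suffix factorials bounded by 1)
//         + sum_{j<=g} c_j log F_j
//         + prefix block log-likelihood
//         + sum over unassigned individuals of max_{j>g} (logL[i][j] + log F_j)
//         - min over suffix counts of sum_{j>g} log c_j!.
// Each unassigned individual contributes exactly one logL term and one
// log F factor to any completion, so taking the per-individual maximum of
// their sum over the still-open classes never falls below any completion;
// the suffix factorial product is smallest when the remaining individuals
// spread evenly over the open classes, giving a closed-form floor. Both
// parts are admissible, so pruning at bound < incumbent preserves
// exactness.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct BnB {
  int n, M; // M = m+1 dosage classes
  std::vector<double> logF;
  std::vector<std::vector<double>> CS;     // CS[g][k] = sum_{i<k} logL[i][g]
  std::vector<std::vector<double>> SUF;    // SUF[g][k] = sum_{i>=k} max_{j>=g} (logL[i][j] + logF[j])
  std::vector<double> lf;                  // lf[k] = lgamma(k+1)
  std::vector<int> kopen;                  // #{j >= g : F_j > 0}
  double prune_below;
  double best_val;
  std::vector<int> best_counts;
  std::vector<int> cur_counts;
  long long leaves;

  double safe_mul(int c, double lF) const {
    if (c == 0) return 0.0;
    return std::isinf(lF) ? NEG_INF : c * lF;
  }

  // smallest achievable sum of log c_j! over k classes holding r items:
  // spread as evenly as possible
  double min_lfact(int r, int k) const {
    if (r == 0) return 0.0;
    if (k <= 0) return 0.0; // unreachable: SUF is -inf in that case
    int fl = r / k, q = r - k * fl;
    return (k - q) * lf[fl] + q * lf[fl + 1];
  }

  // replace best on strictly better value, or on an exact tie when the new
  // counts are lexicographically larger (== lexicographically smallest
  // genotype assignment along the sorted order)
  void consider_leaf(double val) {
    ++leaves;
    if (val == NEG_INF) return;
    if (val > best_val ||
        (val == best_val && !best_counts.empty() &&
         std::lexicographical_compare(best_counts.begin(), best_counts.end(),
                                      cur_counts.begin(), cur_counts.end()))) {
      best_val = val;
      best_counts = cur_counts;
    }
  }

  void search(int g, int a, double mult, double lik) {
    int rem = n - a;
    if (g == M - 1) {
      double val = mult + safe_mul(rem, logF[g]) - lf[rem] + lik +
                   (CS[g][n] - CS[g][a]);
      cur_counts[g] = rem;
      consider_leaf(val);
      return;
    }
    // children: choose c_g = 0..rem; order by bound, best first
    std::vector<int> cs;
    std::vector<double> bnd, mlt, lk;
    cs.reserve(rem + 1);
    for (int c = 0; c <= rem; ++c) {
      double mc = mult + safe_mul(c, logF[g]) - lf[c];
      if (std::isinf(mc)) break; // larger c at this class stays -inf
      double lc = lik + (CS[g][a + c] - CS[g][a]);
      double b = mc + lc + SUF[g + 1][a + c] -
                 min_lfact(rem - c, kopen[g + 1]);
      cs.push_back(c); bnd.push_back(b); mlt.push_back(mc); lk.push_back(lc);
    }
    std::vector<int> ord(cs.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int i, int j) { return bnd[i] > bnd[j]; });
    for (int k : ord) {
      double thr = best_val > prune_below ? best_val : prune_below;
      // tiny slack keeps float rounding in the prefix sums from ever
      // pruning an exact optimum
      if (bnd[k] < thr - 1e-10) break; // sorted: the rest are no better
      cur_counts[g] = cs[k];
      search(g + 1, a + cs[k], mlt[k], lk[k]);
    }
    cur_counts[g] = 0;
  }
};

// [[Rcpp::export(name = ".geometric_bnb")]]
List geometric_bnb(NumericMatrix logL, NumericVector logF,
                   IntegerVector init_counts, double init_val,
                   double prune_below) {
  BnB s;
  s.n = logL.nrow();
  s.M = logL.ncol();
  if (logF.size() != s.M) stop("logF length mismatch");
  s.logF.assign(logF.begin(), logF.end());
  s.prune_below = prune_below;
  s.leaves = 0;

  s.lf.resize(s.n + 1);
  for (int k = 0; k <= s.n; ++k) s.lf[k] = std::lgamma(k + 1.0);

  s.CS.assign(s.M, std::vector<double>(s.n + 1, 0.0));
  for (int g = 0; g < s.M; ++g)
    for (int i = 0; i < s.n; ++i)
      s.CS[g][i + 1] = s.CS[g][i] + logL(i, g);

  s.kopen.assign(s.M + 1, 0);
  for (int g = s.M - 1; g >= 0; --g)
    s.kopen[g] = s.kopen[g + 1] + (std::isinf((double)logF[g]) ? 0 : 1);

  // SUF[g][k]: suffix sums of row-wise maxima of logL + logF over j >= g
  s.SUF.assign(s.M + 1, std::vector<double>(s.n + 1, 0.0));
  std::vector<double> rowmax(s.n, NEG_INF);
  for (int g = s.M - 1; g >= 0; --g) {
    for (int i = 0; i < s.n; ++i) {
      double v = std::isinf((double)logF[g]) ? NEG_INF : logL(i, g) + logF[g];
      rowmax[i] = std::max(rowmax[i], v);
    }
    for (int i = s.n - 1; i >= 0; --i)
      s.SUF[g][i] = s.SUF[g][i + 1] + rowmax[i];
  }

  s.cur_counts.assign(s.M, 0);
  if (init_counts.size() == s.M) {
    s.best_counts.assign(init_counts.begin(), init_counts.end());
    s.best_val = init_val;
  } else {
    s.best_counts.clear();
    s.best_val = NEG_INF;
  }

  double root_mult = s.lf[s.n]; // log n!
  s.search(0, 0, root_mult, 0.0);

  return List::create(_["counts"] = IntegerVector(s.best_counts.begin(),
                                                  s.best_counts.end()),
                      _["log_joint"] = s.best_val,
                      _["leaves"] = (double)s.leaves,
                      _["pruned"] = s.best_val <= prune_below);
}
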