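#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Greedy forward-selection collapsing engine.
//
// For every phenotype column it re-runs the full selection path of a gene:
// base common SNP by maximal simple-regression F on raw minor-allele
// counts, then repeated accretion of the rare variant whose collapsed
// score (indicator / sum / weighted sum over the whole member set)
// maximally increases F, accepting only strict improvements.  The
// returned statistic is |t| = sqrt(F) of the final model.
//
// Rare-variant columns are sparse (few carriers), so candidate scores are
// evaluated through O(#carriers) updates of the running sums of the
// current collapsed score instead of full-length passes.
//
// method: 1 = indicator, 2 = sum, 3 = weighted sum.

namespace {

const double DEGENERATE_F = -1.0;

// F of the simple regression of y on s from accumulated sums.
// sxy = sum s_i (y_i - ybar); Sxx = sum s_i^2 - (sum s_i)^2 / n.
inline double f_from_sums(double sum_s, double sum_ss, double sxy,
                          double Syy, int n) {
  double sxx = sum_ss - sum_s * sum_s / n;
  if (sxx <= 0.0) return DEGENERATE_F;
  double denom = sxx * Syy - sxy * sxy;
  if (denom <= 4.0 * std::numeric_limits<double>::epsilon() * sxx * Syy)
    return R_PosInf;  // perfect fit
  return (n - 2) * sxy * sxy / denom;
}

struct SparseCol {            // one rare variant's effective column
  std::vector<int> idx;       // carrier rows
  std::vector<double> val;    // effective value at carriers
  double sum_v, sum_vv;       // column sums of value and value^2
};

struct GenePrep {
  std::vector<int> common;                  // 0-based columns
  std::vector<int> rare;                    // 0-based columns
  std::vector<SparseCol> rare_eff;
  std::vector<std::vector<double>> base_eff;  // effective base per common
};

struct PathResult {
  int base;                    // 0-based column, -1 if unusable
  std::vector<int> selected;   // accepted rare columns, in order
  std::vector<double> f_trace;
  double stat;                 // sqrt(final F), NA if unusable
};

PathResult run_gene(const GenePrep& gp, const NumericMatrix& G,
                    const std::vector<double>& sy, double Syy,
                    int n, int method,
                    std::vector<double>& acc,      // scratch, length n
                    std::vector<double>& gsy) {    // scratch, per rare
  PathResult res;
  res.base = -1;
  res.stat = NA_REAL;

  // Step 1: base = argmax F over raw common counts, ties -> lowest index.
  double bestF = -1.0;
  int best = -1, best_pos = -1;
  for (size_t c = 0; c < gp.common.size(); ++c) {
    int j = gp.common[c];
    double sum_s = 0.0, sum_ss = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = G(i, j);
      sum_s += g; sum_ss += g * g; sxy += g * sy[i];
    }
    double F = f_from_sums(sum_s, sum_ss, sxy, Syy, n);
    if (F == DEGENERATE_F) continue;
    if (best < 0 || F > bestF) { bestF = F; best = j; best_pos = (int)c; }
  }
  if (best < 0) return res;
  res.base = best;
  res.f_trace.push_back(bestF);

  int nr = (int)gp.rare.size();
  // per-column dot products of effective rare values with centred y
  for (int k = 0; k < nr; ++k) {
    const SparseCol& s = gp.rare_eff[k];
    double d = 0.0;
    for (size_t t = 0; t < s.idx.size(); ++t) d += s.val[t] * sy[s.idx[t]];
    gsy[k] = d;
  }

  // initialise the running collapsed score from the base's effective column
  double accS = 0.0, accSS = 0.0, accSY = 0.0;
  if (method == 1) {
    for (int i = 0; i < n; ++i) {
      double v = G(i, best) > 0.0 ? 1.0 : 0.0;
      acc[i] = v;
      if (v > 0.0) { accS += 1.0; accSY += sy[i]; }
    }
    accSS = accS;
  } else {
    const std::vector<double>& be = gp.base_eff[best_pos];
    for (int i = 0; i < n; ++i) {
      double v = be[i];
      acc[i] = v;
      accS += v; accSS += v * v; accSY += v * sy[i];
    }
  }

  std::vector<char> used(nr, 0);
  double curF = bestF;
  for (;;) {
    double bF = -1.0; int bk = -1;
    double b_sum = 0.0, b_ss = 0.0, b_sxy = 0.0;
    for (int k = 0; k < nr; ++k) {
      if (used[k]) continue;
      const SparseCol& s = gp.rare_eff[k];
      double sum_s, sum_ss, sxy;
      if (method == 1) {
        // OR of carrier indicators: only rows not yet carried change
        double dS = 0.0, dSY = 0.0;
        for (size_t t = 0; t < s.idx.size(); ++t) {
          int i = s.idx[t];
          if (acc[i] == 0.0) { dS += 1.0; dSY += sy[i]; }
        }
        sum_s = accS + dS;
        sum_ss = sum_s;          // 0/1 score
        sxy = accSY + dSY;
      } else {
        double cross = 0.0;      // sum over carriers of acc_i * g_i
        for (size_t t = 0; t < s.idx.size(); ++t)
          cross += acc[s.idx[t]] * s.val[t];
        sum_s = accS + s.sum_v;
        sum_ss = accSS + 2.0 * cross + s.sum_vv;
        sxy = accSY + gsy[k];
      }
      double F = f_from_sums(sum_s, sum_ss, sxy, Syy, n);
      if (F == DEGENERATE_F) continue;
      if (bk < 0 || F > bF) {
        bF = F; bk = k; b_sum = sum_s; b_ss = sum_ss; b_sxy = sxy;
      }
    }
    if (bk < 0 || !(bF > curF)) break;
    const SparseCol& s = gp.rare_eff[bk];
    if (method == 1) {
      for (size_t t = 0; t < s.idx.size(); ++t) acc[s.idx[t]] = 1.0;
    } else {
      for (size_t t = 0; t < s.idx.size(); ++t) acc[s.idx[t]] += s.val[t];
    }
    accS = b_sum; accSS = b_ss; accSY = b_sxy;
    used[bk] = 1;
    curF = bF;
    res.selected.push_back(gp.rare[bk]);
    res.f_trace.push_back(bF);
  }
  res.stat = std::sqrt(curF);
  return res;
}

GenePrep prep_gene(const IntegerVector& common1, const IntegerVector& rare1,
                   const NumericMatrix& G, const NumericVector& weights,
                   int method) {
  int n = G.nrow();
  GenePrep gp;
  gp.common.assign(common1.begin(), common1.end());
  gp.rare.assign(rare1.begin(), rare1.end());
  for (int& j : gp.common) --j;  // 1-based -> 0-based
  for (int& j : gp.rare) --j;
  gp.rare_eff.resize(gp.rare.size());
  for (size_t k = 0; k < gp.rare.size(); ++k) {
    int j = gp.rare[k];
    SparseCol& s = gp.rare_eff[k];
    s.sum_v = s.sum_vv = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = G(i, j);
      if (g == 0.0) continue;
      double v;
      if (method == 1) v = 1.0;
      else if (method == 2) v = g;
      else v = g / weights[j];
      s.idx.push_back(i);
      s.val.push_back(v);
      s.sum_v += v;
      s.sum_vv += v * v;
    }
  }
  if (method != 1) {
    gp.base_eff.resize(gp.common.size(), std::vector<double>(n));
    for (size_t c = 0; c < gp.common.size(); ++c) {
      int j = gp.common[c];
      for (int i = 0; i < n; ++i) {
        double g = G(i, j);
        gp.base_eff[c][i] = (method == 2) ? g : g / weights[j];
      }
    }
  }
  return gp;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fs_stat_matrix(NumericMatrix Y, NumericMatrix G,
                                 List common_idx, List rare_idx,
                                 NumericVector weights, int method) {
  int n = G.nrow();
  if (Y.nrow() != n) stop("Y and G must have the same number of rows");
  int K = common_idx.size();
  int P = Y.ncol();
  NumericMatrix out(K, P);

  std::vector<GenePrep> preps;
  preps.reserve(K);
  size_t max_rare = 0;
  for (int k = 0; k < K; ++k) {
    preps.push_back(prep_gene(common_idx[k], rare_idx[k], G, weights, method));
    max_rare = std::max(max_rare, preps.back().rare.size());
  }

  std::vector<double> sy(n), acc(n), gsy(std::max(max_rare, (size_t)1));
  for (int p = 0; p < P; ++p) {
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += Y(i, p);
    ybar /= n;
    double Syy = 0.0;
    for (int i = 0; i < n; ++i) {
      sy[i] = Y(i, p) - ybar;
      Syy += sy[i] * sy[i];
    }
    for (int k = 0; k < K; ++k) {
      PathResult r = run_gene(preps[k], G, sy, Syy, n, method, acc, gsy);
      out(k, p) = r.stat;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_fs_single(NumericVector y, NumericMatrix G,
                   IntegerVector common_idx, IntegerVector rare_idx,
                   NumericVector weights, int method) {
  int n = G.nrow();
  if (y.size() != n) stop("y and G must agree in length");
  GenePrep gp = prep_gene(common_idx, rare_idx, G, weights, method);
  double ybar = mean(y);
  std::vector<double> sy(n);
  double Syy = 0.0;
  for (int i = 0; i < n; ++i) { sy[i] = y[i] - ybar; Syy += sy[i] * sy[i]; }
  std::vector<double> acc(n), gsy(std::max(gp.rare.size(), (size_t)1));
  PathResult r = run_gene(gp, G, sy, Syy, n,
                          /*method=*/method, acc, gsy);
  IntegerVector sel(r.selected.size());
  for (size_t i = 0; i < r.selected.size(); ++i) sel[i] = r.selected[i] + 1;
  return List::create(
    _["base_variant"] = r.base < 0 ? NA_INTEGER : r.base + 1,
    _["selected_rares"] = sel,
    _["f_trace"] = NumericVector(r.f_trace.begin(), r.f_trace.end()),
    _["fs_stat"] = r.stat);
}
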