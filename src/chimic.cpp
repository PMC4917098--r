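// Grid-search core for MIC computation: equipartitions with atomic ties,
// clump/superclump candidate cuts, the ApproxMaxMI prefix dynamic program,
// and the ChiMIC greedy endpoint insertion with chi-square termination.
//
// Conventions used throughout:
//  * "cut position" p is in count space along an axis's sorted order:
//    p in 1..n-1 splits the first p points from the rest (1-based counts).
//  * points with tied raw values are atomic: no cut may fall between them.
//  * all logarithms are base 2, so mutual information is in bits.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

static inline double xlog2x(double p) {
  return p > 0.0 ? p * std::log2(p) : 0.0;
}

static std::vector<int> stable_order(const NumericVector& v) {
  std::vector<int> idx(v.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Legal cut positions: sorted-order boundaries not splitting tied values.
static std::vector<int> legal_positions(const NumericVector& v,
                                        const std::vector<int>& ord) {
  std::vector<int> legal;
  int n = v.size();
  for (int p = 1; p < n; ++p)
    if (v[ord[p - 1]] != v[ord[p]]) legal.push_back(p);
  return legal;
}

// Snap an ideal (real-valued) count position to the nearest entry of a
// sorted candidate list; ties resolved toward the smaller position.
static int snap_nearest(const std::vector<int>& cand, double ideal) {
  auto it = std::lower_bound(cand.begin(), cand.end(), ideal);
  if (it == cand.begin()) return *it;
  if (it == cand.end()) return cand.back();
  int hi = *it, lo = *(it - 1);
  return (std::fabs(lo - ideal) <= std::fabs(hi - ideal)) ? lo : hi;
}

// Equipartition into r bins: ideal cuts at i*n/r snapped to the nearest
// tie-legal position. Returns a strictly increasing, de-duplicated set, so
// the achieved bin count may be below r when ties coarsen the axis.
static std::vector<int> equip_cut_positions(const NumericVector& v, int r) {
  std::vector<int> ord = stable_order(v);
  std::vector<int> legal = legal_positions(v, ord);
  std::vector<int> cuts;
  if (legal.empty()) return cuts;
  int n = v.size();
  for (int i = 1; i < r; ++i)
    cuts.push_back(snap_nearest(legal, (double)i * n / r));
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  return cuts;
}

// Bin id (0-based) per original point given sorted-order cut positions.
static std::vector<int> assign_bins(const NumericVector& v,
                                    const std::vector<int>& cuts) {
  int n = v.size();
  std::vector<int> ord = stable_order(v);
  std::vector<int> bin(n);
  int b = 0;
  size_t ci = 0;
  for (int i = 0; i < n; ++i) {
    while (ci < cuts.size() && i >= cuts[ci]) {
      ++b;
      ++ci;
    }
    bin[ord[i]] = b;
  }
  return bin;
}

// Clump boundaries: positions (x-order count space) separating maximal runs
// of consecutive points lying in the same y-row. Points tied on x form an
// atom; an atom spanning several rows never merges with its neighbours.
static std::vector<int> clump_positions(const NumericVector& x,
                                        const std::vector<int>& xord,
                                        const std::vector<int>& rows) {
  int n = x.size();
  std::vector<std::pair<int, int>> atoms;  // (end position, row or -1 if mixed)
  int i = 0;
  while (i < n) {
    int j = i, row = rows[xord[i]];
    bool mixed = false;
    while (j + 1 < n && x[xord[j + 1]] == x[xord[i]]) {
      ++j;
      if (rows[xord[j]] != row) mixed = true;
    }
    atoms.push_back(std::make_pair(j + 1, mixed ? -1 : row));
    i = j + 1;
  }
  std::vector<int> bpos;
  for (size_t a = 1; a < atoms.size(); ++a) {
    int prev = atoms[a - 1].second, cur = atoms[a].second;
    if (prev != cur || prev == -1) bpos.push_back(atoms[a - 1].first);
  }
  return bpos;
}

// Superclump coarsening: when more than cap-1 clump boundaries exist, keep
// an equipartition-like subset snapped onto clump boundaries.
static std::vector<int> superclump_positions(const std::vector<int>& cpos,
                                             int n, int cap) {
  if (cap < 1 || (int)cpos.size() <= cap - 1) return cpos;
  std::vector<int> out;
  for (int i = 1; i < cap; ++i)
    out.push_back(snap_nearest(cpos, (double)i * n / cap));
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

// Prefix row counts at each candidate boundary; supports O(rows) evaluation
// of a bin's additive mutual-information contribution
//   g(s, t) = -(m/n) log2(m/n) + sum_rows (c/n) log2(c/n)
// so that I(P;Q) = H(Q) + sum_bins g(bin).
struct PrefixCounts {
  std::vector<int> pos;                 // 0, candidate boundaries..., n
  std::vector<std::vector<int>> cum;    // cumulative row counts at pos
  int n, nrow;
  double HQ;

  double g(int s, int t) const {
    double m = (double)(pos[t] - pos[s]);
    double val = -xlog2x(m / n);
    for (int r = 0; r < nrow; ++r)
      val += xlog2x((double)(cum[t][r] - cum[s][r]) / n);
    return val;
  }
};

static PrefixCounts build_prefix(const std::vector<int>& bpos,
                                 const std::vector<int>& xord,
                                 const std::vector<int>& rows, int n,
                                 int nrow) {
  PrefixCounts pc;
  pc.n = n;
  pc.nrow = nrow;
  pc.pos.push_back(0);
  for (size_t i = 0; i < bpos.size(); ++i) pc.pos.push_back(bpos[i]);
  pc.pos.push_back(n);
  int K = pc.pos.size();
  pc.cum.assign(K, std::vector<int>(nrow, 0));
  std::vector<int> run(nrow, 0);
  int pi = 1;
  for (int i = 0; i < n; ++i) {
    run[rows[xord[i]]]++;
    while (pi < K && pc.pos[pi] == i + 1) pc.cum[pi++] = run;
  }
  pc.HQ = 0.0;
  for (int r = 0; r < nrow; ++r) pc.HQ -= xlog2x((double)run[r] / n);
  return pc;
}

// Dynamic program: I[l] = max mutual information over partitions of the
// candidate intervals into at most l bins, for l = 2..maxbins.
static std::vector<double> dp_optimize(const PrefixCounts& pc, int maxbins) {
  int K = (int)pc.pos.size() - 1;  // atomic intervals available
  int L = std::min(maxbins, K);
  std::vector<std::vector<double>> F(K + 1,
                                     std::vector<double>(L + 1, -1e300));
  for (int t = 1; t <= K; ++t) F[t][1] = pc.g(0, t);
  for (int l = 2; l <= L; ++l)
    for (int t = l; t <= K; ++t) {
      double best = -1e300;
      for (int s = l - 1; s < t; ++s) {
        double v = F[s][l - 1] + pc.g(s, t);
        if (v > best) best = v;
      }
      F[t][l] = best;
    }
  std::vector<double> I(maxbins + 1, 0.0);
  double run = 0.0;
  for (int l = 2; l <= maxbins; ++l) {
    double val = (l <= L) ? F[K][l] + pc.HQ : run;
    run = (l == 2) ? val : std::max(run, val);
    if (run < 0) run = 0.0;  // guard fp round-off on independent data
    I[l] = run;
  }
  return I;
}

// Chi-square statistic on the r x 2 table flanking a candidate endpoint,
// with Yates continuity correction for 2 x 2 tables (|O-E| floored at 0
// after subtracting 0.5, as in stats::chisq.test). Cells with zero expected
// count contribute nothing; df = nrow - 1.
static double flank_chisq(const PrefixCounts& pc, int sL, int t, int sR,
                          bool yates, double* pval) {
  double N = (double)(pc.pos[sR] - pc.pos[sL]);
  double T1 = (double)(pc.pos[t] - pc.pos[sL]);
  double T2 = (double)(pc.pos[sR] - pc.pos[t]);
  double stat = 0.0;
  for (int r = 0; r < pc.nrow; ++r) {
    double f1 = (double)(pc.cum[t][r] - pc.cum[sL][r]);
    double f2 = (double)(pc.cum[sR][r] - pc.cum[t][r]);
    double ni = f1 + f2;
    double e1 = ni * T1 / N, e2 = ni * T2 / N;
    if (e1 > 0) {
      double d = std::fabs(f1 - e1) - (yates ? 0.5 : 0.0);
      if (d < 0) d = 0;
      stat += d * d / e1;
    }
    if (e2 > 0) {
      double d = std::fabs(f2 - e2) - (yates ? 0.5 : 0.0);
      if (d < 0) d = 0;
      stat += d * d / e2;
    }
  }
  *pval = R::pchisq(stat, pc.nrow - 1, 0, 0);
  return stat;
}

// Greedy conditional endpoint insertion: previously accepted cuts stay
// frozen; each step inserts the candidate maximizing total I, and (from the
// second endpoint on) keeps it only if the flanking-column chi-square test
// rejects independence at alpha. Returns I by achieved bin count (2..).
static std::vector<double> chimic_insert(const PrefixCounts& pc, double alpha,
                                         bool test_first,
                                         std::vector<double>* pvals,
                                         std::vector<int>* cutpos) {
  int K = (int)pc.pos.size() - 1;
  std::vector<double> out;
  if (K < 2) return out;
  std::vector<int> active;
  active.push_back(0);
  active.push_back(K);
  double G = pc.g(0, K);
  int m = 0;
  while ((int)active.size() - 1 < K) {
    double bestDelta = -1.0;
    int bestT = -1, bestSL = -1, bestSR = -1;
    for (size_t bi = 0; bi + 1 < active.size(); ++bi) {
      int s = active[bi], e = active[bi + 1];
      if (e - s < 2) continue;
      double gbin = pc.g(s, e);
      for (int t = s + 1; t < e; ++t) {
        double d = pc.g(s, t) + pc.g(t, e) - gbin;
        if (d > bestDelta + 1e-15) {
          bestDelta = d;
          bestT = t;
          bestSL = s;
          bestSR = e;
        }
      }
    }
    if (bestT < 0) break;
    ++m;
    if (m > 1 || test_first) {
      double p;
      flank_chisq(pc, bestSL, bestT, bestSR, pc.nrow == 2, &p);
      if (pvals) pvals->push_back(p);
      if (!(p < alpha)) break;  // endpoint not useful: terminate this sweep
    }
    active.insert(std::upper_bound(active.begin(), active.end(), bestT),
                  bestT);
    G += bestDelta;
    double I = G + pc.HQ;
    if (I < 0) I = 0;
    out.push_back(I);
    if (cutpos) cutpos->push_back(pc.pos[bestT]);
  }
  return out;
}

static int budget_bins(double B, int r, int rounding) {
  double raw = B / r;
  if (rounding == 0) return (int)std::floor(raw);
  if (rounding == 2) return (int)std::ceil(raw);
  return (int)std::floor(raw + 0.5);  // round half up
}

typedef std::map<std::pair<int, int>, double> ScoreMap;

static void record(ScoreMap& M, int nx, int ny, double score) {
  if (score > 1.0) score = 1.0;
  if (score < 0.0) score = 0.0;
  std::pair<int, int> key(nx, ny);
  ScoreMap::iterator it = M.find(key);
  if (it == M.end() || it->second < score) M[key] = score;
}

// One ApproxMaxMI orientation: equipartition rows on yv, DP-optimize
// columns on xv under the per-row column budget.
static void approx_orientation(const NumericVector& xv,
                               const NumericVector& yv, double B, int c,
                               int rounding, bool swapAxes, ScoreMap& M) {
  int n = xv.size();
  int rmax = (int)std::floor(B / 2.0);
  std::vector<int> xord = stable_order(xv);
  for (int r = 2; r <= rmax; ++r) {
    int L = budget_bins(B, r, rounding);
    if (L < 2) continue;
    std::vector<int> ycuts = equip_cut_positions(yv, r);
    int nrow = (int)ycuts.size() + 1;
    if (nrow < 2) continue;
    std::vector<int> rows = assign_bins(yv, ycuts);
    std::vector<int> bpos = clump_positions(xv, xord, rows);
    if (bpos.empty()) continue;
    std::vector<int> spos = superclump_positions(bpos, n, c * L);
    PrefixCounts pc = build_prefix(spos, xord, rows, n, nrow);
    std::vector<double> I = dp_optimize(pc, L);
    for (int l = 2; l <= L; ++l) {
      double score = I[l] / std::log2((double)std::min(l, nrow));
      if (swapAxes)
        record(M, nrow, l, score);
      else
        record(M, l, nrow, score);
    }
  }
}

// One ChiMIC orientation: equipartition rows on yv, greedy chi-square-
// terminated insertion on xv (full clump candidate set, no column budget).
static void chimic_orientation(const NumericVector& xv,
                               const NumericVector& yv, double alpha,
                               int rmax, bool test_first, double B, int c,
                               int rounding, bool swapAxes, ScoreMap& M) {
  int n = xv.size();
  std::vector<int> xord = stable_order(xv);
  for (int r = 2; r <= rmax; ++r) {
    std::vector<int> ycuts = equip_cut_positions(yv, r);
    int nrow = (int)ycuts.size() + 1;
    if (nrow < 2) continue;
    std::vector<int> rows = assign_bins(yv, ycuts);
    std::vector<int> bpos = clump_positions(xv, xord, rows);
    if (bpos.empty()) continue;
    if (c >= 1) {
      int L = budget_bins(B, r, rounding);
      if (L < 2) L = 2;
      bpos = superclump_positions(bpos, n, c * L);
    }
    PrefixCounts pc = build_prefix(bpos, xord, rows, n, nrow);
    std::vector<double> I = chimic_insert(pc, alpha, test_first, 0, 0);
    for (size_t i = 0; i < I.size(); ++i) {
      int l = (int)i + 2;
      double score = I[i] / std::log2((double)std::min(l, nrow));
      if (swapAxes)
        record(M, nrow, l, score);
      else
        record(M, l, nrow, score);
    }
  }
}

static DataFrame map_to_frame(const ScoreMap& M) {
  int k = (int)M.size();
  IntegerVector l(k), r(k);
  NumericVector s(k);
  int i = 0;
  for (ScoreMap::const_iterator it = M.begin(); it != M.end(); ++it, ++i) {
    l[i] = it->first.first;
    r[i] = it->first.second;
    s[i] = it->second;
  }
  return DataFrame::create(Named("nx") = l, Named("ny") = r,
                           Named("score") = s);
}

// [[Rcpp::export(name = ".cpp_cm_approx")]]
DataFrame cpp_cm_approx(NumericVector x, NumericVector y, double B, int c,
                        int rounding) {
  ScoreMap M;
  approx_orientation(x, y, B, c, rounding, false, M);
  approx_orientation(y, x, B, c, rounding, true, M);
  return map_to_frame(M);
}

// [[Rcpp::export(name = ".cpp_cm_chimic")]]
DataFrame cpp_cm_chimic(NumericVector x, NumericVector y, double alpha,
                        int rmax, bool test_first, double B, int c,
                        int rounding) {
  ScoreMap M;
  chimic_orientation(x, y, alpha, rmax, test_first, B, c, rounding, false, M);
  chimic_orientation(y, x, alpha, rmax, test_first, B, c, rounding, true, M);
  return map_to_frame(M);
}

// [[Rcpp::export(name = ".cpp_equip_cuts")]]
IntegerVector cpp_equip_cuts(NumericVector v, int r) {
  std::vector<int> cuts = equip_cut_positions(v, r);
  return wrap(cuts);
}

// [[Rcpp::export(name = ".cpp_assign_bins")]]
IntegerVector cpp_assign_bins(NumericVector v, IntegerVector cuts) {
  std::vector<int> cc(cuts.begin(), cuts.end());
  std::vector<int> bins = assign_bins(v, cc);
  return wrap(bins);
}

// [[Rcpp::export(name = ".cpp_clumps")]]
IntegerVector cpp_clumps(NumericVector x, IntegerVector rows) {
  std::vector<int> rr(rows.begin(), rows.end());
  std::vector<int> xord = stable_order(x);
  std::vector<int> bpos = clump_positions(x, xord, rr);
  return wrap(bpos);
}

// [[Rcpp::export(name = ".cpp_superclumps")]]
IntegerVector cpp_superclumps(IntegerVector cpos, int n, int cap) {
  std::vector<int> cc(cpos.begin(), cpos.end());
  std::vector<int> out = superclump_positions(cc, n, cap);
  return wrap(out);
}

// [[Rcpp::export(name = ".cpp_optimize_x_axis")]]
NumericVector cpp_optimize_x_axis(NumericVector x, IntegerVector rows,
                                  int nrow, int max_bins, int c,
                                  bool use_superclumps) {
  int n = x.size();
  std::vector<int> rr(rows.begin(), rows.end());
  std::vector<int> xord = stable_order(x);
  std::vector<int> bpos = clump_positions(x, xord, rr);
  if (use_superclumps)
    bpos = superclump_positions(bpos, n, c * max_bins);
  PrefixCounts pc = build_prefix(bpos, xord, rr, n, nrow);
  std::vector<double> I = dp_optimize(pc, max_bins);
  NumericVector out(max_bins - 1);
  for (int l = 2; l <= max_bins; ++l) out[l - 2] = I[l];
  return out;
}

// [[Rcpp::export(name = ".cpp_chimic_x_axis")]]
List cpp_chimic_x_axis(NumericVector x, IntegerVector rows, int nrow,
                       double alpha, bool test_first) {
  int n = x.size();
  std::vector<int> rr(rows.begin(), rows.end());
  std::vector<int> xord = stable_order(x);
  std::vector<int> bpos = clump_positions(x, xord, rr);
  PrefixCounts pc = build_prefix(bpos, xord, rr, n, nrow);
  std::vector<double> pvals;
  std::vector<int> cutpos;
  std::vector<double> I = chimic_insert(pc, alpha, test_first, &pvals, &cutpos);
  std::sort(cutpos.begin(), cutpos.end());
  return List::create(Named("I") = wrap(I), Named("cuts") = wrap(cutpos),
                      Named("p_values") = wrap(pvals));
}
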