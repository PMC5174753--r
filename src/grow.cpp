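// Recursive growth of a GUIDE-style cost-sensitive binary classification
// tree.  Split variables are selected by chi-squared curvature tests
// (continuous predictors binned at node-local quartiles) with
// Bonferroni-corrected pairwise interaction tests; splits are univariate
// thresholds, categorical subsets, or bivariate linear combinations searched
// over a fixed grid of directions.  Costs enter as class weights.
//
// Node ids follow the 2t / 2t+1 scheme (root 1); a row routes left iff the
// split condition is satisfied.  Growth runs in C++ because cross-validated
// pruning and the bootstrap refit loop call it thousands of times.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;

// kinds: 0 continuous, 1 ordinal (numeric thresholds on level codes),
//        2 nominal (subset splits)

struct SplitRes {
  bool ok = false;
  int type = 0;  // 1 numeric threshold, 2 categorical subset, 3 linear
  int v1 = -1, v2 = -1;
  double a = 0.0, cut = 0.0;
  std::vector<int> left_levels;  // 1-based level codes routed left
  double reduction = 0.0;        // impurity decrease (parent-normalised)
};

static inline double gini_w(double w0, double w1) {
  double W = w0 + w1;
  if (W <= 0) return 0.0;
  return 2.0 * w0 * w1 / (W * W);
}

// empirical quantile, type 7, on a sorted vector
static double quantile7(const std::vector<double>& s, double p) {
  int m = (int)s.size();
  if (m == 1) return s[0];
  double h = (m - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= m - 1) return s[m - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// same quantile via nth_element on a scratch copy (O(n), no full sort)
static double quantile7_nth(std::vector<double>& scratch, double p) {
  int m = (int)scratch.size();
  if (m == 1) return scratch[0];
  double h = (m - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= m - 1)
    return *std::max_element(scratch.begin(), scratch.end());
  std::nth_element(scratch.begin(), scratch.begin() + lo, scratch.end());
  double vlo = scratch[lo];
  double vhi = *std::min_element(scratch.begin() + lo + 1, scratch.end());
  return vlo + (h - lo) * (vhi - vlo);
}

// Pearson chi-squared p-value for a (bins x 2) weighted table; zero-margin
// rows/columns are dropped from the degrees of freedom.
static double chisq_p(const std::vector<double>& t0,
                      const std::vector<double>& t1) {
  int nb = (int)t0.size();
  double c0 = 0.0, c1 = 0.0;
  int r_nz = 0;
  for (int b = 0; b < nb; b++) {
    c0 += t0[b]; c1 += t1[b];
    if (t0[b] + t1[b] > 0) r_nz++;
  }
  double N = c0 + c1;
  int c_nz = (c0 > 0) + (c1 > 0);
  int df = (r_nz - 1) * (c_nz - 1);
  if (df < 1 || N <= 0) return NA_REAL;
  double stat = 0.0;
  for (int b = 0; b < nb; b++) {
    double rt = t0[b] + t1[b];
    if (rt <= 0) continue;
    double e0 = rt * c0 / N, e1 = rt * c1 / N;
    if (e0 > 0) stat += (t0[b] - e0) * (t0[b] - e0) / e0;
    if (e1 > 0) stat += (t1[b] - e1) * (t1[b] - e1) / e1;
  }
  return R::pchisq(stat, (double)df, 0, 0);
}

// quartile bins (<=4) for continuous values; fewer than 4 distinct values
// get one bin per distinct value; ties go to the lower bin (right-closed).
// `scratch` is a reusable buffer to avoid per-call allocation.
static void bin_quartiles(const std::vector<double>& x, std::vector<int>& bin,
                          int& nb, std::vector<double>& scratch) {
  int n = (int)x.size();
  bin.resize(n);
  // cheap distinct-count probe: collect up to 4 distinct values
  double d[4];
  int nd = 0;
  for (int i = 0; i < n && nd < 4; i++) {
    bool seen = false;
    for (int k = 0; k < nd; k++) if (d[k] == x[i]) { seen = true; break; }
    if (!seen) d[nd++] = x[i];
  }
  if (nd < 4) {
    std::sort(d, d + nd);
    nb = nd;
    for (int i = 0; i < n; i++) {
      int k = 0;
      while (d[k] != x[i]) k++;
      bin[i] = k;
    }
    return;
  }
  scratch = x;
  std::sort(scratch.begin(), scratch.end());
  double br[3] = { quantile7(scratch, 0.25), quantile7(scratch, 0.5),
                   quantile7(scratch, 0.75) };
  double breaks[3];
  int nbk = 0;
  for (double b : br)
    if (nbk == 0 || b > breaks[nbk - 1]) breaks[nbk++] = b;
  nb = nbk + 1;
  for (int i = 0; i < n; i++) {
    int k = 0;
    for (int j = 0; j < nbk; j++) if (breaks[j] < x[i]) k++;
    bin[i] = k;
  }
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;   // 0/1
  const NumericVector& w;   // per-row cost weight
  const IntegerVector& kinds;
  const IntegerVector& nlev;
  int p;
  int min_split, min_leaf, max_depth, inter_topk, n_angles, linear_min_n;
  int inter_min_n;
  double linear_pref, inter_alpha;
  bool do_inter, do_linear;

  std::vector<int> out_id, out_type, out_v1, out_v2, out_pred, out_leaf;
  std::vector<double> out_a, out_cut, out_n0, out_n1, out_w0, out_w1;
  std::vector<std::vector<int>> out_lev;

  // reusable scratch buffers (hot path: thousands of node evaluations)
  std::vector<double> xbuf, qbuf, t0buf, t1buf;
  std::vector<int> binbuf;

  Grower(const NumericMatrix& X_, const IntegerVector& y_,
         const NumericVector& w_, const IntegerVector& kinds_,
         const IntegerVector& nlev_, List opts)
      : X(X_), y(y_), w(w_), kinds(kinds_), nlev(nlev_) {
    p = X.ncol();
    min_split   = as<int>(opts["min_split"]);
    inter_min_n = as<int>(opts["interaction_min_n"]);
    min_leaf    = as<int>(opts["min_leaf"]);
    max_depth   = as<int>(opts["max_depth"]);
    inter_topk  = as<int>(opts["interaction_top_k"]);
    n_angles    = as<int>(opts["n_angles"]);
    linear_min_n = as<int>(opts["linear_min_n"]);
    linear_pref = as<double>(opts["linear_preference"]);
    inter_alpha = as<double>(opts["interaction_alpha"]);
    do_inter    = as<bool>(opts["do_interaction"]);
    do_linear   = as<bool>(opts["do_linear"]);
  }

  double curvature_p(int j, const std::vector<int>& rows) {
    int n = (int)rows.size();
    if (kinds[j] == 0) {
      xbuf.resize(n);
      for (int i = 0; i < n; i++) xbuf[i] = X(rows[i], j);
      int nb;
      bin_quartiles(xbuf, binbuf, nb, qbuf);
      t0buf.assign(nb, 0.0); t1buf.assign(nb, 0.0);
      for (int i = 0; i < n; i++) {
        if (y[rows[i]] == 1) t1buf[binbuf[i]] += w[rows[i]];
        else t0buf[binbuf[i]] += w[rows[i]];
      }
    } else {
      int nb = nlev[j];
      t0buf.assign(nb, 0.0); t1buf.assign(nb, 0.0);
      for (int i = 0; i < n; i++) {
        int b = (int)X(rows[i], j) - 1;
        if (y[rows[i]] == 1) t1buf[b] += w[rows[i]];
        else t0buf[b] += w[rows[i]];
      }
    }
    return chisq_p(t0buf, t1buf);
  }

  // coarse 2-level binning of a variable for interaction tests; returns
  // false when the binning is degenerate at this node
  bool coarse_bin(int j, const std::vector<int>& rows, std::vector<int>& b) {
    int n = (int)rows.size();
    b.resize(n);
    if (kinds[j] != 2) {
      xbuf.resize(n);
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < n; i++) {
        xbuf[i] = X(rows[i], j);
        if (xbuf[i] < mn) mn = xbuf[i];
        if (xbuf[i] > mx) mx = xbuf[i];
      }
      if (mn == mx) return false;
      qbuf = xbuf;
      double med = quantile7_nth(qbuf, 0.5);
      bool any1 = false, any0 = false;
      for (int i = 0; i < n; i++) {
        b[i] = xbuf[i] <= med ? 0 : 1;
        (b[i] ? any1 : any0) = true;
      }
      return any1 && any0;
    }
    int L = nlev[j];
    if (L == 2) {
      bool a0 = false, a1 = false;
      for (int i = 0; i < n; i++) {
        b[i] = (int)X(rows[i], j) - 1;
        (b[i] ? a1 : a0) = true;
      }
      return a0 && a1;
    }
    // >2 levels: group by level class-1 weighted share vs the node share
    std::vector<double> lw0(L, 0.0), lw1(L, 0.0);
    double W0 = 0.0, W1 = 0.0;
    for (int i = 0; i < n; i++) {
      int l = (int)X(rows[i], j) - 1;
      if (y[rows[i]] == 1) { lw1[l] += w[rows[i]]; W1 += w[rows[i]]; }
      else { lw0[l] += w[rows[i]]; W0 += w[rows[i]]; }
    }
    double pnode = W1 / (W0 + W1);
    bool a0 = false, a1 = false;
    for (int i = 0; i < n; i++) {
      int l = (int)X(rows[i], j) - 1;
      double pl = (lw0[l] + lw1[l]) > 0 ? lw1[l] / (lw0[l] + lw1[l]) : 0.0;
      b[i] = pl > pnode ? 1 : 0;
      (b[i] ? a1 : a0) = true;
    }
    return a0 && a1;
  }

  double interaction_p(int j, int k, const std::vector<int>& rows) {
    std::vector<int> bj, bk;
    if (!coarse_bin(j, rows, bj) || !coarse_bin(k, rows, bk)) return NA_REAL;
    return interaction_p_binned(bj, bk, rows);
  }

  double interaction_p_binned(const std::vector<int>& bj,
                              const std::vector<int>& bk,
                              const std::vector<int>& rows) {
    std::vector<double> t0(4, 0.0), t1(4, 0.0);
    for (size_t i = 0; i < rows.size(); i++) {
      int cell = bj[i] * 2 + bk[i];
      if (y[rows[i]] == 1) t1[cell] += w[rows[i]];
      else t0[cell] += w[rows[i]];
    }
    return chisq_p(t0, t1);
  }

  // best threshold split on a numeric score; returns cut + reduction
  bool best_threshold(const std::vector<double>& v,
                      const std::vector<int>& rows,
                      double& cut, double& red) {
    int n = (int)rows.size();
    // value + class-signed weight pairs, sorted together (cache-friendly)
    std::vector<std::pair<double, double>> vw(n);
    double W0 = 0.0, W1 = 0.0;
    for (int i = 0; i < n; i++) {
      int r = rows[i];
      double wr = w[r];
      if (y[r] == 1) { W1 += wr; vw[i] = { v[i], wr }; }
      else { W0 += wr; vw[i] = { v[i], -wr }; }
    }
    std::sort(vw.begin(), vw.end());
    double W = W0 + W1, gp = gini_w(W0, W1);
    double lw0 = 0.0, lw1 = 0.0;
    bool found = false;
    double best = -1.0;
    for (int i = 0; i < n - 1; i++) {
      double s = vw[i].second;
      if (s > 0) lw1 += s; else lw0 -= s;
      if (vw[i].first == vw[i + 1].first) continue;  // not between distinct
      int ln = i + 1;
      if (ln < min_leaf || (n - ln) < min_leaf) continue;
      double g = (lw0 + lw1) / W * gini_w(lw0, lw1) +
                 (W0 - lw0 + W1 - lw1) / W * gini_w(W0 - lw0, W1 - lw1);
      double r2 = gp - g;
      if (r2 > best + 1e-12) {  // strict improvement; ties keep smaller cut
        best = r2;
        cut = (vw[i].first + vw[i + 1].first) / 2.0;
        found = true;
      }
    }
    red = best;
    return found;
  }

  SplitRes best_numeric(int j, const std::vector<int>& rows) {
    SplitRes s;
    int n = (int)rows.size();
    std::vector<double> v(n);
    for (int i = 0; i < n; i++) v[i] = X(rows[i], j);
    double cut, red;
    if (!best_threshold(v, rows, cut, red)) return s;
    s.ok = true; s.type = 1; s.v1 = j; s.cut = cut; s.reduction = red;
    return s;
  }

  SplitRes best_subset(int j, const std::vector<int>& rows) {
    SplitRes s;
    int L = nlev[j], n = (int)rows.size();
    std::vector<double> lw0(L, 0.0), lw1(L, 0.0);
    std::vector<int> ln(L, 0);
    double W0 = 0.0, W1 = 0.0;
    for (int i = 0; i < n; i++) {
      int l = (int)X(rows[i], j) - 1;
      ln[l]++;
      if (y[rows[i]] == 1) { lw1[l] += w[rows[i]]; W1 += w[rows[i]]; }
      else { lw0[l] += w[rows[i]]; W0 += w[rows[i]]; }
    }
    std::vector<int> lv;
    for (int l = 0; l < L; l++) if (ln[l] > 0) lv.push_back(l);
    if ((int)lv.size() < 2) return s;
    std::sort(lv.begin(), lv.end(), [&](int a, int b) {
      double pa = lw1[a] / (lw0[a] + lw1[a]);
      double pb = lw1[b] / (lw0[b] + lw1[b]);
      if (pa != pb) return pa < pb;
      return a < b;
    });
    double W = W0 + W1, gp = gini_w(W0, W1);
    double aw0 = 0.0, aw1 = 0.0;
    int an = 0;
    double best = -1.0;
    int bestk = -1;
    for (size_t k = 0; k + 1 < lv.size(); k++) {
      aw0 += lw0[lv[k]]; aw1 += lw1[lv[k]]; an += ln[lv[k]];
      if (an < min_leaf || (n - an) < min_leaf) continue;
      double g = (aw0 + aw1) / W * gini_w(aw0, aw1) +
                 (W0 - aw0 + W1 - aw1) / W * gini_w(W0 - aw0, W1 - aw1);
      double r2 = gp - g;
      if (r2 > best + 1e-12) { best = r2; bestk = (int)k; }
    }
    if (bestk < 0) return s;
    s.ok = true; s.type = 2; s.v1 = j; s.reduction = best;
    for (int k = 0; k <= bestk; k++) s.left_levels.push_back(lv[k] + 1);
    std::sort(s.left_levels.begin(), s.left_levels.end());
    return s;
  }

  SplitRes best_uni(int j, const std::vector<int>& rows) {
    return kinds[j] == 2 ? best_subset(j, rows) : best_numeric(j, rows);
  }

  SplitRes best_linear(int i, int j, const std::vector<int>& rows) {
    SplitRes s;
    int n = (int)rows.size();
    std::vector<double> xi(n), xj(n);
    double mi = 0.0, mj = 0.0;
    for (int r = 0; r < n; r++) {
      xi[r] = X(rows[r], i); xj[r] = X(rows[r], j);
      mi += xi[r]; mj += xj[r];
    }
    mi /= n; mj /= n;
    double si = 0.0, sj = 0.0;
    for (int r = 0; r < n; r++) {
      si += (xi[r] - mi) * (xi[r] - mi);
      sj += (xj[r] - mj) * (xj[r] - mj);
    }
    si = std::sqrt(si / (n - 1)); sj = std::sqrt(sj / (n - 1));
    if (si <= 0 || sj <= 0) return s;
    std::vector<double> score(n);
    for (int k = 1; k <= n_angles; k++) {
      double th = -M_PI / 2.0 + k * M_PI / (n_angles + 1.0);
      double t = std::tan(th);
      for (int r = 0; r < n; r++)
        score[r] = t * (xi[r] - mi) / si + (xj[r] - mj) / sj;
      double cut, red;
      if (!best_threshold(score, rows, cut, red)) continue;
      if (!s.ok || red > s.reduction + 1e-12) {
        double a = t * sj / si;
        s.ok = true; s.type = 3; s.v1 = i; s.v2 = j;
        s.a = a; s.cut = sj * cut + a * mi + mj;
        s.reduction = red;
      }
    }
    return s;
  }

  bool goes_left(const SplitRes& s, int row) {
    if (s.type == 1) return X(row, s.v1) <= s.cut;
    if (s.type == 3) return s.a * X(row, s.v1) + X(row, s.v2) <= s.cut;
    int l = (int)X(row, s.v1);
    return std::binary_search(s.left_levels.begin(), s.left_levels.end(), l);
  }

  // total two-level impurity: split `rows` by s, then each child optimally
  // on variable b; returns parent-normalised impurity (lower is better)
  double two_level_total(const SplitRes& s, int b,
                         const std::vector<int>& rows) {
    std::vector<int> L, R;
    for (int r : rows) (goes_left(s, r) ? L : R).push_back(r);
    double W = 0.0;
    for (int r : rows) W += w[r];
    double tot = 0.0;
    for (auto* child : { &L, &R }) {
      double w0 = 0.0, w1 = 0.0;
      for (int r : *child) {
        if (y[r] == 1) w1 += w[r]; else w0 += w[r];
      }
      double Wc = w0 + w1;
      double imp = gini_w(w0, w1);
      if ((int)child->size() >= 2 * min_leaf) {
        SplitRes cs = best_uni(b, *child);
        if (cs.ok) imp -= cs.reduction;
      }
      tot += Wc / W * imp;
    }
    return tot;
  }

  // marginal impurity reduction of an arbitrary split
  double split_reduction(const SplitRes& s, const std::vector<int>& rows) {
    double w0 = 0.0, w1 = 0.0, l0 = 0.0, l1 = 0.0;
    for (int r : rows) {
      bool L = goes_left(s, r);
      if (y[r] == 1) { w1 += w[r]; if (L) l1 += w[r]; }
      else { w0 += w[r]; if (L) l0 += w[r]; }
    }
    double W = w0 + w1;
    return gini_w(w0, w1) - (l0 + l1) / W * gini_w(l0, l1) -
           (w0 - l0 + w1 - l1) / W * gini_w(w0 - l0, w1 - l1);
  }

  // best top-level split on `vt` judged by two-level total impurity (the
  // node on vt, children optimally on vc).  A pure interaction has a flat
  // marginal on vt, so besides the marginal-best rule the candidate set
  // holds decile cutoffs, ordered balanced-first; ties keep the earlier
  // (more balanced) candidate.
  SplitRes two_level_best_top(int vt, int vc, const std::vector<int>& rows,
                              double& total_out) {
    std::vector<SplitRes> cands;
    SplitRes mb = best_uni(vt, rows);
    // balanced (decile) candidates matter when the marginal is flat (a pure
    // interaction); a strong marginal cut is the two-level answer already
    double w0 = 0.0, w1 = 0.0;
    for (int r : rows) { if (y[r] == 1) w1 += w[r]; else w0 += w[r]; }
    bool flat = !mb.ok || mb.reduction < 0.1 * gini_w(w0, w1);
    if (flat && kinds[vt] != 2) {
      int n = (int)rows.size();
      std::vector<double> v(n);
      for (int i = 0; i < n; i++) v[i] = X(rows[i], vt);
      std::vector<double> s(v);
      std::sort(s.begin(), s.end());
      const double probs[1] = { 0.5 };
      std::vector<double> used;
      for (double p : probs) {
        double q = quantile7(s, p);
        bool dup = false;
        for (double u : used) if (u == q) { dup = true; break; }
        if (dup) continue;
        int nl = 0;
        for (double x : v) if (x <= q) nl++;
        if (nl < min_leaf || n - nl < min_leaf) continue;
        used.push_back(q);
        SplitRes c;
        c.ok = true; c.type = 1; c.v1 = vt; c.cut = q;
        cands.push_back(c);
      }
    }
    if (mb.ok) cands.push_back(mb);
    SplitRes best;
    total_out = R_PosInf;
    for (SplitRes& c : cands) {
      double t = two_level_total(c, vc, rows);
      if (t < total_out - 1e-12) {
        total_out = t;
        c.reduction = split_reduction(c, rows);
        best = c;
      }
    }
    return best;
  }

  // two-level interaction search: orientation (i then j) vs (j then i);
  // the winning orientation's top-level rule splits the node; ties keep i
  SplitRes two_level_split(int i, int j, const std::vector<int>& rows) {
    double ti, tj;
    SplitRes si = two_level_best_top(i, j, rows, ti);
    SplitRes sj = two_level_best_top(j, i, rows, tj);
    if (si.ok && (!sj.ok || ti <= tj + 1e-12)) return si;
    if (sj.ok) return sj;
    return SplitRes();
  }

  SplitRes choose_split(const std::vector<int>& rows) {
    std::vector<double> pv(p, NA_REAL);
    std::vector<int> valid;
    for (int j = 0; j < p; j++) {
      pv[j] = curvature_p(j, rows);
      if (!ISNA(pv[j])) valid.push_back(j);
    }
    if (valid.empty()) return SplitRes();
    int m = (int)valid.size();
    std::vector<int> ordv(valid);
    std::sort(ordv.begin(), ordv.end(), [&](int a, int b) {
      if (pv[a] != pv[b]) return pv[a] < pv[b];
      return a < b;
    });
    double main_adj = std::min(1.0, pv[ordv[0]] * m);

    // interaction screen among the strongest main-effect candidates
    double int_adj = NA_REAL;
    int bi = -1, bj = -1;
    if (do_inter && m >= 2 && (int)rows.size() >= inter_min_n) {
      int K = std::min(inter_topk, m);
      int npairs = K * (K - 1) / 2;
      // cache the coarse binning of each candidate once per node
      std::vector<std::vector<int>> cb(K);
      std::vector<bool> cb_ok(K);
      for (int a = 0; a < K; a++) cb_ok[a] = coarse_bin(ordv[a], rows, cb[a]);
      double bestp = NA_REAL;
      for (int a = 0; a < K; a++) {
        if (!cb_ok[a]) continue;
        for (int b = a + 1; b < K; b++) {
          if (!cb_ok[b]) continue;
          double pij = interaction_p_binned(cb[a], cb[b], rows);
          if (ISNA(pij)) continue;
          if (ISNA(bestp) || pij < bestp) {
            bestp = pij; bi = ordv[a]; bj = ordv[b];
          }
        }
      }
      if (!ISNA(bestp)) int_adj = std::min(1.0, bestp * npairs);
    }

    SplitRes cand;
    if (!ISNA(int_adj) && int_adj < main_adj && bi >= 0) {
      // pair member with smaller curvature p plays the X_i role
      int i2 = bi, j2 = bj;
      if (pv[j2] < pv[i2] || (pv[j2] == pv[i2] && j2 < i2)) std::swap(i2, j2);
      cand = two_level_split(i2, j2, rows);
      if (cand.ok) return cand;
    }

    // main-effect route: best feasible split, variables in p-value order
    for (int j : ordv) {
      cand = best_uni(j, rows);
      if (cand.ok) break;
    }

    // bivariate linear splits only when no interaction test is significant
    // and the node is large enough to estimate an oblique boundary
    bool lin_ok = do_linear && (int)rows.size() >= linear_min_n &&
                  (ISNA(int_adj) || int_adj >= inter_alpha);
    if (lin_ok) {
      int c1 = -1, c2 = -1;
      for (int j : ordv) {
        if (kinds[j] != 0) continue;
        if (c1 < 0) c1 = j;
        else if (c2 < 0) { c2 = j; break; }
      }
      if (c2 >= 0) {
        SplitRes lin = best_linear(c1, c2, rows);
        if (lin.ok && (!cand.ok ||
                       linear_pref * lin.reduction > cand.reduction + 1e-12))
          cand = lin;
      }
    }
    return cand;
  }

  void emit(int id, bool leaf, const SplitRes& s, double n0, double n1,
            double w0, double w1) {
    out_id.push_back(id);
    out_leaf.push_back(leaf ? 1 : 0);
    out_type.push_back(leaf ? 0 : s.type);
    out_v1.push_back(leaf ? NA_INTEGER : s.v1 + 1);
    out_v2.push_back(!leaf && s.type == 3 ? s.v2 + 1 : NA_INTEGER);
    out_a.push_back(!leaf && s.type == 3 ? s.a : NA_REAL);
    out_cut.push_back(!leaf && s.type != 2 ? s.cut : NA_REAL);
    out_lev.push_back(leaf ? std::vector<int>() : s.left_levels);
    out_n0.push_back(n0); out_n1.push_back(n1);
    out_w0.push_back(w0); out_w1.push_back(w1);
    out_pred.push_back(w1 > w0 ? 1 : 0);
  }

  void recurse(std::vector<int>& rows, int id, int depth) {
    double n0 = 0.0, n1 = 0.0, w0 = 0.0, w1 = 0.0;
    for (int r : rows) {
      if (y[r] == 1) { n1 += 1; w1 += w[r]; }
      else { n0 += 1; w0 += w[r]; }
    }
    SplitRes s;
    // below 2*min_leaf no split can satisfy the child-size constraint
    bool leaf = n0 == 0 || n1 == 0 ||
                (int)rows.size() < min_split ||
                (int)rows.size() < 2 * min_leaf || depth >= max_depth;
    if (!leaf) {
      s = choose_split(rows);
      leaf = !s.ok;
    }
    emit(id, leaf, s, n0, n1, w0, w1);
    if (leaf) return;
    std::vector<int> L, R;
    for (int r : rows) (goes_left(s, r) ? L : R).push_back(r);
    recurse(L, 2 * id, depth + 1);
    recurse(R, 2 * id + 1, depth + 1);
  }
};

// [[Rcpp::export]]
List grow_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
              IntegerVector kinds, IntegerVector nlev, IntegerVector rows,
              List opts) {
  Grower g(X, y, w, kinds, nlev, opts);
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); i++) rr[i] = rows[i] - 1;
  g.recurse(rr, 1, 0);
  int nn = (int)g.out_id.size();
  List lev(nn);
  for (int i = 0; i < nn; i++) lev[i] = wrap(g.out_lev[i]);
  return List::create(
      _["id"] = wrap(g.out_id), _["leaf"] = wrap(g.out_leaf),
      _["type"] = wrap(g.out_type), _["v1"] = wrap(g.out_v1),
      _["v2"] = wrap(g.out_v2), _["a"] = wrap(g.out_a),
      _["cut"] = wrap(g.out_cut), _["left_levels"] = lev,
      _["n0"] = wrap(g.out_n0), _["n1"] = wrap(g.out_n1),
      _["w0"] = wrap(g.out_w0), _["w1"] = wrap(g.out_w1),
      _["pred"] = wrap(g.out_pred));
}

// Route rows through a (possibly pruned) tree given as parallel node arrays.
// `keep_leaf[i]` marks node i as terminal in the current subtree.  Unseen
// categorical levels (coded NA) route right.
// [[Rcpp::export]]
List route_cpp(IntegerVector id, IntegerVector leaf, IntegerVector type,
               IntegerVector v1, IntegerVector v2, NumericVector a,
               NumericVector cut, List left_levels, IntegerVector pred,
               NumericMatrix X) {
  std::map<int, int> pos;
  for (int i = 0; i < id.size(); i++) pos[id[i]] = i;
  int n = X.nrow();
  IntegerVector node_out(n), pred_out(n);
  for (int r = 0; r < n; r++) {
    int cur = pos[1];
    while (!leaf[cur]) {
      bool go_left = false;
      if (type[cur] == 1) {
        double x = X(r, v1[cur] - 1);
        go_left = !ISNAN(x) && x <= cut[cur];
      } else if (type[cur] == 3) {
        double s = a[cur] * X(r, v1[cur] - 1) + X(r, v2[cur] - 1);
        go_left = !ISNAN(s) && s <= cut[cur];
      } else {
        double xl = X(r, v1[cur] - 1);
        if (!ISNAN(xl)) {
          IntegerVector ll = left_levels[cur];
          int l = (int)xl;
          for (int k = 0; k < ll.size(); k++)
            if (ll[k] == l) { go_left = true; break; }
        }
      }
      int child = 2 * id[cur] + (go_left ? 0 : 1);
      std::map<int, int>::iterator it = pos.find(child);
      if (it == pos.end()) break;  // child pruned away: stop here
      cur = it->second;
    }
    node_out[r] = id[cur];
    pred_out[r] = pred[cur];
  }
  return List::create(_["node"] = node_out, _["pred"] = pred_out);
}
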