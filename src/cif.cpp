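// Conditional-inference regression forest core.
//
// Trees select split variables by the asymptotic permutation p-value of the
// standardized linear statistic T = sum_i g(x_i) y_i (g identity for numeric
// predictors, one-hot for categorical ones), standardized by its conditional
// permutation mean and covariance; split points maximize the standardized
// two-sample statistic of the outcome.  Variable importance permutes one
// predictor at a time (optionally within strata of correlated predictors)
// and records the mean increase in per-tree MSE.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;        // split column (0-based), -1 for leaf
  std::vector<double> cut;     // numeric threshold (x <= cut goes left)
  std::vector<int> mask;       // categorical left-level bitmask, -1 if numeric
  std::vector<int> left, right;
  std::vector<double> value;   // node mean of y
  std::vector<double> pval;    // Bonferroni-adjusted p of the accepted split
  std::vector<int> nnode;
  std::vector<int> oob;        // 0-based out-of-bag row indices
  std::vector<int> inbag;      // 0-based subsample row indices
};

// Asymptotic p-value of the standardized linear-statistic test.
// nlev == 0: numeric predictor; nlev >= 2: codes 0..nlev-1.
void assoc_test(const std::vector<int>& idx, const double* x, const double* y,
                int nlev, double& stat, double& df, double& p) {
  const int n = (int)idx.size();
  stat = 0.0; df = 0.0; p = 1.0;
  if (n < 2) return;
  double sy = 0.0;
  for (int i : idx) sy += y[i];
  const double mu = sy / n;
  double ssy = 0.0;
  for (int i : idx) { const double d = y[i] - mu; ssy += d * d; }
  const double vh = ssy / n;  // conditional variance of h(y)
  if (vh <= 0.0) return;      // constant outcome

  if (nlev == 0) {
    double sx = 0.0, sxx = 0.0, sxy = 0.0;
    for (int i : idx) { sx += x[i]; sxx += x[i] * x[i]; sxy += x[i] * y[i]; }
    const double xbar = sx / n;
    const double ssx = sxx - sx * xbar;
    const double var = vh * (double)n * ssx / (double)(n - 1);
    if (var <= 1e-12 * (vh * (sxx + 1.0))) return;  // constant predictor
    const double d = sxy - sx * mu;
    stat = d * d / var;
    df = 1.0;
    p = R::pchisq(stat, 1.0, 0, 0);
    return;
  }

  const int k = nlev;
  arma::vec T(k, arma::fill::zeros), cnt(k, arma::fill::zeros);
  for (int i : idx) {
    const int lv = (int)x[i];
    T(lv) += y[i];
    cnt(lv) += 1.0;
  }
  int present = 0;
  for (int j = 0; j < k; ++j) if (cnt(j) > 0) ++present;
  if (present < 2) return;
  arma::vec d = T - cnt * mu;
  arma::mat V = (vh / (double)(n - 1)) *
    ((double)n * arma::diagmat(cnt) - cnt * cnt.t());
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, V)) return;
  const double tol = eval.max() * 1e-10;
  double q = 0.0;
  int rank = 0;
  for (int j = 0; j < k; ++j) {
    if (eval(j) > tol) {
      const double proj = arma::dot(evec.col(j), d);
      q += proj * proj / eval(j);
      ++rank;
    }
  }
  if (rank == 0) return;
  stat = q;
  df = (double)rank;
  p = R::pchisq(q, (double)rank, 0, 0);
}

// Best split of `idx` on column v; returns false if no cut satisfies the
// minimum child size.  Ties in the two-sample statistic resolve to the
// smallest left-child size (first maximum in the scan).
bool best_split(const std::vector<int>& idx, const double* x, const double* y,
                int nlev, int min_node, double& cut, int& mask) {
  const int n = (int)idx.size();
  double sy = 0.0;
  for (int i : idx) sy += y[i];
  const double mu = sy / n;
  double ssy = 0.0;
  for (int i : idx) { const double d = y[i] - mu; ssy += d * d; }
  const double vh = ssy / n;
  if (vh <= 0.0) return false;

  if (nlev == 0) {
    std::vector<int> ord(idx);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    double best = -1.0, cs = 0.0;
    int bestm = -1;
    for (int m = 1; m < n; ++m) {
      cs += y[ord[m - 1]];
      if (m < min_node || n - m < min_node) continue;
      if (x[ord[m]] <= x[ord[m - 1]]) continue;  // no real threshold here
      const double d = cs - m * mu;
      const double var = vh * (double)m * (double)(n - m) / (double)(n - 1);
      const double z2 = d * d / var;
      if (z2 > best + 1e-12) { best = z2; bestm = m; }
    }
    if (bestm < 0) return false;
    cut = 0.5 * (x[ord[bestm - 1]] + x[ord[bestm]]);
    mask = -1;
    return true;
  }

  // Categorical: order levels by mean outcome, scan prefix partitions.
  const int k = nlev;
  std::vector<double> lsum(k, 0.0);
  std::vector<int> lcnt(k, 0);
  for (int i : idx) { const int lv = (int)x[i]; lsum[lv] += y[i]; ++lcnt[lv]; }
  std::vector<int> lev;
  for (int j = 0; j < k; ++j) if (lcnt[j] > 0) lev.push_back(j);
  if ((int)lev.size() < 2) return false;
  std::sort(lev.begin(), lev.end(), [&](int a, int b) {
    const double ma = lsum[a] / lcnt[a], mb = lsum[b] / lcnt[b];
    if (ma != mb) return ma < mb;
    return a < b;
  });
  double best = -1.0, cs = 0.0;
  int cm = 0, bestj = -1;
  for (int j = 0; j + 1 < (int)lev.size(); ++j) {
    cs += lsum[lev[j]];
    cm += lcnt[lev[j]];
    if (cm < min_node || n - cm < min_node) continue;
    const double d = cs - cm * mu;
    const double var = vh * (double)cm * (double)(n - cm) / (double)(n - 1);
    const double z2 = d * d / var;
    if (z2 > best + 1e-12) { best = z2; bestj = j; }
  }
  if (bestj < 0) return false;
  int m = 0;
  for (int j = 0; j <= bestj; ++j) m |= (1 << lev[j]);
  mask = m;
  cut = NA_REAL;
  return true;
}

// Sample `m` distinct values from 0..n-1 (partial Fisher-Yates), ascending.
std::vector<int> sample_wor(int n, int m, std::mt19937_64& rng) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < m; ++i) {
    std::uniform_int_distribution<int> u(i, n - 1);
    std::swap(pool[i], pool[u(rng)]);
  }
  pool.resize(m);
  std::sort(pool.begin(), pool.end());
  return pool;
}

struct GrowCtx {
  const double* X;  // column-major n x p
  const double* y;
  int n, p;
  const int* nlev;
  int mtry, min_node;
  double alpha;
  std::mt19937_64* rng;
  Tree* tree;
};

const double* col(const GrowCtx& c, int v) { return c.X + (size_t)c.n * v; }

int grow_node(GrowCtx& c, const std::vector<int>& idx) {
  Tree& t = *c.tree;
  const int me = (int)t.var.size();
  double sy = 0.0;
  for (int i : idx) sy += c.y[i];
  t.var.push_back(-1);
  t.cut.push_back(NA_REAL);
  t.mask.push_back(-1);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(sy / idx.size());
  t.pval.push_back(NA_REAL);
  t.nnode.push_back((int)idx.size());

  if ((int)idx.size() < 2 * c.min_node) return me;

  const int m = std::min(c.mtry, c.p);
  std::vector<int> cand = sample_wor(c.p, m, *c.rng);
  double bestp = 2.0;
  int bestv = -1, tested = 0;
  for (int v : cand) {
    double stat, df, pv;
    assoc_test(idx, col(c, v), c.y, c.nlev[v], stat, df, pv);
    if (df > 0.0) ++tested;      // non-degenerate predictor actually tested
    if (df > 0.0 && pv < bestp) { bestp = pv; bestv = v; }
  }
  if (bestv < 0) return me;
  const double padj = std::min(1.0, bestp * tested);
  if (padj > c.alpha) return me;

  double cut;
  int mask;
  if (!best_split(idx, col(c, bestv), c.y, c.nlev[bestv], c.min_node, cut,
                  mask))
    return me;

  std::vector<int> li, ri;
  const double* xv = col(c, bestv);
  if (mask < 0) {
    for (int i : idx) (xv[i] <= cut ? li : ri).push_back(i);
  } else {
    for (int i : idx) (((mask >> (int)xv[i]) & 1) ? li : ri).push_back(i);
  }
  if ((int)li.size() < c.min_node || (int)ri.size() < c.min_node) return me;

  t.var[me] = bestv;
  t.cut[me] = cut;
  t.mask[me] = mask;
  t.pval[me] = padj;
  const int l = grow_node(c, li);
  t.left[me] = l;
  const int r = grow_node(c, ri);
  t.right[me] = r;
  return me;
}

double predict_row(const Tree& t, const double* X, int n, int row,
                   double xperm, int vperm) {
  int node = 0;
  while (t.var[node] >= 0) {
    const int v = t.var[node];
    const double x = (v == vperm) ? xperm : X[(size_t)n * v + row];
    bool goleft;
    if (t.mask[node] < 0)
      goleft = (x <= t.cut[node]);
    else
      goleft = ((t.mask[node] >> (int)x) & 1) != 0;
    node = goleft ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(
      _["var"] = wrap(t.var), _["cut"] = wrap(t.cut), _["mask"] = wrap(t.mask),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["value"] = wrap(t.value), _["pval"] = wrap(t.pval),
      _["n"] = wrap(t.nnode), _["oob"] = wrap(t.oob),
      _["inbag"] = wrap(t.inbag));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.var = as<std::vector<int>>(l["var"]);
  t.cut = as<std::vector<double>>(l["cut"]);
  t.mask = as<std::vector<int>>(l["mask"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  t.pval = as<std::vector<double>>(l["pval"]);
  t.nnode = as<std::vector<int>>(l["n"]);
  t.oob = as<std::vector<int>>(l["oob"]);
  t.inbag = as<std::vector<int>>(l["inbag"]);
  return t;
}

}  // namespace

// [[Rcpp::export]]
List cif_assoc_test_cpp(NumericVector x, NumericVector y, int nlev) {
  std::vector<int> idx(x.size());
  for (int i = 0; i < (int)x.size(); ++i) idx[i] = i;
  double stat, df, p;
  assoc_test(idx, x.begin(), y.begin(), nlev, stat, df, p);
  return List::create(_["statistic"] = stat, _["df"] = df, _["p_value"] = p);
}

// [[Rcpp::export]]
List cif_fit_forest_cpp(NumericMatrix X, IntegerVector nlev, NumericVector y,
                        int n_trees, int mtry, double alpha_split,
                        double subsample_fraction, int min_node_size,
                        double seed) {
  const int n = X.nrow();
  List out(n_trees);
  const int nsub =
      std::max(2, std::min(n, (int)std::floor(subsample_fraction * n)));
  for (int tr = 0; tr < n_trees; ++tr) {
    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + (uint64_t)tr + 1ULL);
    Tree tree;
    std::vector<int> sub = sample_wor(n, nsub, rng);
    tree.inbag = sub;
    std::vector<char> in(n, 0);
    for (int i : sub) in[i] = 1;
    for (int i = 0; i < n; ++i)
      if (!in[i]) tree.oob.push_back(i);
    GrowCtx c{X.begin(), y.begin(),      n,    X.ncol(), nlev.begin(),
              mtry,      min_node_size, alpha_split, &rng, &tree};
    grow_node(c, sub);
    out[tr] = tree_to_list(tree);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cif_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), nt = forest.size();
  NumericVector out(n, 0.0);
  for (int tr = 0; tr < nt; ++tr) {
    Tree t = tree_from_list(forest[tr]);
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(t, X.begin(), n, i, 0.0, -1);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// Permutation importance.  If use_oob, evaluation cases of tree t are its
// out-of-bag rows of X (training matrix); otherwise all rows of X (held-out
// data).  cond: p x p logical matrix; cond(w, v) != 0 means predictor w is
// in the conditioning set of v.  In conditional mode the permutation of v
// is restricted to the cells of the partition that the tree itself induces
// on v's conditioning set (its own cutpoints / level masks on those
// variables); an all-zero cond gives the marginal permutation.
// [[Rcpp::export]]
NumericVector cif_importance_cpp(List forest, NumericMatrix X, NumericVector y,
                                 LogicalMatrix cond, int n_perm, double seed,
                                 bool use_oob) {
  const int n = X.nrow(), p = X.ncol(), nt = forest.size();
  NumericVector imp(p, 0.0);
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 11ULL);
  std::vector<double> xbuf(n);
  std::vector<int> order(n), sid(n);

  for (int tr = 0; tr < nt; ++tr) {
    Tree t = tree_from_list(forest[tr]);
    std::vector<int> ev;
    if (use_oob)
      ev = t.oob;
    else {
      ev.resize(n);
      for (int i = 0; i < n; ++i) ev[i] = i;
    }
    const int ne = (int)ev.size();
    if (ne == 0) continue;

    double mse0 = 0.0;
    for (int i : ev) {
      const double d = predict_row(t, X.begin(), n, i, 0.0, -1) - y[i];
      mse0 += d * d;
    }
    mse0 /= ne;

    std::vector<char> used(p, 0);
    // cutpoints this tree applies, per variable
    std::vector<std::vector<double>> cuts(p);
    std::vector<std::vector<int>> masks(p);
    for (size_t j = 0; j < t.var.size(); ++j) {
      const int v = t.var[j];
      if (v < 0) continue;
      used[v] = 1;
      if (t.mask[j] < 0)
        cuts[v].push_back(t.cut[j]);
      else
        masks[v].push_back(t.mask[j]);
    }
    for (int v = 0; v < p; ++v) {
      std::sort(cuts[v].begin(), cuts[v].end());
      cuts[v].erase(std::unique(cuts[v].begin(), cuts[v].end()),
                    cuts[v].end());
    }

    for (int v = 0; v < p; ++v) {
      if (!used[v]) continue;  // unchanged predictions: exact zero increase

      // stratum id of each evaluation case under the tree's partition of
      // v's conditioning set
      std::fill(sid.begin(), sid.begin() + ne, 0);
      for (int w = 0; w < p; ++w) {
        if (w == v || !cond[(size_t)p * v + w]) continue;
        if (!cuts[w].empty()) {
          const int nb = (int)cuts[w].size() + 1;
          for (int j = 0; j < ne; ++j) {
            const double x = X[(size_t)n * w + ev[j]];
            const int b = (int)(std::upper_bound(cuts[w].begin(),
                                                 cuts[w].end(), x) -
                                cuts[w].begin());
            sid[j] = sid[j] * nb + b;
          }
        }
        for (int msk : masks[w])
          for (int j = 0; j < ne; ++j) {
            const int code = (int)X[(size_t)n * w + ev[j]];
            sid[j] = sid[j] * 2 + ((msk >> code) & 1);
          }
      }

      double acc = 0.0;
      for (int rep = 0; rep < n_perm; ++rep) {
        for (int j = 0; j < ne; ++j) xbuf[j] = X[(size_t)n * v + ev[j]];
        for (int j = 0; j < ne; ++j) order[j] = j;
        std::sort(order.begin(), order.begin() + ne, [&](int a, int b) {
          if (sid[a] != sid[b]) return sid[a] < sid[b];
          return a < b;
        });
        int s = 0;
        while (s < ne) {
          int e = s;
          while (e < ne && sid[order[e]] == sid[order[s]]) ++e;
          for (int j = e - 1; j > s; --j) {
            std::uniform_int_distribution<int> u(s, j);
            const int k = u(rng);
            std::swap(xbuf[order[j]], xbuf[order[k]]);
          }
          s = e;
        }
        double mse = 0.0;
        for (int j = 0; j < ne; ++j) {
          const int i = ev[j];
          const double d =
              predict_row(t, X.begin(), n, i, xbuf[j], v) - y[i];
          mse += d * d;
        }
        acc += mse / ne - mse0;
      }
      imp[v] += acc / n_perm;
    }
  }
  for (int v = 0; v < p; ++v) imp[v] /= nt;
  return imp;
}
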