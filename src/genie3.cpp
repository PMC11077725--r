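#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// Randomized regression-tree ensemble importance, GENIE3 style.
//
// Trees are grown on all samples (no per-index bootstrap, so results are
// invariant to sample order); at each node a random subset of mtry
// candidate predictors is drawn and the best exhaustive variance-reducing
// split among them is taken. A predictor's importance is the total
// variance reduction (N*Var decrease) it achieves, summed over nodes and
// averaged over trees.

namespace {

struct TreeContext {
  const double* x;       // n x p, column major
  const double* y;
  int n, p, mtry, min_node;
  std::mt19937* rng;
  std::vector<double>* importance;
  std::vector<int>* var_pool;      // scratch, size p
  std::vector<std::pair<double, double>>* scratch;  // (x value, y)
};

void grow_node(TreeContext& ctx, std::vector<int>& idx) {
  const int m = static_cast<int>(idx.size());
  if (m < ctx.min_node) return;

  // canonical (sorted) accumulation so that results are bitwise invariant
  // to the order samples arrive in
  std::vector<double> ys;
  ys.reserve(m);
  for (int i : idx) ys.push_back(ctx.y[i]);
  std::sort(ys.begin(), ys.end());
  double sum = 0.0, sum2 = 0.0;
  for (double v : ys) { sum += v; sum2 += v * v; }
  const double sse_node = sum2 - sum * sum / m;
  if (sse_node <= 1e-12) return;

  // draw mtry distinct predictors (partial Fisher-Yates)
  std::vector<int>& pool = *ctx.var_pool;
  for (int j = 0; j < ctx.p; ++j) pool[j] = j;
  const int take = std::min(ctx.mtry, ctx.p);
  for (int j = 0; j < take; ++j) {
    std::uniform_int_distribution<int> pick(j, ctx.p - 1);
    std::swap(pool[j], pool[pick(*ctx.rng)]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, double>>& sc = *ctx.scratch;

  for (int j = 0; j < take; ++j) {
    const int v = pool[j];
    const double* col = ctx.x + static_cast<size_t>(v) * ctx.n;
    sc.clear();
    for (int i : idx) sc.emplace_back(col[i], ctx.y[i]);
    std::sort(sc.begin(), sc.end());  // by (x, y): canonical within x ties
    double lsum = 0.0, lsum2 = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      lsum += sc[i].second;
      lsum2 += sc[i].second * sc[i].second;
      if (sc[i].first == sc[i + 1].first) continue;  // split between distinct values
      const int nl = i + 1, nr = m - nl;
      const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      const double sse_l = lsum2 - lsum * lsum / nl;
      const double sse_r = rsum2 - rsum * rsum / nr;
      const double gain = sse_node - sse_l - sse_r;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = v;
        best_thr = 0.5 * (sc[i].first + sc[i + 1].first);
      }
    }
  }
  if (best_var < 0) return;

  (*ctx.importance)[best_var] += best_gain;

  const double* col = ctx.x + static_cast<size_t>(best_var) * ctx.n;
  std::vector<int> left, right;
  left.reserve(m); right.reserve(m);
  for (int i : idx) (col[i] <= best_thr ? left : right).push_back(i);
  if (left.empty() || right.empty()) return;  // degenerate, shouldn't happen
  grow_node(ctx, left);
  grow_node(ctx, right);
}

}  // namespace

// [[Rcpp::export]]
NumericVector tree_ensemble_importance(NumericMatrix x, NumericVector y,
                                       int n_trees, int mtry, int min_node,
                                       int seed) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("x and y dimensions disagree");
  if (p < 1) stop("need at least one predictor");
  if (mtry < 1) mtry = 1;
  if (min_node < 2) min_node = 2;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<double> importance(p, 0.0);
  std::vector<int> var_pool(p);
  std::vector<std::pair<double, double>> scratch;
  scratch.reserve(n);

  TreeContext ctx;
  ctx.x = x.begin();
  ctx.y = y.begin();
  ctx.n = n; ctx.p = p; ctx.mtry = mtry; ctx.min_node = min_node;
  ctx.rng = &rng;
  ctx.importance = &importance;
  ctx.var_pool = &var_pool;
  ctx.scratch = &scratch;

  std::vector<int> root(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) root[i] = i;
    std::vector<int> idx = root;
    grow_node(ctx, idx);
  }

  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = importance[j] / n_trees;
  return out;
}
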