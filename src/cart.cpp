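// Greedy binary classification tree (Gini impurity, unlimited depth) used as
// the wrapper classifier inside the genetic-algorithm fitness and as the
// final per-split classifier. Grown to purity by default (min_split = 2),
// scores are leaf class-1 fractions. Fully deterministic: ties in split gain
// are broken by lowest column index, then lowest threshold.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Split {
  double gain = 0.0;
  int col = -1;
  double threshold = 0.0;
  bool found = false;
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

Split best_split(const NumericMatrix& X, const IntegerVector& y,
                 const std::vector<int>& idx) {
  const int n = (int)idx.size();
  const int p = X.ncol();
  double n1 = 0.0;
  for (int i = 0; i < n; ++i) n1 += y[idx[i]];
  const double parent = gini(n1, (double)n);
  Split best;
  std::vector<std::pair<double, int>> v(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) v[i] = {X(idx[i], j), y[idx[i]]};
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) continue;  // constant column
    double left1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      left1 += v[i].second;
      if (v[i].first == v[i + 1].first) continue;  // not a valid cut point
      double nl = i + 1.0, nr = n - nl;
      double gain = parent - (nl / n) * gini(left1, nl)
                           - (nr / n) * gini(n1 - left1, nr);
      double thr = v[i].first + (v[i + 1].first - v[i].first) / 2.0;
      if (gain > best.gain + 1e-12 ||
          (best.found && std::abs(gain - best.gain) <= 1e-12 &&
           (j < best.col || (j == best.col && thr < best.threshold)))) {
        if (gain > 1e-12) {
          best.gain = gain; best.col = j; best.threshold = thr;
          best.found = true;
        }
      }
    }
  }
  return best;
}

void grow(const NumericMatrix& Xtr, const IntegerVector& ytr,
          const NumericMatrix& Xte, NumericVector& out,
          std::vector<int>& tr, std::vector<int>& te, int min_split) {
  const int n = (int)tr.size();
  double n1 = 0.0;
  for (int i = 0; i < n; ++i) n1 += ytr[tr[i]];
  bool pure = (n1 == 0.0 || n1 == (double)n);
  Split sp;
  if (!pure && n >= min_split) sp = best_split(Xtr, ytr, tr);
  if (pure || n < min_split || !sp.found) {
    double leaf = n1 / (double)n;
    for (int k : te) out[k] = leaf;
    return;
  }
  std::vector<int> trL, trR, teL, teR;
  for (int i : tr) (Xtr(i, sp.col) <= sp.threshold ? trL : trR).push_back(i);
  for (int k : te) (Xte(k, sp.col) <= sp.threshold ? teL : teR).push_back(k);
  if (!teL.empty()) grow(Xtr, ytr, Xte, out, trL, teL, min_split);
  if (!teR.empty()) grow(Xtr, ytr, Xte, out, trR, teR, min_split);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cart_tree_predict(NumericMatrix Xtr, IntegerVector ytr,
                                NumericMatrix Xte, int min_split = 2) {
  if (Xtr.nrow() != ytr.size()) stop("nrow(Xtr) must equal length(ytr)");
  if (Xtr.ncol() != Xte.ncol()) stop("train and test column counts differ");
  if (Xtr.nrow() == 0) stop("empty training set");
  for (int i = 0; i < ytr.size(); ++i)
    if (ytr[i] != 0 && ytr[i] != 1) stop("ytr must be 0/1");
  NumericVector out(Xte.nrow());
  if (Xte.nrow() == 0) return out;
  std::vector<int> tr(Xtr.nrow()), te(Xte.nrow());
  for (int i = 0; i < Xtr.nrow(); ++i) tr[i] = i;
  for (int k = 0; k < Xte.nrow(); ++k) te[k] = k;
  grow(Xtr, ytr, Xte, out, tr, te, min_split);
  return out;
}
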