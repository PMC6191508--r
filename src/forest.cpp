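#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: deterministic across platforms, unlike the distributions in
// <random>, which are implementation-defined.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(double seed) : s((uint64_t)seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feat;  // split feature (0-based), -1 at leaves
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;  // majority class of the node (tie -> 1)
};

// Grow a CART node on samples idx[lo, hi).  X is n x p column-major
// (one sample per row, so each feature column is contiguous, which keeps
// the split search cache-friendly).  Gini impurity, midpoint thresholds,
// first best split wins; leaves are pure nodes, singletons, or nodes
// where no sampled feature admits a split with positive impurity
// decrease.
int grow(const double* X, int ntot, int p, const int* y, std::vector<int>& idx,
         int lo, int hi, int mtry, int min_node, SplitMix& rng,
         std::vector<int>& featpool, Tree& T, std::vector<double>& pbuf,
         std::vector<double>& nbuf) {
  const int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  T.pred.push_back(2 * n1 >= n ? 1 : 0);
  if (n < 2 || n < 2 * min_node || n1 == 0 || n1 == n) return node;

  const int m = std::min(mtry, p);
  double bestGain = 1e-12;
  int bestF = -1;
  double bestThr = 0.0;
  const double parent = (double)n1 * (n - n1) / n;
  for (int t = 0; t < m; ++t) {
    const int r = t + rng.below(p - t);
    std::swap(featpool[t], featpool[r]);
    const int f = featpool[t];
    // per-class value sort + merge scan: same splits as a joint sorted
    // scan, but sorting plain doubles is much cheaper than (value, label)
    // pairs on this hot path
    pbuf.resize(n);
    nbuf.resize(n);
    int np = 0, nn = 0;
    const double* col = X + (size_t)f * ntot;
    for (int i = lo; i < hi; ++i) {
      const double v = col[idx[i]];
      if (y[idx[i]]) pbuf[np++] = v; else nbuf[nn++] = v;
    }
    std::sort(pbuf.begin(), pbuf.begin() + np);
    std::sort(nbuf.begin(), nbuf.begin() + nn);
    int i = 0, j = 0, c1 = 0, c0 = 0;
    double prev = 0.0;
    bool have_prev = false;
    while (i < np || j < nn) {
      const double v =
          (j >= nn || (i < np && pbuf[i] <= nbuf[j])) ? pbuf[i] : nbuf[j];
      if (have_prev && v != prev) {
        const int nl = c1 + c0, nr = n - nl;
        const int l1 = c1, r1 = n1 - c1;
        const double gain = parent - (double)l1 * (nl - l1) / nl -
                            (double)r1 * (nr - r1) / nr;
        if (gain > bestGain) {
          bestGain = gain;
          bestF = f;
          bestThr = 0.5 * (prev + v);
        }
      }
      while (i < np && pbuf[i] == v) { ++i; ++c1; }
      while (j < nn && nbuf[j] == v) { ++j; ++c0; }
      prev = v;
      have_prev = true;
    }
  }
  if (bestF < 0) return node;

  std::vector<int> lft, rgt;
  lft.reserve(n);
  rgt.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X[(size_t)idx[i] + (size_t)bestF * ntot] <= bestThr)
      lft.push_back(idx[i]);
    else
      rgt.push_back(idx[i]);
  }
  for (size_t i = 0; i < lft.size(); ++i) idx[lo + (int)i] = lft[i];
  for (size_t i = 0; i < rgt.size(); ++i) idx[lo + (int)lft.size() + (int)i] = rgt[i];
  const int mid = lo + (int)lft.size();
  T.feat[node] = bestF;
  T.thr[node] = bestThr;
  T.left[node] = grow(X, ntot, p, y, idx, lo, mid, mtry, min_node, rng,
                      featpool, T, pbuf, nbuf);
  T.right[node] = grow(X, ntot, p, y, idx, mid, hi, mtry, min_node, rng,
                       featpool, T, pbuf, nbuf);
  return node;
}

Tree grow_tree(const double* X, int n, int p, const int* y, int mtry,
               int min_node, SplitMix& rng, std::vector<int>& featpool,
               std::vector<double>& pbuf, std::vector<double>& nbuf) {
  // bootstrap resample of the n training samples
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
  Tree T;
  grow(X, n, p, y, idx, 0, n, mtry, min_node, rng, featpool, T, pbuf, nbuf);
  return T;
}

int tree_vote(const Tree& T, const double* x, int p) {
  int node = 0;
  while (T.feat[node] >= 0)
    node = x[T.feat[node]] <= T.thr[node] ? T.left[node] : T.right[node];
  return T.pred[node];
}

List tree_to_list(const Tree& T) {
  return List::create(_["feat"] = IntegerVector(T.feat.begin(), T.feat.end()),
                      _["thr"] = NumericVector(T.thr.begin(), T.thr.end()),
                      _["left"] = IntegerVector(T.left.begin(), T.left.end()),
                      _["right"] = IntegerVector(T.right.begin(), T.right.end()),
                      _["pred"] = IntegerVector(T.pred.begin(), T.pred.end()));
}

Tree tree_from_list(const List& L) {
  Tree T;
  IntegerVector feat = L["feat"], left = L["left"], right = L["right"],
                pred = L["pred"];
  NumericVector thr = L["thr"];
  T.feat.assign(feat.begin(), feat.end());
  T.thr.assign(thr.begin(), thr.end());
  T.left.assign(left.begin(), left.end());
  T.right.assign(right.begin(), right.end());
  T.pred.assign(pred.begin(), pred.end());
  return T;
}

// X: n x p column-major (samples in rows)
std::vector<Tree> train_forest_core(const double* X, int n, int p, const int* y,
                                    int ntree, int mtry, int min_node,
                                    double seed) {
  SplitMix rng(seed);
  std::vector<int> featpool(p);
  for (int i = 0; i < p; ++i) featpool[i] = i;
  std::vector<double> pbuf, nbuf;
  std::vector<Tree> forest;
  forest.reserve(ntree);
  for (int t = 0; t < ntree; ++t)
    forest.push_back(
        grow_tree(X, n, p, y, mtry, min_node, rng, featpool, pbuf, nbuf));
  return forest;
}

// Balanced most-similar subset: indices (0-based, into the candidate set)
// of up to k per class, ranked by squared Euclidean feature distance to
// the target voxel; stable within ties (candidate order preserved).
void rank_balanced(const std::vector<double>& d, const int* lab, int m, int k,
                   std::vector<int>& pos, std::vector<int>& neg) {
  std::vector<int> ip, in;
  for (int j = 0; j < m; ++j) (lab[j] == 1 ? ip : in).push_back(j);
  struct Cmp {
    const std::vector<double>& d;
    explicit Cmp(const std::vector<double>& d_) : d(d_) {}
    bool operator()(int a, int b) const { return d[a] < d[b]; }
  } cmp(d);
  std::stable_sort(ip.begin(), ip.end(), cmp);
  std::stable_sort(in.begin(), in.end(), cmp);
  if ((int)ip.size() > k) ip.resize(k);
  if ((int)in.size() > k) in.resize(k);
  pos.swap(ip);
  neg.swap(in);
}

double sqdist(const double* a, const double* b, int p) {
  double s = 0.0;
  for (int i = 0; i < p; ++i) {
    const double d = a[i] - b[i];
    s += d * d;
  }
  return s;
}

}  // namespace

// Training matrix X holds one sample per ROW (n x p); prediction input
// holds one query per COLUMN (p x m).
// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> forest =
      train_forest_core(REAL(X), n, p, INTEGER(y), ntree, mtry, min_node, seed);
  List out(ntree);
  for (int t = 0; t < ntree; ++t) out[t] = tree_to_list(forest[t]);
  return out;
}

// Per-tree hard votes: queries in columns of X; returns ncol(X) x ntree.
// [[Rcpp::export]]
IntegerMatrix cpp_rf_votes(List forest, NumericMatrix X) {
  const int p = X.nrow(), m = X.ncol(), ntree = forest.size();
  std::vector<Tree> trees;
  trees.reserve(ntree);
  for (int t = 0; t < ntree; ++t) trees.push_back(tree_from_list(forest[t]));
  IntegerMatrix out(m, ntree);
  for (int j = 0; j < m; ++j) {
    const double* x = &X(0, j);
    for (int t = 0; t < ntree; ++t) out(j, t) = tree_vote(trees[t], x, p);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_balanced_subset(NumericMatrix F, IntegerVector lab,
                         NumericVector target, int k) {
  const int p = F.nrow(), m = F.ncol();
  std::vector<double> d(m);
  for (int j = 0; j < m; ++j) d[j] = sqdist(&F(0, j), REAL(target), p);
  std::vector<int> pos, neg;
  rank_balanced(d, INTEGER(lab), m, k, pos, neg);
  for (size_t i = 0; i < pos.size(); ++i) pos[i] += 1;  // 1-based for R
  for (size_t i = 0; i < neg.size(); ++i) neg[i] += 1;
  return List::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["neg"] = IntegerVector(neg.begin(), neg.end()));
}

// Fused per-voxel loop used by rf_segment(): for each ambiguous voxel,
// balanced subset selection, forest training and target prediction, all
// through the same core routines as the exported single-voxel operations,
// so the composed path and this one agree bitwise for a given seed.
//
// candIdx holds, per ambiguous voxel, 0-based column indices into candF
// (atlas-major, neighborhood-offset-minor order); candLab the matching
// labels; seeds one RNG seed per voxel.  Returns the foreground
// probability and a status code (0 = forest, 1 = only foreground
// candidates, 2 = only background candidates).
// [[Rcpp::export]]
List cpp_rf_fuse(NumericMatrix targetF, NumericMatrix candF,
                 IntegerVector candLab, List candIdx, int k, int ntree,
                 int mtry, int min_node, NumericVector seeds) {
  const int p = targetF.nrow();
  const int na = targetF.ncol();
  if (candF.nrow() != p) stop("feature dimension mismatch");
  if (candIdx.size() != na || seeds.size() != na)
    stop("per-voxel inputs disagree in length");
  NumericVector prob(na);
  IntegerVector status(na);
  std::vector<double> Xsub;
  std::vector<int> ysub;
  std::vector<double> d;
  std::vector<int> lgather;
  for (int v = 0; v < na; ++v) {
    IntegerVector ci = candIdx[v];
    const int m = ci.size();
    d.resize(m);
    lgather.resize(m);
    for (int j = 0; j < m; ++j) {
      const int col = ci[j];
      d[j] = sqdist(&candF(0, col), &targetF(0, v), p);
      lgather[j] = candLab[col];
    }
    std::vector<int> pos, neg;
    rank_balanced(d, &lgather[0], m, k, pos, neg);
    if (neg.empty()) {
      prob[v] = 1.0;
      status[v] = 1;
      continue;
    }
    if (pos.empty()) {
      prob[v] = 0.0;
      status[v] = 2;
      continue;
    }
    const int nsub = (int)(pos.size() + neg.size());
    Xsub.resize((size_t)p * nsub);
    ysub.resize(nsub);
    std::vector<const double*> src(nsub);
    int at = 0;
    for (size_t i = 0; i < pos.size(); ++i, ++at) {
      src[at] = &candF(0, ci[pos[i]]);
      ysub[at] = 1;
    }
    for (size_t i = 0; i < neg.size(); ++i, ++at) {
      src[at] = &candF(0, ci[neg[i]]);
      ysub[at] = 0;
    }
    // blocked sample-major -> feature-major transpose (keeps both the
    // scattered reads and the strided writes inside L1-sized tiles)
    const int BF = 64, BA = 32;
    for (int f0 = 0; f0 < p; f0 += BF) {
      const int f1 = std::min(f0 + BF, p);
      for (int a0 = 0; a0 < nsub; a0 += BA) {
        const int a1 = std::min(a0 + BA, nsub);
        for (int a = a0; a < a1; ++a) {
          const double* s = src[a];
          for (int f = f0; f < f1; ++f)
            Xsub[(size_t)a + (size_t)f * nsub] = s[f];
        }
      }
    }
    std::vector<Tree> forest = train_forest_core(
        &Xsub[0], nsub, p, &ysub[0], ntree, mtry, min_node, seeds[v]);
    int votes = 0;
    for (int t = 0; t < ntree; ++t)
      votes += tree_vote(forest[t], &targetF(0, v), p);
    prob[v] = (double)votes / ntree;
    status[v] = 0;
    if (v % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["prob"] = prob, _["status"] = status);
}
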