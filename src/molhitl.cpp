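#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic counter-based RNG (splitmix64). All stochastic components of
// the package draw from streams derived from user seeds via these functions,
// so runs are reproducible across platforms independently of R's global RNG.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(splitmix64(seed ^ 0xD6E8FEB86659FD93ULL)) {}
  uint64_t next() { state = splitmix64(state); return state; }
  // uniform in (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  // integer in [0, n)
  int below(int n) { return (int)(unif() * n) % n; }
};

// [[Rcpp::export]]
NumericVector cpp_hash_unif(double seed, NumericVector idx) {
  int n = idx.size();
  NumericVector out(n);
  uint64_t s = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n; ++i) {
    uint64_t h = splitmix64(s * 0x9E3779B97F4A7C15ULL ^ splitmix64((uint64_t)(int64_t)idx[i]));
    out[i] = ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Morgan (ECFP-style) circular environment identifiers.
//
// init_inv: initial integer invariant per atom; nbrs / bord: adjacency lists
// (0-based atom indices) and bond orders aligned with them; bidx: bond id per
// adjacency entry. Returns one identifier per emitted environment, following
// the usual deduplication rules: an atom emits at radius r > 0 only if its
// bond environment grew, and structurally identical environments (same bond
// set) at the same radius are counted once.
// ---------------------------------------------------------------------------

static inline uint32_t fold32(uint64_t h) { return (uint32_t)(h ^ (h >> 32)); }

// [[Rcpp::export]]
NumericVector cpp_morgan_ids(IntegerVector init_inv, List nbrs, List bord,
                             List bidx, int radius) {
  int n = init_inv.size();
  std::vector<uint64_t> hash(n), newhash(n);
  std::vector< std::set<int> > env(n), newenv(n);
  for (int a = 0; a < n; ++a)
    hash[a] = splitmix64((uint64_t)(uint32_t)init_inv[a] + 0x51ED270B0A1ULL);

  std::vector<double> ids;
  for (int a = 0; a < n; ++a) ids.push_back((double)fold32(hash[a]));

  for (int r = 1; r <= radius; ++r) {
    // environments seen at this radius: bond set -> best (lowest) hash
    std::vector< std::pair<std::set<int>, uint64_t> > seen;
    std::vector<bool> grew(n, false);
    for (int a = 0; a < n; ++a) {
      IntegerVector nb = nbrs[a], bo = bord[a], bi = bidx[a];
      std::vector< std::pair<int, uint64_t> > parts;
      newenv[a] = env[a];
      for (int j = 0; j < nb.size(); ++j) {
        parts.push_back(std::make_pair(bo[j], hash[nb[j]]));
        newenv[a].insert(bi[j]);
        newenv[a].insert(env[nb[j]].begin(), env[nb[j]].end());
      }
      std::sort(parts.begin(), parts.end());
      uint64_t h = splitmix64(hash[a] + (uint64_t)r * 0x100000001B3ULL);
      for (size_t j = 0; j < parts.size(); ++j) {
        h = splitmix64(h ^ splitmix64((uint64_t)(uint32_t)parts[j].first * 0x10001ULL));
        h = splitmix64(h ^ parts[j].second);
      }
      newhash[a] = h;
      grew[a] = newenv[a].size() > env[a].size();
    }
    for (int a = 0; a < n; ++a) {
      if (!grew[a]) continue;
      bool dup = false;
      for (size_t s = 0; s < seen.size(); ++s)
        if (seen[s].first == newenv[a]) { dup = true; break; }
      if (!dup) {
        seen.push_back(std::make_pair(newenv[a], newhash[a]));
        ids.push_back((double)fold32(newhash[a]));
      }
    }
    hash = newhash;
    env = newenv;
  }
  return wrap(ids);
}

// ---------------------------------------------------------------------------
// Random forest: bagged CART trees with per-split feature subsampling.
// Sample weights act through the bootstrap (draws with probability
// proportional to weight), so zero-weight records can never influence a fit
// and leave the tree-level RNG stream unchanged.
// ---------------------------------------------------------------------------

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

static void build_node(Tree &tr, const NumericMatrix &X, const NumericVector &y,
                       std::vector<int> &rows, int lo, int hi, int depth,
                       int max_depth, int min_split, int mtry, bool classify,
                       Rng &rng) {
  int node = tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);

  int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[rows[i]];
  double mean = sum / n;
  double leaf = classify ? (mean >= 0.5 ? 1.0 : 0.0) : mean;
  tr.value.push_back(leaf);

  bool pure = true;
  for (int i = lo + 1; i < hi; ++i)
    if (y[rows[i]] != y[rows[lo]]) { pure = false; break; }
  if (pure || n < min_split || depth >= max_depth) return;

  int p = X.ncol();
  // partial Fisher-Yates for the mtry candidate features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + rng.below(p - j);
    std::swap(feats[j], feats[k]);
  }

  // parent impurity terms
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  double sum2 = 0.0, n1 = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum2 += y[rows[i]] * y[rows[i]];
    n1 += (y[rows[i]] > 0.5);
  }

  std::vector< std::pair<double, double> > vals(n); // (x, y)
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[lo + i], f), y[rows[lo + i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double lsum = 0.0, ln1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vals[i].second;
      ln1 += (vals[i].second > 0.5);
      if (vals[i + 1].first == vals[i].first) continue;
      int nl = i + 1, nr = n - nl;
      double gain;
      if (classify) {
        double rn1 = n1 - ln1;
        double gl = ln1 * (nl - ln1) / (double)nl;
        double gr = rn1 * (nr - rn1) / (double)nr;
        double gp = n1 * (n - n1) / (double)n;
        gain = (gp - gl - gr) / n; // weighted Gini decrease
      } else {
        double rsum = sum - lsum;
        // SSE decrease = parent SSE - child SSEs; constant sum2 cancels
        gain = (lsum * lsum / nl + rsum * rsum / nr - sum * sum / n) / n;
      }
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition rows in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[mid++], rows[i]);
  if (mid == lo || mid == hi) return;

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  tr.left[node] = tr.feature.size();
  build_node(tr, X, y, rows, lo, mid, depth + 1, max_depth, min_split, mtry,
             classify, rng);
  tr.right[node] = tr.feature.size();
  build_node(tr, X, y, rows, mid, hi, depth + 1, max_depth, min_split, mtry,
             classify, rng);
}

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, NumericVector w, int ntree,
                int mtry, int max_depth, int min_split, bool classify,
                double seed) {
  int n = X.nrow();
  std::vector<double> cw(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { tot += w[i]; cw[i] = tot; }
  if (tot <= 0) stop("all sample weights are zero");

  List forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    Rng rng(splitmix64((uint64_t)(int64_t)seed) ^ splitmix64((uint64_t)(b + 1)));
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      double u = rng.unif() * tot;
      rows[i] = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
      if (rows[i] >= n) rows[i] = n - 1;
    }
    Tree tr;
    build_node(tr, X, y, rows, 0, n, 0, max_depth, min_split, mtry, classify,
               rng);
    forest[b] = List::create(_["feature"] = wrap(tr.feature),
                             _["threshold"] = wrap(tr.threshold),
                             _["left"] = wrap(tr.left),
                             _["right"] = wrap(tr.right),
                             _["value"] = wrap(tr.value));
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    List tr = forest[b];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out(i, b) = value[node];
    }
  }
  return out;
}
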