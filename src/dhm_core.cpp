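#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Fractional identity between two DNA strings.
// Equal lengths: Hamming matches / length. Unequal lengths: global
// Needleman-Wunsch (match +1, mismatch -1, gap -2, linear, no end-gap
// discount), identity = matching columns / alignment columns. Traceback
// tie-break: diagonal, then up (gap in b), then left, so the result is
// deterministic.
static double identity_pair(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == m) {
    int match = 0;
    for (int i = 0; i < n; ++i)
      if (a[i] == b[i]) ++match;
    return (double)match / (double)n;
  }
  const int GAP = -2;
  std::vector<int> F((size_t)(n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) F[j] = GAP * j;
  for (int i = 1; i <= n; ++i) {
    F[(size_t)i * W] = GAP * i;
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? 1 : -1;
      int diag = F[(size_t)(i - 1) * W + (j - 1)] + s;
      int up = F[(size_t)(i - 1) * W + j] + GAP;
      int left = F[(size_t)i * W + (j - 1)] + GAP;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F[(size_t)i * W + j] = best;
    }
  }
  int i = n, j = m, match = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      int s = (a[i - 1] == b[j - 1]) ? 1 : -1;
      if (F[(size_t)i * W + j] == F[(size_t)(i - 1) * W + (j - 1)] + s) {
        if (s == 1) ++match;
        --i; --j; ++cols;
        continue;
      }
    }
    if (i > 0 && F[(size_t)i * W + j] == F[(size_t)(i - 1) * W + j] + GAP) {
      --i; ++cols;
      continue;
    }
    --j; ++cols;
  }
  return (double)match / (double)cols;
}

// [[Rcpp::export]]
double nw_identity_cpp(std::string a, std::string b) {
  return identity_pair(a, b);
}

// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = identity_pair(s[i], s[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Agglomerative merge tree on a similarity (identity) matrix.
// linkage: 1 = MIN/single (cross-cluster max identity), 2 = MAX/complete
// (cross min), 3 = AVG/UPGMA (unweighted mean over all cross pairs).
// At every step the pair with the highest linkage identity is merged; ties
// (within tol) resolve to the lexicographically smallest (min-member-index)
// pair. Cluster labels are the minimum original member index, so a merged
// cluster keeps the smaller label. Returns (n-1) x 3: label_a, label_b
// (1-based, a < b), linkage identity at merge time.
// [[Rcpp::export]]
NumericMatrix merge_tree_cpp(NumericMatrix sim, int linkage, double tol) {
  const int n = sim.nrow();
  NumericMatrix out(std::max(n - 1, 0), 3);
  if (n <= 1) return out;
  std::vector<double> L((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) L[(size_t)i * n + j] = sim(i, j);
  std::vector<int> alive;   // ascending original-index labels
  std::vector<double> size((size_t)n, 1.0);
  alive.reserve(n);
  for (int i = 0; i < n; ++i) alive.push_back(i);

  for (int step = 0; step < n - 1; ++step) {
    double best = -2.0;
    int bi = -1, bj = -1; // positions in `alive`
    const int na = (int)alive.size();
    for (int p = 0; p < na; ++p) {
      const int i = alive[p];
      const double *row = &L[(size_t)i * n];
      for (int q = p + 1; q < na; ++q) {
        double v = row[alive[q]];
        if (v > best + tol) { best = v; bi = p; bj = q; }
        // ties keep the first (lexicographically smallest) pair
      }
    }
    const int a = alive[bi], b = alive[bj]; // a < b
    out(step, 0) = a + 1;
    out(step, 1) = b + 1;
    out(step, 2) = L[(size_t)a * n + b];
    const double sa = size[a], sb = size[b];
    for (int p = 0; p < na; ++p) {
      const int k = alive[p];
      if (k == a || k == b) continue;
      const double va = L[(size_t)a * n + k];
      const double vb = L[(size_t)b * n + k];
      double v;
      if (linkage == 1)      v = (va > vb) ? va : vb;
      else if (linkage == 2) v = (va < vb) ? va : vb;
      else                   v = (sa * va + sb * vb) / (sa + sb);
      L[(size_t)a * n + k] = v;
      L[(size_t)k * n + a] = v;
    }
    size[a] = sa + sb;
    alive.erase(alive.begin() + bj);
  }
  return out;
}

// Greedy centroid clustering over sequences processed in `order` (1-based
// indices into seqs). The first record founds cluster 1 and is its centroid;
// each later record joins the highest-identity centroid if that identity
// meets the cutoff (>= cutoff - tol), else founds a new cluster. Centroid
// ties resolve to the earliest-founded cluster.
// [[Rcpp::export]]
List greedy_assign_cpp(CharacterVector seqs, IntegerVector order,
                       double cutoff, double tol) {
  const int m = order.size();
  std::vector<std::string> s(seqs.size());
  for (int i = 0; i < (int)s.size(); ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector cluster(m);
  std::vector<int> centroids; // 0-based indices into seqs
  for (int t = 0; t < m; ++t) {
    const int idx = order[t] - 1;
    if (centroids.empty()) {
      centroids.push_back(idx);
      cluster[t] = 1;
      continue;
    }
    double best = -2.0;
    int bestc = -1;
    for (int c = 0; c < (int)centroids.size(); ++c) {
      double v = identity_pair(s[idx], s[centroids[c]]);
      if (v > best + tol) { best = v; bestc = c; }
      // ties keep the earlier-founded centroid
    }
    if (best >= cutoff - tol) {
      cluster[t] = bestc + 1;
    } else {
      centroids.push_back(idx);
      cluster[t] = (int)centroids.size();
    }
  }
  IntegerVector cent(centroids.size());
  for (int c = 0; c < (int)centroids.size(); ++c) cent[c] = centroids[c] + 1;
  return List::create(_["cluster"] = cluster, _["centroids"] = cent);
}
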