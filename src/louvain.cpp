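#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Generalized Louvain on a dense symmetric (modularity) matrix B.
// Maximizes sum_{i,j : g_i == g_j} B_ij (diagonal included).  The caller
// divides by the multilayer normalization 2*mu to obtain Q.
//
// Move phase: nodes visited in randomized order; a node adopts the
// community with the largest gain; moves with gain <= tol are rejected.
// Aggregation collapses communities into super-nodes and the phases repeat
// until the move phase makes no move.

static bool move_phase(const std::vector<double>& M, int n,
                       std::vector<int>& lab, std::mt19937& rng,
                       double tol) {
  bool any = false, improved = true;
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  std::vector<double> w(n);
  std::vector<int> touched;
  touched.reserve(n);
  while (improved) {
    improved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      touched.clear();
      const double* row = &M[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        int c = lab[j];
        if (w[c] == 0.0) touched.push_back(c);
        w[c] += row[j];
      }
      int cur = lab[i];
      if (w[cur] == 0.0) touched.push_back(cur); // ensure reset later
      double wcur = w[cur];
      int best = cur;
      double wbest = wcur;
      for (size_t k = 0; k < touched.size(); ++k) {
        int c = touched[k];
        if (c == cur) continue;
        if (w[c] > wbest + tol) { wbest = w[c]; best = c; }
      }
      if (best != cur && wbest - wcur > tol) {
        lab[i] = best;
        improved = true;
        any = true;
      }
      for (size_t k = 0; k < touched.size(); ++k) w[touched[k]] = 0.0;
      w[cur] = 0.0;
    }
  }
  return any;
}

// compact labels in-place to 0..k-1, return k
static int compact_labels(std::vector<int>& lab) {
  std::vector<int> map(lab.size(), -1);
  int k = 0;
  for (size_t i = 0; i < lab.size(); ++i) {
    if (map[lab[i]] < 0) map[lab[i]] = k++;
    lab[i] = map[lab[i]];
  }
  return k;
}

static double partition_total(const std::vector<double>& B, int n,
                              const std::vector<int>& lab) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* row = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      if (lab[i] == lab[j]) total += row[j];
  }
  return total;
}

// one full Louvain cycle (move + aggregate until no move) starting from
// an arbitrary node-level partition; labels updated in place
static bool louvain_cycle(const std::vector<double>& B, int n0,
                          std::vector<int>& node_lab, std::mt19937& rng,
                          double tol) {
  int k = compact_labels(node_lab);
  // first sweep at node level: refines single node assignments even
  // after earlier aggregation froze them into super-nodes
  bool any = move_phase(B, n0, node_lab, rng, tol);
  k = compact_labels(node_lab);
  while (k > 1) {
    // aggregate communities of the *original* matrix into super-nodes
    std::vector<double> M((size_t)k * k, 0.0);
    for (int i = 0; i < n0; ++i) {
      const double* row = &B[(size_t)i * n0];
      for (int j = 0; j < n0; ++j)
        M[(size_t)node_lab[i] * k + node_lab[j]] += row[j];
    }
    std::vector<int> sup(k);
    std::iota(sup.begin(), sup.end(), 0);
    if (!move_phase(M, k, sup, rng, tol)) break;
    any = true;
    for (int v = 0; v < n0; ++v) node_lab[v] = sup[node_lab[v]];
    int k2 = compact_labels(node_lab);
    if (k2 == k) break;
    k = k2;
  }
  return any;
}

// [[Rcpp::export]]
List cpp_louvain(NumericMatrix B, int seed, double tol = 1e-12) {
  int n0 = B.nrow();
  if (B.ncol() != n0) stop("B must be square");
  std::mt19937 rng((unsigned)seed);
  std::vector<double> Bv((size_t)n0 * n0);
  for (int j = 0; j < n0; ++j)
    for (int i = 0; i < n0; ++i)
      Bv[(size_t)i * n0 + j] = B(i, j);
  std::vector<int> lab(n0);
  std::iota(lab.begin(), lab.end(), 0);
  double total = partition_total(Bv, n0, lab);
  // iterate full cycles, each starting with a node-level refinement
  // sweep over the current partition, until the quality stops improving
  for (int it = 0; it < 100; ++it) {
    std::vector<int> cand(lab);
    bool any = louvain_cycle(Bv, n0, cand, rng, tol);
    double cand_total = partition_total(Bv, n0, cand);
    if (!any || cand_total <= total + tol) break;
    lab = cand;
    total = cand_total;
  }
  IntegerVector out(n0);
  for (int v = 0; v < n0; ++v) out[v] = lab[v] + 1;
  return List::create(_["labels"] = out, _["total"] = total);
}

// Exhaustive best partition of a dense symmetric matrix by restricted
// growth strings (set partitions).  Oracle for small instances; n <= 13.
static void bp_rec(const NumericMatrix& B, int i, int maxlab,
                   std::vector<int>& lab, double score,
                   double& best, std::vector<int>& bestlab) {
  int n = B.nrow();
  if (i == n) {
    if (score > best) { best = score; bestlab = lab; }
    return;
  }
  for (int c = 0; c <= maxlab; ++c) {
    double delta = B(i, i);
    for (int j = 0; j < i; ++j)
      if (lab[j] == c) delta += 2.0 * B(i, j);
    lab[i] = c;
    bp_rec(B, i + 1, std::max(maxlab, c + 1), lab, score + delta,
           best, bestlab);
  }
}

// [[Rcpp::export]]
List cpp_best_partition(NumericMatrix B) {
  int n = B.nrow();
  if (n > 13) stop("exhaustive search limited to n <= 13");
  std::vector<int> lab(n, 0), bestlab(n, 0);
  double best = -std::numeric_limits<double>::infinity();
  bp_rec(B, 0, 0, lab, 0.0, best, bestlab);
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = bestlab[v] + 1;
  return List::create(_["labels"] = out, _["total"] = best);
}
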