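#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Meta-path constrained random walks over a typed adjacency structure.
//
// adj_int:  per node, 1-based indices of neighbours reachable via an
//           interaction edge (always the opposite node type).
// adj_sim:  per node, 1-based indices of neighbours reachable via a
//           similarity edge (always the same node type).
// node_type: 1 = lncRNA, 2 = protein, per node.
// scheme:    sequence of types t_1..t_m with t_1 == t_m; the step from walk
//            position i uses scheme slot ((i-1) mod (m-1)); a step between
//            equal types traverses similarity edges, between different types
//            interaction edges (uniform over admissible neighbours).
// Walks start from every node of type t_1, num_walks times, and stop at
// walk_length nodes or at a dead end; dead-ended walks shorter than 2 nodes
// are discarded.
// [[Rcpp::export]]
List metapath_walks_cpp(List adj_int, List adj_sim, IntegerVector node_type,
                        IntegerVector scheme, int num_walks, int walk_length,
                        int seed) {
  int n = node_type.size();
  int m = scheme.size();
  if (m < 2 || scheme[0] != scheme[m - 1])
    stop("scheme must have length >= 2 with first type == last type");
  if (walk_length < m) stop("walk_length must be >= scheme length");

  std::vector<std::vector<int>> aint(n), asim(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector vi = adj_int[i];
    IntegerVector vs = adj_sim[i];
    aint[i].assign(vi.begin(), vi.end());
    asim[i].assign(vs.begin(), vs.end());
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<std::vector<int>> walks;
  int cycle = m - 1;

  for (int start = 0; start < n; ++start) {
    if (node_type[start] != scheme[0]) continue;
    for (int w = 0; w < num_walks; ++w) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start + 1);  // 1-based
      int cur = start;
      for (int pos = 1; pos < walk_length; ++pos) {
        int slot = (pos - 1) % cycle;           // scheme step slot
        int t_from = scheme[slot], t_to = scheme[slot + 1];
        const std::vector<int>& cand =
            (t_from == t_to) ? asim[cur] : aint[cur];
        if (cand.empty()) break;                // dead end
        std::uniform_int_distribution<int> pick(0, (int)cand.size() - 1);
        int nxt = cand[pick(rng)] - 1;
        if (node_type[nxt] != t_to) stop("adjacency/type inconsistency");
        walk.push_back(nxt + 1);
        cur = nxt;
      }
      if ((int)walk.size() >= 2) walks.push_back(std::move(walk));
    }
  }

  List out(walks.size());
  for (size_t i = 0; i < walks.size(); ++i)
    out[i] = IntegerVector(walks[i].begin(), walks[i].end());
  return out;
}
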