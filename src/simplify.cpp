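#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Genealogy-table simplification.
//
// Reduces node/edge tables to the ancestry of a set of sample nodes,
// retaining (besides the samples themselves) only nodes that are a most
// recent common ancestor of at least two samples on some genomic interval
// (unary ancestors are not retained). Samples are renumbered first, in the
// order given. The algorithm propagates per-node lists of ancestry segments
// (genomic interval -> output node) from the samples up through parents in
// order of decreasing birth time, coalescing wherever two or more segments
// overlap under one parent.

struct Seg {
  double l, r;
  int out;
};

// [[Rcpp::export]]
List simplify_cpp(int n_nodes, NumericVector node_time,
                  NumericVector edge_l, NumericVector edge_r,
                  IntegerVector edge_parent, IntegerVector edge_child,
                  IntegerVector samples, double L,
                  IntegerVector mut_node, NumericVector mut_pos) {
  int n_edges = edge_l.size();
  std::vector<std::vector<Seg>> A(n_nodes);
  std::vector<int> out_id(n_nodes, -1);
  std::vector<int> out_input;   // input id per output node
  std::vector<bool> is_sample(n_nodes, false);

  for (int i = 0; i < samples.size(); i++) {
    int s = samples[i];
    if (s < 0 || s >= n_nodes) stop("unknown node id in sample set");
    if (is_sample[s]) stop("duplicate node id in sample set");
    is_sample[s] = true;
    out_id[s] = i;
    out_input.push_back(s);
    A[s].push_back({0.0, L, i});
  }
  if (samples.size() == 0) stop("empty sample set");

  // group edges by parent
  std::vector<std::vector<int>> edges_of(n_nodes);
  for (int e = 0; e < n_edges; e++) edges_of[edge_parent[e]].push_back(e);

  // parents in decreasing birth-time order (children are born after parents)
  std::vector<int> order;
  order.reserve(n_nodes);
  for (int u = 0; u < n_nodes; u++)
    if (!edges_of[u].empty() || is_sample[u]) order.push_back(u);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (node_time[a] != node_time[b]) return node_time[a] > node_time[b];
    return a < b;
  });

  std::vector<double> oe_l, oe_r;
  std::vector<int> oe_p, oe_c;

  std::vector<Seg> S;
  std::vector<double> bp;
  for (int u : order) {
    if (edges_of[u].empty()) continue;  // sample leaf: ancestry already set
    S.clear();
    for (int e : edges_of[u]) {
      double l = edge_l[e], r = edge_r[e];
      for (const Seg &x : A[edge_child[e]]) {
        if (x.r > l && r > x.l)
          S.push_back({std::max(x.l, l), std::min(x.r, r), x.out});
      }
    }
    if (is_sample[u])
      S.push_back({0.0, L, out_id[u]});
    if (S.empty()) continue;

    bp.clear();
    for (const Seg &s : S) { bp.push_back(s.l); bp.push_back(s.r); }
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

    std::vector<Seg> anc;
    size_t edge_start = oe_l.size();
    for (size_t i = 0; i + 1 < bp.size(); i++) {
      double a = bp[i], b = bp[i + 1];
      int cnt = 0, single = -1;
      for (const Seg &s : S)
        if (s.l <= a && s.r >= b) { cnt++; single = s.out; }
      if (cnt == 0) continue;
      int map_to;
      if (cnt == 1 && !is_sample[u]) {
        map_to = single;  // unary pass-through: not retained
      } else {
        if (out_id[u] < 0) {
          out_id[u] = out_input.size();
          out_input.push_back(u);
        }
        int v = out_id[u];
        for (const Seg &s : S)
          if (s.l <= a && s.r >= b && s.out != v) {
            oe_l.push_back(a); oe_r.push_back(b);
            oe_p.push_back(v); oe_c.push_back(s.out);
          }
        map_to = v;
      }
      if (!anc.empty() && anc.back().out == map_to && anc.back().r == a)
        anc.back().r = b;
      else
        anc.push_back({a, b, map_to});
    }
    A[u] = std::move(anc);

    // squash this parent's output edges: sort by (child, left), merge abutting
    size_t n_new = oe_l.size() - edge_start;
    if (n_new > 1) {
      std::vector<int> idx(n_new);
      for (size_t i = 0; i < n_new; i++) idx[i] = edge_start + i;
      std::sort(idx.begin(), idx.end(), [&](int a, int b) {
        if (oe_c[a] != oe_c[b]) return oe_c[a] < oe_c[b];
        return oe_l[a] < oe_l[b];
      });
      std::vector<double> sl, sr;
      std::vector<int> sc;
      for (int i : idx) {
        if (!sc.empty() && sc.back() == oe_c[i] && sr.back() == oe_l[i]) {
          sr.back() = oe_r[i];
        } else {
          sl.push_back(oe_l[i]); sr.push_back(oe_r[i]); sc.push_back(oe_c[i]);
        }
      }
      oe_l.resize(edge_start); oe_r.resize(edge_start); oe_c.resize(edge_start);
      oe_p.resize(edge_start);
      for (size_t i = 0; i < sl.size(); i++) {
        oe_l.push_back(sl[i]); oe_r.push_back(sr[i]);
        oe_p.push_back(out_id[u]); oe_c.push_back(sc[i]);
      }
    }
  }

  int n_out = out_input.size();
  IntegerVector node_map(n_nodes, -1);
  for (int u = 0; u < n_nodes; u++) node_map[u] = out_id[u];
  IntegerVector node_input(n_out);
  NumericVector out_time(n_out);
  for (int v = 0; v < n_out; v++) {
    node_input[v] = out_input[v];
    out_time[v] = node_time[out_input[v]];
  }

  // map mutations through the final ancestry lists
  int n_mut = mut_node.size();
  IntegerVector mut_map(n_mut, -1);
  for (int m = 0; m < n_mut; m++) {
    int u = mut_node[m];
    double p = mut_pos[m];
    for (const Seg &s : A[u])
      if (s.l <= p && p < s.r) { mut_map[m] = s.out; break; }
  }

  return List::create(
    _["node_map"] = node_map,
    _["node_input"] = node_input,
    _["node_time"] = out_time,
    _["edge_l"] = NumericVector(oe_l.begin(), oe_l.end()),
    _["edge_r"] = NumericVector(oe_r.begin(), oe_r.end()),
    _["edge_parent"] = IntegerVector(oe_p.begin(), oe_p.end()),
    _["edge_child"] = IntegerVector(oe_c.begin(), oe_c.end()),
    _["mut_map"] = mut_map);
}
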