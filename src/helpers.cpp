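#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sweep over the marginal trees of an edge table (left-to-right edge
// insertion/removal) and, for every site, count the sample nodes descending
// from the node carrying the site's mutation. Returns per-set derived-allele
// counts and, optionally, per-sample 0/1 genotypes.
//
// site_pos must be sorted ascending; set_id / col_id give, per node, the
// statistic set (or genotype column) it belongs to, -1 otherwise.

// [[Rcpp::export]]
List site_descent_cpp(int n_nodes,
                      NumericVector edge_l, NumericVector edge_r,
                      IntegerVector edge_parent, IntegerVector edge_child,
                      NumericVector site_pos, IntegerVector site_node,
                      IntegerVector set_id, int n_sets,
                      bool want_geno, IntegerVector col_id, int n_cols) {
  int E = edge_l.size(), S = site_pos.size();
  std::vector<int> in_order(E), out_order(E);
  for (int e = 0; e < E; e++) in_order[e] = out_order[e] = e;
  std::sort(in_order.begin(), in_order.end(), [&](int a, int b) {
    return edge_l[a] < edge_l[b];
  });
  std::sort(out_order.begin(), out_order.end(), [&](int a, int b) {
    return edge_r[a] < edge_r[b];
  });

  std::vector<std::vector<int>> children(n_nodes);
  IntegerMatrix counts(S, n_sets);
  IntegerMatrix geno(want_geno ? S : 0, want_geno ? n_cols : 0);

  int ii = 0, oi = 0;
  std::vector<int> stack;
  for (int s = 0; s < S; s++) {
    double x = site_pos[s];
    while (oi < E && edge_r[out_order[oi]] <= x) {
      int e = out_order[oi++];
      auto &ch = children[edge_parent[e]];
      auto it = std::find(ch.begin(), ch.end(), edge_child[e]);
      if (it != ch.end()) ch.erase(it);  // skip edges that were never inserted
    }
    while (ii < E && edge_l[in_order[ii]] <= x) {
      int e = in_order[ii++];
      if (edge_r[e] > x) children[edge_parent[e]].push_back(edge_child[e]);
    }
    // DFS from the mutation's node
    stack.clear();
    stack.push_back(site_node[s]);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      if (set_id[u] >= 0) counts(s, set_id[u])++;
      if (want_geno && col_id[u] >= 0) geno(s, col_id[u]) = 1;
      for (int c : children[u]) stack.push_back(c);
    }
  }
  return List::create(_["counts"] = counts, _["geno"] = geno);
}

// Number of same-population neighbors within distance r (self excluded).
// [[Rcpp::export]]
IntegerVector neighbor_counts_cpp(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  IntegerVector out(n, 0);
  double r2 = r * r;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) { out[i]++; out[j]++; }
    }
  }
  return out;
}

// Mean nearest-neighbor distance statistics (used for spatial dispersion).
// [[Rcpp::export]]
NumericVector nearest_neighbor_dist_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int j = 0; j < n; j++) {
      if (i == j) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each offspring (whose first parent sits at (px, py)), choose a mate
// uniformly among candidates within the mating radius (excluding the first
// parent itself, given by self_idx); if no candidate is in range, the
// nearest candidate is used. Reservoir sampling keeps this single-pass;
// draws come from R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector choose_mates_cpp(NumericVector px, NumericVector py,
                               NumericVector cx, NumericVector cy,
                               IntegerVector self_idx, double r_m) {
  int n = px.size(), m = cx.size();
  IntegerVector out(n, -1);
  double r2 = r_m * r_m;
  for (int i = 0; i < n; i++) {
    int chosen = -1, k = 0, nearest = -1;
    double best = R_PosInf;
    for (int j = 0; j < m; j++) {
      if (j == self_idx[i]) continue;
      double dx = cx[j] - px[i], dy = cy[j] - py[i];
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        k++;
        if (unif_rand() * k < 1.0) chosen = j;
      }
      if (d2 < best) { best = d2; nearest = j; }
    }
    out[i] = (chosen >= 0) ? chosen : nearest;
  }
  return out;
}

// Maximum number of genealogical roots over all marginal trees: 1 means the
// sample set is fully coalesced at every position. Sweeps edge insertions
// and removals left-to-right, maintaining per-node active parent/child
// counts; a node is present if it is a sample or touches an active edge.
// [[Rcpp::export]]
int max_marginal_roots_cpp(int n_nodes,
                           NumericVector edge_l, NumericVector edge_r,
                           IntegerVector edge_parent, IntegerVector edge_child,
                           IntegerVector samples, double L) {
  int E = edge_l.size();
  std::vector<int> in_order(E), out_order(E);
  for (int e = 0; e < E; e++) in_order[e] = out_order[e] = e;
  std::sort(in_order.begin(), in_order.end(), [&](int a, int b) {
    return edge_l[a] < edge_l[b];
  });
  std::sort(out_order.begin(), out_order.end(), [&](int a, int b) {
    return edge_r[a] < edge_r[b];
  });
  std::vector<int> parent_cnt(n_nodes, 0), child_cnt(n_nodes, 0);
  std::vector<bool> is_sample(n_nodes, false);
  for (int i = 0; i < samples.size(); i++) is_sample[samples[i]] = true;

  auto is_root = [&](int u) {
    bool present = is_sample[u] || parent_cnt[u] > 0 || child_cnt[u] > 0;
    return present && parent_cnt[u] == 0;
  };

  int n_roots = 0;
  for (int u = 0; u < n_nodes; u++) if (is_root(u)) n_roots++;
  int max_roots = 0;
  int ii = 0, oi = 0;
  double x = 0.0;
  while (ii < E || oi < E) {
    // process all events at position x
    while (oi < E && edge_r[out_order[oi]] <= x) {
      int e = out_order[oi++];
      int p = edge_parent[e], c = edge_child[e];
      bool rp = is_root(p), rc = is_root(c);
      child_cnt[p]--; parent_cnt[c]--;
      n_roots += (is_root(p) - rp) + (is_root(c) - rc);
    }
    while (ii < E && edge_l[in_order[ii]] <= x) {
      int e = in_order[ii++];
      int p = edge_parent[e], c = edge_child[e];
      bool rp = is_root(p), rc = is_root(c);
      child_cnt[p]++; parent_cnt[c]++;
      n_roots += (is_root(p) - rp) + (is_root(c) - rc);
    }
    if (x < L && n_roots > max_roots) max_roots = n_roots;
    // advance to the next event position
    double nx = R_PosInf;
    if (ii < E) nx = std::min(nx, edge_l[in_order[ii]]);
    if (oi < E) nx = std::min(nx, edge_r[out_order[oi]]);
    if (nx == R_PosInf) break;
    x = nx;
  }
  return max_roots;
}

// Even-odd point-in-polygon test with the closed-set convention: points
// within eps*scale of the boundary count as inside.
// [[Rcpp::export]]
LogicalVector pip_cpp(NumericVector px, NumericVector py,
                      NumericVector vx, NumericVector vy, double eps) {
  int n = px.size(), m = vx.size();
  LogicalVector out(n);
  double scale = 1.0;
  for (int i = 0; i < m; i++) {
    scale = std::max(scale, std::fabs(vx[i]));
    scale = std::max(scale, std::fabs(vy[i]));
  }
  double tol2 = (eps * scale) * (eps * scale);
  for (int i = 0; i < n; i++) {
    double x = px[i], y = py[i];
    bool inside = false, onb = false;
    int j = m - 1;
    for (int k = 0; k < m; k++) {
      double ax = vx[j], ay = vy[j], bx = vx[k], by = vy[k];
      if (((by > y) != (ay > y)) &&
          (x < (ax - bx) * (y - by) / (ay - by) + bx))
        inside = !inside;
      if (!onb) {
        double dx = bx - ax, dy = by - ay;
        double len2 = dx * dx + dy * dy;
        double t = len2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        double ex = x - (ax + t * dx), ey = y - (ay + t * dy);
        if (ex * ex + ey * ey <= tol2) onb = true;
      }
      j = k;
    }
    out[i] = inside || onb;
  }
  return out;
}
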