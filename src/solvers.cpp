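#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
using namespace Rcpp;

// Axial-coordinate offsets of the six triangular-lattice neighbours.
static const int DQ[6] = {1, -1, 0, 0, 1, -1};
static const int DR[6] = {0, 0, 1, -1, -1, 1};

// ---------------------------------------------------------------------------
// Exact oracle: branch-and-bound over self-avoiding walks.
//
// Symmetry reduction: the first step is fixed to (+1, 0); the first step that
// leaves the q-axis is restricted to the upper half-plane (offsets (0,1) and
// (-1,1)), quotienting out the reflection across the axis.  Pruning uses the
// admissible bound that every yet-unplaced interior H can contribute at most
// 4 new bonds (6 neighbours minus 2 chain neighbours) and a terminal H at
// most 5.
// ---------------------------------------------------------------------------

namespace {

struct OracleCtx {
  int n;
  std::vector<int> isH;     // 0/1 per position
  std::vector<int> grid;    // occupancy: position index + 1, 0 = empty
  int size, centre;         // grid is size x size, walk starts at centre
  std::vector<int> qs, rs;  // current walk
  std::vector<int> suffix;  // suffix[i] = admissible bound on bonds from positions >= i
  int best;
  std::vector<int> best_qs, best_rs;
  double states;

  int cell(int q, int r) const { return (q + centre) * size + (r + centre); }

  void dfs(int i, int q, int r, int bonds, bool mirror_broken) {
    ++states;
    if (i == n) {
      if (bonds > best) {
        best = bonds;
        best_qs = qs; best_rs = rs;
      }
      return;
    }
    if (bonds + suffix[i] <= best) return;
    for (int d = 0; d < 6; ++d) {
      int nq = q + DQ[d], nr = r + DR[d];
      bool broken = mirror_broken;
      if (!broken) {
        if (nr > 0) {
          broken = true;           // first move off the axis: upper half only
        } else if (nr < 0) {
          continue;                // mirror image, skip
        }
      }
      int c = cell(nq, nr);
      if (grid[c] != 0) continue;
      int add = 0;
      if (isH[i]) {
        for (int e = 0; e < 6; ++e) {
          int j = grid[cell(nq + DQ[e], nr + DR[e])];
          if (j > 0 && j - 1 != i - 1 && isH[j - 1]) ++add;
        }
      }
      grid[c] = i + 1;
      qs.push_back(nq); rs.push_back(nr);
      dfs(i + 1, nq, nr, bonds + add, broken);
      qs.pop_back(); rs.pop_back();
      grid[c] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_enumerate_optimal(LogicalVector is_h) {
  int n = is_h.size();
  if (n < 1) stop("empty string");
  OracleCtx ctx;
  ctx.n = n;
  ctx.isH.assign(n, 0);
  for (int i = 0; i < n; ++i) ctx.isH[i] = is_h[i] ? 1 : 0;
  ctx.size = 2 * n + 5;
  ctx.centre = n + 2;
  ctx.grid.assign((size_t)ctx.size * ctx.size, 0);
  ctx.suffix.assign(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) {
    int cap = ctx.isH[i] ? (i == n - 1 ? 5 : 4) : 0;
    ctx.suffix[i] = ctx.suffix[i + 1] + cap;
  }
  ctx.best = -1;
  ctx.states = 0.0;

  ctx.grid[ctx.cell(0, 0)] = 1;
  ctx.qs.push_back(0); ctx.rs.push_back(0);
  if (n == 1) {
    ctx.best = 0;
    ctx.best_qs = ctx.qs; ctx.best_rs = ctx.rs;
    ctx.states = 1.0;
  } else {
    // fix the first step to (+1, 0)
    ctx.grid[ctx.cell(1, 0)] = 2;
    ctx.qs.push_back(1); ctx.rs.push_back(0);
    ctx.dfs(2, 1, 0, 0, false);
    if (ctx.best < 0) { // n == 2 falls straight through dfs at i == n
      ctx.best = 0;
      ctx.best_qs = ctx.qs; ctx.best_rs = ctx.rs;
    }
  }
  return List::create(
    _["optimal_bonds"] = ctx.best,
    _["q"] = wrap(ctx.best_qs),
    _["r"] = wrap(ctx.best_rs),
    _["states_explored"] = ctx.states);
}

// ---------------------------------------------------------------------------
// Hamiltonian path on a point set with fixed start and optional end set.
// DFS in canonical (r, q) neighbour order with two admissible prunes:
//  * the unvisited points must stay connected (single BFS component);
//  * at most one unvisited point may have a single unvisited neighbour, and
//    such a point must be an allowed endpoint reachable last.
// ---------------------------------------------------------------------------

namespace {

struct HamCtx {
  int n;
  std::vector<std::array<int, 6> > adj; // neighbour indices, -1 padded
  std::vector<int> deg;
  std::vector<char> visited;
  std::vector<char> is_end;
  bool any_end;
  std::vector<int> path;
  double budget, states;
  bool found;

  bool prune(int current) {
    int remaining = n - (int)path.size();
    if (remaining == 0) return false;
    // connectivity of unvisited points, seeded from any unvisited neighbour
    // of the current point
    int seed = -1;
    for (int k = 0; k < 6; ++k) {
      int v = adj[current][k];
      if (v >= 0 && !visited[v]) { seed = v; break; }
    }
    if (seed < 0) return true;
    std::vector<int> stack;
    std::vector<char> seen(n, 0);
    stack.push_back(seed); seen[seed] = 1;
    int count = 0;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      ++count;
      for (int k = 0; k < 6; ++k) {
        int v = adj[u][k];
        if (v >= 0 && !visited[v] && !seen[v]) { seen[v] = 1; stack.push_back(v); }
      }
    }
    if (count != remaining) return true;
    // degree-based endpoint prune: an unvisited point with a single free
    // neighbour (and no edge to the current point) must be the path's final
    // vertex, so there can be at most one and it must be an allowed end.
    int tight = 0;
    int singles = 0;
    for (int u = 0; u < n; ++u) {
      if (visited[u]) continue;
      int free_nb = 0;
      bool touches_current = false;
      for (int k = 0; k < 6; ++k) {
        int v = adj[u][k];
        if (v < 0) continue;
        if (v == current) touches_current = true;
        if (!visited[v]) ++free_nb;
      }
      if (free_nb == 0 && !(touches_current && remaining == 1)) return true;
      if (free_nb == 1 && !touches_current) {
        if (any_end && !is_end[u]) ++tight; else ++singles;
      }
    }
    if (singles + tight > 1) return true;
    if (any_end && tight > 0) return true;
    return false;
  }

  void dfs(int u) {
    if (found || states > budget) return;
    ++states;
    if ((int)path.size() == n) {
      if (!any_end || is_end[u]) found = true;
      return;
    }
    if (prune(u)) return;
    for (int k = 0; k < 6 && !found; ++k) {
      int v = adj[u][k];
      if (v < 0 || visited[v]) continue;
      visited[v] = 1;
      path.push_back(v);
      dfs(v);
      if (!found) { path.pop_back(); visited[v] = 0; }
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_hamiltonian_path(IntegerVector q, IntegerVector r,
                                   int start, IntegerVector ends,
                                   double budget) {
  int n = q.size();
  if (n == 0) return IntegerVector(0);
  // index points by key for adjacency lookup
  std::map<long long, int> index;
  for (int i = 0; i < n; ++i) {
    long long key = (long long)(q[i] + 4096) * 8192 + (r[i] + 4096);
    index[key] = i;
  }
  HamCtx ctx;
  ctx.n = n;
  ctx.adj.assign(n, std::array<int, 6>());
  ctx.deg.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int d = 0; d < 6; ++d) {
      long long key = (long long)(q[i] + DQ[d] + 4096) * 8192 + (r[i] + DR[d] + 4096);
      std::map<long long, int>::iterator it = index.find(key);
      if (it != index.end()) ctx.adj[i][m++] = it->second;
    }
    ctx.deg[i] = m;
    for (; m < 6; ++m) ctx.adj[i][m] = -1;
  }
  ctx.visited.assign(n, 0);
  ctx.is_end.assign(n, 0);
  ctx.any_end = ends.size() > 0;
  for (int i = 0; i < ends.size(); ++i) ctx.is_end[ends[i] - 1] = 1; // 1-based
  ctx.budget = budget;
  ctx.states = 0.0;
  ctx.found = false;
  int s = start - 1; // 1-based
  ctx.visited[s] = 1;
  ctx.path.push_back(s);
  ctx.dfs(s);
  if (!ctx.found) return IntegerVector(0);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ctx.path[i] + 1;
  return out;
}
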