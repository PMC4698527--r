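#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Log-rank survival tree growing. Exhaustive cutoff search is the hot
// path (every midpoint of every candidate variable at every node), so it
// lives here; tree bookkeeping stays thin and is re-exposed to R as plain
// vectors.

namespace {

struct EventGroup {
  int first;   // first index (in time-sorted order) with T >= t_l
  int len;     // run length of this distinct time value
  int deaths;  // events at t_l
};

struct NodeScan {
  int nn;
  std::vector<int> ord_t;            // node positions sorted by time
  std::vector<EventGroup> groups;    // distinct event times only
  int total_deaths;
};

// Build time ordering and per-event-time risk/death table for one node.
// t, ev are node-local arrays of length nn.
void build_scan(const std::vector<double>& t, const std::vector<int>& ev,
                NodeScan& sc) {
  int nn = t.size();
  sc.nn = nn;
  sc.ord_t.resize(nn);
  for (int i = 0; i < nn; ++i) sc.ord_t[i] = i;
  std::sort(sc.ord_t.begin(), sc.ord_t.end(),
            [&](int a, int b) { return t[a] < t[b]; });
  sc.groups.clear();
  sc.total_deaths = 0;
  int i = 0;
  while (i < nn) {
    int j = i;
    double tv = t[sc.ord_t[i]];
    int d = 0;
    while (j < nn && t[sc.ord_t[j]] == tv) {
      d += ev[sc.ord_t[j]];
      ++j;
    }
    if (d > 0) {
      EventGroup g;
      g.first = i;
      g.len = j - i;
      g.deaths = d;
      sc.groups.push_back(g);
      sc.total_deaths += d;
    }
    i = j;
  }
}

// Two-sample log-rank chi-square for a given left-membership indicator.
// Zero hypergeometric variance => 0 by convention.
double logrank_stat(const NodeScan& sc, const std::vector<int>& ev,
                    const std::vector<char>& in_left,
                    std::vector<int>& suff_left) {
  int nn = sc.nn;
  suff_left[nn] = 0;
  for (int i = nn - 1; i >= 0; --i)
    suff_left[i] = suff_left[i + 1] + (in_left[sc.ord_t[i]] ? 1 : 0);
  double O1 = 0.0, E1 = 0.0, V = 0.0;
  for (const EventGroup& g : sc.groups) {
    int Y = nn - g.first;
    int Y1 = suff_left[g.first];
    int d1 = 0;
    for (int k = g.first; k < g.first + g.len; ++k) {
      int pos = sc.ord_t[k];
      if (ev[pos] && in_left[pos]) ++d1;
    }
    double p = (double)Y1 / Y;
    O1 += d1;
    E1 += g.deaths * p;
    if (Y > 1)
      V += g.deaths * p * (1.0 - p) * (double)(Y - g.deaths) / (Y - 1);
  }
  if (V <= 1e-12) return 0.0;
  double diff = O1 - E1;
  return diff * diff / V;
}

struct BestSplit {
  int var = -1;          // 0-based column, -1 = none
  double thr = NA_REAL;
  double stat = -1.0;
  bool found = false;
};

// Scan every admissible cutoff of the candidate variables; keep the split
// maximising the log-rank statistic. Ties keep the first candidate in
// (ascending variable index, ascending cutoff) order.
BestSplit best_split_node(const NumericMatrix& X,
                          const std::vector<int>& rows,  // global rows
                          const std::vector<double>& t,
                          const std::vector<int>& ev,
                          const std::vector<int>& cand,  // sorted, 0-based
                          int min_size, int min_deaths) {
  BestSplit best;
  int nn = rows.size();
  if (nn < 2 * min_size) return best;
  NodeScan sc;
  build_scan(t, ev, sc);
  if (sc.total_deaths < 2 * min_deaths) return best;

  std::vector<int> ord_x(nn), suff_left(nn + 1);
  std::vector<char> in_left(nn);
  std::vector<double> xv(nn);

  for (int ci = 0; ci < (int)cand.size(); ++ci) {
    int v = cand[ci];
    for (int i = 0; i < nn; ++i) xv[i] = X(rows[i], v);
    for (int i = 0; i < nn; ++i) ord_x[i] = i;
    std::sort(ord_x.begin(), ord_x.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    if (xv[ord_x[0]] == xv[ord_x[nn - 1]]) continue;  // constant in node
    std::fill(in_left.begin(), in_left.end(), 0);
    int deaths_left = 0;
    for (int k = 1; k < nn; ++k) {
      int pos = ord_x[k - 1];
      in_left[pos] = 1;
      deaths_left += ev[pos];
      if (xv[pos] == xv[ord_x[k]]) continue;  // not a boundary
      if (k < min_size || nn - k < min_size) continue;
      if (deaths_left < min_deaths || sc.total_deaths - deaths_left < min_deaths)
        continue;
      double stat = logrank_stat(sc, ev, in_left, suff_left);
      if (stat > best.stat) {
        best.stat = stat;
        best.var = v;
        best.thr = (xv[pos] + xv[ord_x[k]]) / 2.0;
        best.found = true;
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cpp_best_split(NumericVector time, IntegerVector status, NumericMatrix X,
                    IntegerVector rows0, IntegerVector cand0,
                    int min_size, int min_deaths) {
  std::vector<int> rows(rows0.begin(), rows0.end());
  int nn = rows.size();
  std::vector<double> t(nn);
  std::vector<int> ev(nn);
  for (int i = 0; i < nn; ++i) {
    t[i] = time[rows[i]];
    ev[i] = status[rows[i]];
  }
  std::vector<int> cand(cand0.begin(), cand0.end());
  std::sort(cand.begin(), cand.end());
  BestSplit b = best_split_node(X, rows, t, ev, cand, min_size, min_deaths);
  return List::create(_["found"] = b.found, _["var"] = b.var,
                      _["threshold"] = b.thr, _["statistic"] = b.stat);
}

// Grow a full tree. rows0 are 0-based global row indices (bootstrap
// multiplicity allowed). mtry = 0 means all variables; otherwise mtry
// variables are drawn fresh at every node via R's RNG.
// [[Rcpp::export]]
List cpp_grow_tree(NumericVector time, IntegerVector status, NumericMatrix X,
                   IntegerVector rows0, int mtry, int min_size,
                   int min_deaths) {
  int p = X.ncol();
  int n_elem = rows0.size();

  std::vector<int> node_var;
  std::vector<double> node_thr, node_stat;
  std::vector<int> node_left, node_right, node_n, node_deaths;
  IntegerVector leaf_of(n_elem, -1);

  struct Work {
    int id;
    std::vector<int> elems;  // indices into rows0
  };
  std::vector<Work> stack;

  auto new_node = [&](const std::vector<int>& elems) {
    int id = node_var.size();
    node_var.push_back(-1);
    node_thr.push_back(NA_REAL);
    node_stat.push_back(NA_REAL);
    node_left.push_back(-1);
    node_right.push_back(-1);
    int d = 0;
    for (int e : elems) d += status[rows0[e]];
    node_n.push_back((int)elems.size());
    node_deaths.push_back(d);
    return id;
  };

  std::vector<int> all(n_elem);
  for (int i = 0; i < n_elem; ++i) all[i] = i;
  int root = new_node(all);
  stack.push_back({root, std::move(all)});

  std::vector<int> cand_all(p);
  for (int v = 0; v < p; ++v) cand_all[v] = v;

  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    int nn = w.elems.size();

    std::vector<int> rows(nn);
    std::vector<double> t(nn);
    std::vector<int> ev(nn);
    for (int i = 0; i < nn; ++i) {
      rows[i] = rows0[w.elems[i]];
      t[i] = time[rows[i]];
      ev[i] = status[rows[i]];
    }

    std::vector<int> cand;
    if (mtry <= 0 || mtry >= p) {
      cand = cand_all;
    } else {
      IntegerVector s = sample(p, mtry, false);  // R's RNG, 1-based
      cand.resize(mtry);
      for (int i = 0; i < mtry; ++i) cand[i] = s[i] - 1;
      std::sort(cand.begin(), cand.end());
    }

    BestSplit b = best_split_node(X, rows, t, ev, cand, min_size, min_deaths);
    if (!b.found) {
      for (int e : w.elems) leaf_of[e] = w.id;
      continue;
    }

    std::vector<int> le, re;
    for (int i = 0; i < nn; ++i) {
      if (X(rows[i], b.var) <= b.thr)
        le.push_back(w.elems[i]);
      else
        re.push_back(w.elems[i]);
    }
    node_var[w.id] = b.var;
    node_thr[w.id] = b.thr;
    node_stat[w.id] = b.stat;
    int lid = new_node(le);
    int rid = new_node(re);
    node_left[w.id] = lid;
    node_right[w.id] = rid;
    // push right first so the left child is processed (and numbered deeper
    // nodes) first: deterministic preorder-ish layout
    stack.push_back({rid, std::move(re)});
    stack.push_back({lid, std::move(le)});
  }

  return List::create(
      _["var"] = wrap(node_var), _["threshold"] = wrap(node_thr),
      _["statistic"] = wrap(node_stat), _["left"] = wrap(node_left),
      _["right"] = wrap(node_right), _["n"] = wrap(node_n),
      _["n_events"] = wrap(node_deaths), _["leaf_of"] = leaf_of);
}

// Route rows of X through a tree; returns 0-based leaf node ids.
// [[Rcpp::export]]
IntegerVector cpp_predict_leaf(IntegerVector var, NumericVector thr,
                               IntegerVector left, IntegerVector right,
                               NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = node;
  }
  return out;
}
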