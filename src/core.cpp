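#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Longest non-decreasing subsequence via patience sorting.
// upper_bound (right insertion) makes ties extend a run, so markers in the
// same recombination bin all count toward colinearity.
static int lnds(const std::vector<double>& x) {
  std::vector<double> tails;
  tails.reserve(x.size());
  for (double v : x) {
    std::vector<double>::iterator it =
      std::upper_bound(tails.begin(), tails.end(), v);
    if (it == tails.end()) tails.push_back(v);
    else *it = v;
  }
  return (int)tails.size();
}

static int lms_vec(const std::vector<double>& x) {
  std::vector<double> neg(x.size());
  for (size_t i = 0; i < x.size(); ++i) neg[i] = -x[i];
  int inc = lnds(x);
  int dec = lnds(neg);
  return inc > dec ? inc : dec;
}

// [[Rcpp::export]]
int lnds_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  return lnds(v);
}

// [[Rcpp::export]]
int lms_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  return lms_vec(v);
}

// Concatenate per-scaffold map positions following a signed permutation and
// return the LMS length for one map.  fwd[i] holds map positions of scaffold
// i sorted by ascending physical position; rev[i] the same reversed.
static int map_lms(const IntegerVector& perm, const IntegerVector& signs,
                   const List& fwd, const List& rev) {
  std::vector<double> seq;
  for (int k = 0; k < perm.size(); ++k) {
    int i = perm[k] - 1;
    NumericVector m = (signs[i] < 0) ? as<NumericVector>(rev[i])
                                     : as<NumericVector>(fwd[i]);
    for (int t = 0; t < m.size(); ++t) seq.push_back(m[t]);
  }
  return lms_vec(seq);
}

// Per-map LMS lengths for a signed permutation over all maps.
// [[Rcpp::export]]
IntegerVector config_lms_cpp(IntegerVector perm, IntegerVector signs,
                             List maps_fwd, List maps_rev) {
  int nm = maps_fwd.size();
  IntegerVector out(nm);
  for (int j = 0; j < nm; ++j)
    out[j] = map_lms(perm, signs, as<List>(maps_fwd[j]), as<List>(maps_rev[j]));
  return out;
}

// Weighted L score (fitness) for a signed permutation.
// [[Rcpp::export]]
double score_config_cpp(IntegerVector perm, IntegerVector signs,
                        List maps_fwd, List maps_rev, NumericVector weights) {
  double total = 0.0;
  for (int j = 0; j < maps_fwd.size(); ++j)
    total += weights[j] *
      map_lms(perm, signs, as<List>(maps_fwd[j]), as<List>(maps_rev[j]));
  return total;
}

// Evaluate L for each row of a permutation matrix (one GA generation).
// [[Rcpp::export]]
NumericVector score_population_cpp(IntegerMatrix perms, IntegerVector signs,
                                   List maps_fwd, List maps_rev,
                                   NumericVector weights) {
  int npop = perms.nrow();
  NumericVector out(npop);
  for (int r = 0; r < npop; ++r) {
    IntegerVector p = perms(r, _);
    out[r] = score_config_cpp(p, signs, maps_fwd, maps_rev, weights);
  }
  return out;
}

// Evaluate L for each (permutation, sign vector) pair; signs are indexed
// by canonical scaffold id, one row per individual.
// [[Rcpp::export]]
NumericVector score_population_signed_cpp(IntegerMatrix perms,
                                          IntegerMatrix signs,
                                          List maps_fwd, List maps_rev,
                                          NumericVector weights) {
  int npop = perms.nrow();
  NumericVector out(npop);
  for (int r = 0; r < npop; ++r) {
    IntegerVector p = perms(r, _);
    IntegerVector s = signs(r, _);
    out[r] = score_config_cpp(p, s, maps_fwd, maps_rev, weights);
  }
  return out;
}

// Partially mapped crossover: child inherits p1[i..j] (1-based, inclusive)
// and takes the remaining genes from p2, resolving conflicts through the
// segment mapping p1[k] <-> p2[k].
// [[Rcpp::export]]
IntegerVector pmx_cpp(IntegerVector p1, IntegerVector p2, int i, int j) {
  int n = p1.size();
  if (i < 1 || j > n || i > j) stop("invalid PMX cut points");
  IntegerVector child(n);
  std::vector<int> pos1(n + 1);
  for (int k = 0; k < n; ++k) pos1[p1[k]] = k;
  for (int k = i - 1; k <= j - 1; ++k) child[k] = p1[k];
  for (int k = 0; k < n; ++k) {
    if (k >= i - 1 && k <= j - 1) continue;
    int v = p2[k];
    int guard = 0;
    while (pos1[v] >= i - 1 && pos1[v] <= j - 1) {
      v = p2[pos1[v]];
      if (++guard > n) stop("PMX mapping cycle"); // cannot happen for valid perms
    }
    child[k] = v;
  }
  return child;
}

// ---- TSP path heuristic ------------------------------------------------
// Hamiltonian path through all nodes minimizing the sum of adjacent
// distances.  Reduced to cyclic TSP with a dummy node at zero distance to
// every city, then solved by multi-start nearest-neighbour construction
// followed by 2-opt and Or-opt (segment lengths 1-3) to local optimality.
// Fully deterministic: fixed start set, ties broken by lowest index.

static std::vector<int> nn_tour(const std::vector<std::vector<double> >& d,
                                int m, int start) {
  std::vector<int> tour;
  std::vector<bool> used(m, false);
  int cur = start;
  used[cur] = true;
  tour.push_back(cur);
  for (int step = 0; step < m - 1; ++step) {
    int best = -1;
    double bd = 0.0;
    for (int c = 0; c < m; ++c) {
      if (used[c]) continue;
      if (best < 0 || d[cur][c] < bd) { best = c; bd = d[cur][c]; }
    }
    used[best] = true;
    tour.push_back(best);
    cur = best;
  }
  return tour;
}

static double cycle_cost(const std::vector<int>& tour,
                         const std::vector<std::vector<double> >& d) {
  double s = 0.0;
  int m = (int)tour.size();
  for (int k = 0; k < m; ++k) s += d[tour[k]][tour[(k + 1) % m]];
  return s;
}

// 2-opt + Or-opt local search to a local optimum, in place
static void improve_tour(std::vector<int>& tour,
                         const std::vector<std::vector<double> >& d) {
  int m = (int)tour.size();
  const double eps = 1e-12;
  bool improved = true;
  while (improved) {
    improved = false;
    // 2-opt: reverse tour[i..k]
    for (int i = 1; i < m - 1 && !improved; ++i) {
      for (int k = i + 1; k < m && !improved; ++k) {
        int a = tour[i - 1], b = tour[i];
        int c = tour[k], e = tour[(k + 1) % m];
        double delta = d[a][c] + d[b][e] - d[a][b] - d[c][e];
        if (delta < -eps) {
          std::reverse(tour.begin() + i, tour.begin() + k + 1);
          improved = true;
        }
      }
    }
    if (improved) continue;
    // Or-opt: move a segment of length 1..3 elsewhere (both directions)
    for (int seg = 1; seg <= 3 && !improved; ++seg) {
      for (int i = 1; i + seg <= m && !improved; ++i) {
        int p = tour[i - 1], s0 = tour[i], s1 = tour[i + seg - 1];
        int q = tour[(i + seg) % m];
        double removal = d[p][s0] + d[s1][q] - d[p][q];
        for (int k = 0; k < m && !improved; ++k) {
          if (k >= i - 1 && k <= i + seg - 1) continue;
          int u = tour[k], v = tour[(k + 1) % m];
          if ((k + 1) % m == i - 1 || k == (i + seg) % m) continue;
          double fwd = d[u][s0] + d[s1][v] - d[u][v];
          double bwd = d[u][s1] + d[s0][v] - d[u][v];
          bool flip = bwd < fwd;
          double ins = flip ? bwd : fwd;
          if (ins - removal < -eps) {
            std::vector<int> seg_nodes(tour.begin() + i,
                                       tour.begin() + i + seg);
            if (flip) std::reverse(seg_nodes.begin(), seg_nodes.end());
            std::vector<int> rest;
            rest.reserve(m - seg);
            for (int t = 0; t < m; ++t)
              if (t < i || t >= i + seg) rest.push_back(tour[t]);
            std::vector<int> nt;
            nt.reserve(m);
            for (size_t t = 0; t < rest.size(); ++t) {
              nt.push_back(rest[t]);
              if (rest[t] == u)
                nt.insert(nt.end(), seg_nodes.begin(), seg_nodes.end());
            }
            tour = nt;
            improved = true;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector tsp_path_cpp(NumericMatrix D) {
  int n = D.nrow();
  if (n == 0) return IntegerVector(0);
  if (n == 1) return IntegerVector::create(1);
  int m = n + 1; // node n is the dummy
  std::vector<std::vector<double> > d(m, std::vector<double>(m, 0.0));
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) d[a][b] = D(a, b);

  // multi-start: the dummy plus up to 8 evenly spaced cities
  std::vector<int> starts;
  starts.push_back(n);
  int nstart = n < 8 ? n : 8;
  for (int s = 0; s < nstart; ++s) {
    int c = (int)((long long)s * n / nstart);
    starts.push_back(c);
  }
  std::vector<int> best_tour;
  double best_cost = 0.0;
  for (size_t s = 0; s < starts.size(); ++s) {
    std::vector<int> tour = nn_tour(d, m, starts[s]);
    improve_tour(tour, d);
    double cost = cycle_cost(tour, d);
    if (s == 0 || cost < best_cost - 1e-12) {
      best_cost = cost;
      best_tour = tour;
    }
  }

  // cut the cycle at the dummy
  std::vector<int> path;
  int start = 0;
  for (int k = 0; k < m; ++k) if (best_tour[k] == n) { start = k; break; }
  for (int k = 1; k < m; ++k) path.push_back(best_tour[(start + k) % m]);
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = path[k] + 1;
  return out;
}
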