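#include <Rcpp.h>
using namespace Rcpp;

// Weighted-graph kernels for dense PLV matrices. Edge lengths are the
// inverse weights d_ij = 1/w_ij (the connectivity-toolbox convention);
// w_ij = 0 means no edge. All inputs are symmetric with a zero diagonal.

static void floyd_warshall(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[(size_t)k * n];
    for (int j = 0; j < n; ++j) {
      double dkj = dk[j];
      if (!R_finite(dkj)) continue;
      double* dj = &d[(size_t)j * n];
      for (int i = 0; i < n; ++i) {
        double via = dk[i] + dkj;
        if (via < dj[i]) dj[i] = via;
      }
    }
  }
}

static void weights_to_lengths(const double* w, std::vector<double>& d, int n) {
  d.assign((size_t)n * n, R_PosInf);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double wij = w[i + (size_t)j * n];
      if (i == j) d[i + (size_t)j * n] = 0.0;
      else if (wij > 0.0) d[i + (size_t)j * n] = 1.0 / wij;
    }
}

// L = mean weighted shortest path over reachable ordered pairs i != j,
// Eglob = mean of 1/d over all ordered pairs (unreachable contribute 0).
static void path_stats(const double* w, int n, double* L, double* eglob,
                       int* n_unreachable) {
  std::vector<double> d;
  weights_to_lengths(w, d, n);
  floyd_warshall(d, n);
  double sumL = 0.0, sumE = 0.0;
  R_xlen_t reach = 0, unreach = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      double dij = d[i + (size_t)j * n];
      if (R_finite(dij)) {
        sumL += dij;
        sumE += 1.0 / dij;
        ++reach;
      } else {
        ++unreach;
      }
    }
  *L = (reach > 0) ? sumL / reach : NA_REAL;
  *eglob = (n > 1) ? sumE / ((double)n * (n - 1)) : NA_REAL;
  *n_unreachable = (int)unreach;
}

// [[Rcpp::export]]
NumericMatrix fw_distances_cpp(NumericMatrix W) {
  int n = W.nrow();
  std::vector<double> d;
  weights_to_lengths(W.begin(), d, n);
  floyd_warshall(d, n);
  NumericMatrix D(n, n);
  std::copy(d.begin(), d.end(), D.begin());
  return D;
}

// [[Rcpp::export]]
NumericVector path_stats_cpp(NumericMatrix W) {
  double L, eglob;
  int unreach;
  path_stats(W.begin(), W.nrow(), &L, &eglob, &unreach);
  return NumericVector::create(_["L"] = L, _["eglob"] = eglob,
                               _["n_unreachable"] = (double)unreach);
}

// Onnela geometric-mean weighted clustering per node, on weights normalised
// by the maximum off-diagonal weight. Nodes with fewer than 2 neighbours
// get NA (excluded from the network mean upstream).
static void onnela(const double* w, int n, double* c) {
  double wmax = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && w[i + (size_t)j * n] > wmax) wmax = w[i + (size_t)j * n];
  if (wmax <= 0.0) {
    for (int i = 0; i < n; ++i) c[i] = NA_REAL;
    return;
  }
  std::vector<double> a((size_t)n * n, 0.0);
  std::vector<int> deg(n, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double wij = w[i + (size_t)j * n];
      if (i != j && wij > 0.0) {
        a[i + (size_t)j * n] = std::cbrt(wij / wmax);
        ++deg[j];
      }
    }
  for (int i = 0; i < n; ++i) {
    if (deg[i] < 2) { c[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double aij = a[i + (size_t)j * n];
      if (j == i || aij == 0.0) continue;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        double aik = a[i + (size_t)k * n];
        if (aik == 0.0) continue;
        s += aij * aik * a[j + (size_t)k * n];
      }
    }
    c[i] = s / ((double)deg[i] * (deg[i] - 1));
  }
}

// [[Rcpp::export]]
NumericVector onnela_clustering_cpp(NumericMatrix W) {
  int n = W.nrow();
  NumericVector c(n);
  onnela(W.begin(), n, c.begin());
  return c;
}

static double mean_clustering(const double* w, int n, std::vector<double>& buf) {
  buf.resize(n);
  onnela(w, n, buf.data());
  double s = 0.0;
  int m = 0;
  for (int i = 0; i < n; ++i)
    if (R_finite(buf[i])) { s += buf[i]; ++m; }
  return (m > 0) ? s / m : 0.0;
}

// Mean over *all* nodes of the global efficiency of each node's
// neighbour-induced subgraph (node removed); < 2 neighbours contributes 0.
// [[Rcpp::export]]
double local_efficiency_cpp(NumericMatrix W) {
  int n = W.nrow();
  std::vector<int> nb;
  std::vector<double> sub, d;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && W(j, i) > 0.0) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) continue;
    sub.assign((size_t)m * m, 0.0);
    for (int b = 0; b < m; ++b)
      for (int a = 0; a < m; ++a)
        sub[a + (size_t)b * m] = W(nb[a], nb[b]);
    double L, eglob;
    int unreach;
    path_stats(sub.data(), m, &L, &eglob, &unreach);
    if (R_finite(eglob)) total += eglob;
  }
  return total / n;
}

// Null-ensemble statistics for the small-world index: each column of
// `perms` is a 1-based permutation of the m = n(n-1)/2 upper-triangle
// entries; the permuted weights are symmetrised and (C, L) recorded.
// The normalised cube-rooted weights are precomputed once: both the
// maximum weight and the weight multiset are permutation-invariant.
// [[Rcpp::export]]
NumericMatrix null_ensemble_stats_cpp(NumericMatrix W, IntegerMatrix perms) {
  int n = W.nrow();
  int m = n * (n - 1) / 2;
  int n_surr = perms.ncol();
  if (perms.nrow() != m) stop("permutation matrix must have n*(n-1)/2 rows");

  std::vector<double> upper(m), acub(m);
  double wmax = 0.0;
  {
    int e = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) {
        upper[e] = W(i, j);
        if (upper[e] > wmax) wmax = upper[e];
        ++e;
      }
  }
  for (int e = 0; e < m; ++e)
    acub[e] = (wmax > 0.0 && upper[e] > 0.0) ? std::cbrt(upper[e] / wmax) : 0.0;

  NumericMatrix out(n_surr, 2);
  colnames(out) = CharacterVector::create("C", "L");
  std::vector<double> ws((size_t)n * n), A((size_t)n * n), d;
  std::vector<int> deg(n);
  for (int s = 0; s < n_surr; ++s) {
    std::fill(ws.begin(), ws.end(), 0.0);
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(deg.begin(), deg.end(), 0);
    int e = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) {
        int src = perms(e, s) - 1;
        double w = upper[src], a = acub[src];
        ws[i + (size_t)j * n] = w;
        ws[j + (size_t)i * n] = w;
        A[i + (size_t)j * n] = a;
        A[j + (size_t)i * n] = a;
        if (w > 0.0) { ++deg[i]; ++deg[j]; }
        ++e;
      }
    double L, eglob;
    int unreach;
    path_stats(ws.data(), n, &L, &eglob, &unreach);
    // mean Onnela clustering over nodes with degree >= 2
    double csum = 0.0;
    int cn = 0;
    for (int i = 0; i < n; ++i) {
      if (deg[i] < 2) continue;
      double si = 0.0;
      const double* Ai = &A[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        double aij = Ai[j];
        if (j == i || aij == 0.0) continue;
        const double* Aj = &A[(size_t)j * n];
        for (int k = j + 1; k < n; ++k) {
          if (k == i) continue;
          double aik = Ai[k];
          if (aik == 0.0) continue;
          si += aij * aik * Aj[k];
        }
      }
      csum += 2.0 * si / ((double)deg[i] * (deg[i] - 1));
      ++cn;
    }
    out(s, 0) = (cn > 0) ? csum / cn : 0.0;
    out(s, 1) = L;
  }
  return out;
}
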