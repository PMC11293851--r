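#include <Rcpp.h>
using namespace Rcpp;

// Term kinds shared with the R side (see expandTerms):
//   0 = edges
//   1 = gwesp with fixed decay
//   2 = linear vertex covariate (nodecov, or a nodefactor level indicator)
struct TermSet {
  std::vector<int> kind;
  std::vector<double> decay;
  std::vector<NumericVector> x;
  int p() const { return (int)kind.size(); }
};

static TermSet parse_terms(List terms) {
  TermSet ts;
  for (int k = 0; k < terms.size(); ++k) {
    List t = terms[k];
    ts.kind.push_back(as<int>(t["kind"]));
    ts.decay.push_back(as<double>(t["decay"]));
    ts.x.push_back(as<NumericVector>(t["x"]));
  }
  return ts;
}

// gwesp edge weight for an edge with k shared partners
static inline double wgt(double tau, int k) {
  if (k <= 0) return 0.0;
  return std::exp(tau) * (1.0 - std::pow(1.0 - std::exp(-tau), (double)k));
}

static int common_nbrs(const IntegerMatrix& A, int i, int j) {
  const int n = A.nrow();
  int c = 0;
  for (int u = 0; u < n; ++u)
    if (A(i, u) && A(j, u)) ++c;
  return c;
}

static void full_stats(const IntegerMatrix& A, const TermSet& ts, double* out) {
  const int n = A.nrow(), p = ts.p();
  for (int k = 0; k < p; ++k) out[k] = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!A(i, j)) continue;
      for (int k = 0; k < p; ++k) {
        switch (ts.kind[k]) {
        case 0: out[k] += 1.0; break;
        case 1: out[k] += wgt(ts.decay[k], common_nbrs(A, i, j)); break;
        default: out[k] += ts.x[k][i] + ts.x[k][j];
        }
      }
    }
  }
}

// Change statistics for ADDING edge (i, j); requires A(i, j) == 0.
// For gwesp, adding (i,j) (a) creates an edge with cn(i,j) shared partners
// and (b) gives every edge (i,u), (j,u) with u a common neighbour one extra
// shared partner.  No other edge is affected.
static void add_change(const IntegerMatrix& A, const TermSet& ts,
                       int i, int j, double* d) {
  const int n = A.nrow(), p = ts.p();
  for (int k = 0; k < p; ++k) {
    switch (ts.kind[k]) {
    case 0: d[k] = 1.0; break;
    case 2: d[k] = ts.x[k][i] + ts.x[k][j]; break;
    case 1: {
      const double tau = ts.decay[k];
      int cnij = 0;
      double acc = 0.0;
      for (int u = 0; u < n; ++u) {
        if (A(i, u) && A(j, u)) {
          ++cnij;
          const int ciu = common_nbrs(A, i, u);
          const int cju = common_nbrs(A, j, u);
          acc += (wgt(tau, ciu + 1) - wgt(tau, ciu)) +
                 (wgt(tau, cju + 1) - wgt(tau, cju));
        }
      }
      d[k] = wgt(tau, cnij) + acc;
      break;
    }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_network_stats(IntegerMatrix A, List terms) {
  TermSet ts = parse_terms(terms);
  NumericVector out(ts.p());
  full_stats(A, ts, REAL(out));
  return out;
}

// Change statistic g(y + ij) - g(y - ij) regardless of the edge's current
// state (the edge is temporarily switched off for the local computation).
// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix A, int i, int j, List terms) {
  TermSet ts = parse_terms(terms);
  NumericVector out(ts.p());
  IntegerMatrix B = clone(A);
  B(i, j) = B(j, i) = 0;
  add_change(B, ts, i, j, REAL(out));
  return out;
}

// Design matrix for the pseudolikelihood: one row per dyad i < j with the
// change statistics evaluated with that dyad switched off, plus the edge
// indicator response.
// [[Rcpp::export]]
List cpp_dyad_design(IntegerMatrix A, List terms) {
  TermSet ts = parse_terms(terms);
  const int n = A.nrow(), p = ts.p();
  const int D = n * (n - 1) / 2;
  NumericMatrix X(D, p);
  IntegerVector y(D);
  IntegerMatrix B = clone(A);
  std::vector<double> d(p);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      const int a = B(i, j);
      B(i, j) = B(j, i) = 0;
      add_change(B, ts, i, j, d.data());
      B(i, j) = B(j, i) = a;
      for (int k = 0; k < p; ++k) X(r, k) = d[k];
      y[r] = a;
    }
  }
  return List::create(_["X"] = X, _["y"] = y);
}

// Metropolis-Hastings sampler over single-dyad toggles with uniform dyad
// proposals; uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List cpp_mh_sample(IntegerMatrix A0, List terms, NumericVector theta,
                   int burnin, int thin, int nsamp, bool return_graphs) {
  TermSet ts = parse_terms(terms);
  const int n = A0.nrow(), p = ts.p();
  if (n < 2) stop("sampler requires at least 2 vertices");
  IntegerMatrix A = clone(A0);
  std::vector<double> cur(p), d(p);
  full_stats(A, ts, cur.data());
  NumericMatrix S(nsamp, p);
  List graphs(return_graphs ? nsamp : 0);
  const long total = (long)burnin + (long)thin * (long)nsamp;
  long rec = 0;
  for (long it = 0; it < total; ++it) {
    int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
    int j = (int)(unif_rand() * (n - 1)); if (j >= n - 1) j = n - 2;
    if (j >= i) ++j;
    const int a = A(i, j);
    if (a) { A(i, j) = A(j, i) = 0; }
    add_change(A, ts, i, j, d.data());
    double lr = 0.0;
    for (int k = 0; k < p; ++k) lr += theta[k] * d[k];
    if (a) {
      // deletion proposal; edge currently switched off
      if (std::log(unif_rand()) < -lr) {
        for (int k = 0; k < p; ++k) cur[k] -= d[k];
      } else {
        A(i, j) = A(j, i) = 1;  // reject: restore
      }
    } else {
      if (std::log(unif_rand()) < lr) {
        A(i, j) = A(j, i) = 1;
        for (int k = 0; k < p; ++k) cur[k] += d[k];
      }
    }
    if (it >= burnin && ((it - burnin + 1) % thin) == 0 && rec < nsamp) {
      for (int k = 0; k < p; ++k) S(rec, k) = cur[k];
      if (return_graphs) graphs[rec] = clone(A);
      ++rec;
    }
  }
  return List::create(_["stats"] = S, _["graphs"] = graphs,
                      _["final"] = A);
}

// Statistic vectors of every labelled graph on n vertices (n <= 7).
// Row order: graph index m in 0..2^D-1, dyad bit b for the b-th pair in
// (i<j) lexicographic order.
// [[Rcpp::export]]
NumericMatrix cpp_enumerate_stats(int n, List terms) {
  TermSet ts = parse_terms(terms);
  const int D = n * (n - 1) / 2;
  if (n < 1 || D > 22) stop("exact enumeration limited to n <= 7");
  const long G = 1L << D;
  const int p = ts.p();
  NumericMatrix out((int)G, p);
  std::vector<int> di(D), dj(D);
  int b = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j, ++b) { di[b] = i; dj[b] = j; }
  IntegerMatrix A(n, n);
  std::vector<double> s(p);
  for (long m = 0; m < G; ++m) {
    for (int k = 0; k < D; ++k) {
      const int v = (m >> k) & 1L;
      A(di[k], dj[k]) = A(dj[k], di[k]) = v;
    }
    full_stats(A, ts, s.data());
    for (int k = 0; k < p; ++k) out((int)m, k) = s[k];
  }
  return out;
}
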