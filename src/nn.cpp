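#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour Euclidean distance from each query point to a reference
// set. Query and reference are treated as distinct sets: a query point
// coincident with a reference point gets distance 0.
// [[Rcpp::export(name = ".cppNNDist")]]
NumericVector cppNNDist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Leave-one-out nearest-neighbour distances within one point set
// (used for data-driven spacing estimates, e.g. the interface alpha radius).
// [[Rcpp::export(name = ".cppNNSelf")]]
NumericVector cppNNSelf(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = (best == R_PosInf) ? NA_REAL : std::sqrt(best);
  }
  return out;
}

// Label-permutation null for the nearest-neighbour randomization test.
// pts holds the pooled A+B positions; for each permutation nA indices are
// drawn (without replacement, R's RNG) to act as type A, the rest as type B,
// and the A->B nearest-neighbour distances are accumulated.
// Returns a list with the pooled null distances and the per-permutation
// median A->B distance.
// [[Rcpp::export(name = ".cppNNPermNull")]]
List cppNNPermNull(NumericMatrix pts, int nA, int nPerm) {
  const int n = pts.nrow(), nB = n - nA;
  NumericVector pooled(static_cast<R_xlen_t>(nA) * nPerm);
  NumericVector medians(nPerm);
  IntegerVector idx = seq_len(n) - 1;
  NumericVector dists(nA);
  for (int p = 0; p < nPerm; ++p) {
    IntegerVector perm = sample(idx, n, false);
    for (int i = 0; i < nA; ++i) {
      const double qx = pts(perm[i], 0), qy = pts(perm[i], 1);
      double best = R_PosInf;
      for (int j = nA; j < n; ++j) {
        const double dx = qx - pts(perm[j], 0), dy = qy - pts(perm[j], 1);
        const double d2 = dx * dx + dy * dy;
        if (d2 < best) best = d2;
      }
      dists[i] = std::sqrt(best);
      pooled[static_cast<R_xlen_t>(p) * nA + i] = dists[i];
    }
    NumericVector d = clone(dists);
    std::sort(d.begin(), d.end());
    medians[p] = (nA % 2 == 1) ? d[nA / 2] : 0.5 * (d[nA / 2 - 1] + d[nA / 2]);
  }
  (void)nB;
  return List::create(_["pooled"] = pooled, _["medians"] = medians);
}
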