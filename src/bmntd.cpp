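#include <Rcpp.h>
using namespace Rcpp;

// beta mean nearest taxon distance for one pair of communities.
// d: full patristic matrix (S x S) indexed through perm (tip shuffle);
// ia/ib: 0-based indices of taxa present in each sample;
// wa/wb: weights (relative abundances, or uniform), summing to 1.
static double bmntd_pair(const NumericMatrix& d, const IntegerVector& perm,
                         const std::vector<int>& ia, const std::vector<int>& ib,
                         const std::vector<double>& wa,
                         const std::vector<double>& wb) {
  double acc = 0.0;
  for (size_t i = 0; i < ia.size(); ++i) {
    const int ri = perm[ia[i]];
    double mn = R_PosInf;
    for (size_t j = 0; j < ib.size(); ++j) {
      const double v = d(ri, perm[ib[j]]);
      if (v < mn) mn = v;
    }
    acc += 0.5 * wa[i] * mn;
  }
  for (size_t j = 0; j < ib.size(); ++j) {
    const int rj = perm[ib[j]];
    double mn = R_PosInf;
    for (size_t i = 0; i < ia.size(); ++i) {
      const double v = d(rj, perm[ia[i]]);
      if (v < mn) mn = v;
    }
    acc += 0.5 * wb[j] * mn;
  }
  return acc;
}

static void presence_weights(const NumericMatrix& comm, int col, bool weighted,
                             std::vector<int>& idx, std::vector<double>& w) {
  idx.clear(); w.clear();
  double tot = 0.0;
  for (int i = 0; i < comm.nrow(); ++i) {
    if (comm(i, col) > 0) { idx.push_back(i); tot += comm(i, col); }
  }
  for (size_t k = 0; k < idx.size(); ++k)
    w.push_back(weighted ? comm(idx[k], col) / tot : 1.0 / idx.size());
}

// [[Rcpp::export]]
NumericVector cpp_bmntd(NumericMatrix d, NumericMatrix comm,
                        IntegerMatrix pairs, bool weighted) {
  const int m = pairs.nrow();
  NumericVector out(m);
  IntegerVector ident(d.nrow());
  for (int i = 0; i < d.nrow(); ++i) ident[i] = i;
  std::vector<int> ia, ib; std::vector<double> wa, wb;
  for (int k = 0; k < m; ++k) {
    presence_weights(comm, pairs(k, 0) - 1, weighted, ia, wa);
    presence_weights(comm, pairs(k, 1) - 1, weighted, ib, wb);
    out[k] = bmntd_pair(d, ident, ia, ib, wa, wb);
  }
  return out;
}

// Null betaMNTD under tip-label shuffling: perms is n_null x S, each row a
// permutation of 1..S applied to the distance matrix rows/columns (one
// shuffle shared per replicate across all pairs). Returns m x n_null.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd_null(NumericMatrix d, NumericMatrix comm,
                             IntegerMatrix pairs, IntegerMatrix perms,
                             bool weighted) {
  const int m = pairs.nrow(), n_null = perms.nrow();
  NumericMatrix out(m, n_null);
  std::vector<std::vector<int> > ias(m), ibs(m);
  std::vector<std::vector<double> > was(m), wbs(m);
  for (int k = 0; k < m; ++k) {
    presence_weights(comm, pairs(k, 0) - 1, weighted, ias[k], was[k]);
    presence_weights(comm, pairs(k, 1) - 1, weighted, ibs[k], wbs[k]);
  }
  IntegerVector perm(d.nrow());
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < d.nrow(); ++i) perm[i] = perms(r, i) - 1;
    for (int k = 0; k < m; ++k)
      out(k, r) = bmntd_pair(d, perm, ias[k], ibs[k], was[k], wbs[k]);
  }
  return out;
}
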