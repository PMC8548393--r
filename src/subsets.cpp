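#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lexicographic next k-combination of {0, ..., n-1}; returns false when done.
static bool next_combination(arma::uvec &c, const unsigned int n) {
  const unsigned int k = c.n_elem;
  int i = (int)k - 1;
  while (i >= 0 && c[i] == n - k + i) --i;
  if (i < 0) return false;
  ++c[i];
  for (unsigned int j = i + 1; j < k; ++j) c[j] = c[j - 1] + 1;
  return true;
}

// Exhaustive feasibility scan over all species subsets of size 1..max_size.
// For each subset the interior equilibrium of the Lotka-Volterra subsystem
// is solved; singletons use the monoculture rule (r > tol and positive
// self-limitation). Returns parallel columns keyed by a bitmask over
// species indices (bit i set <=> species i+1 in the subset).
// [[Rcpp::export]]
List enumerate_subsets_cpp(const arma::mat &A, const arma::vec &r,
                           const int max_size, const double tol,
                           const double rcond_tol) {
  const unsigned int S = A.n_rows;
  double total = 0;
  for (int m = 1; m <= max_size; ++m) total += Rf_choose((double)S, (double)m);
  const R_xlen_t n_total = (R_xlen_t)total;

  NumericVector mask(n_total);
  IntegerVector size(n_total);
  LogicalVector feasible(n_total);
  LogicalVector singular(n_total);
  List equilibria(n_total);

  R_xlen_t row = 0;
  arma::vec N;
  for (int m = 1; m <= (int)std::min((unsigned int)max_size, S); ++m) {
    arma::uvec idx(m);
    for (int j = 0; j < m; ++j) idx[j] = j;
    do {
      double bm = 0;
      for (int j = 0; j < m; ++j) bm += std::ldexp(1.0, (int)idx[j]);
      mask[row] = bm;
      size[row] = m;
      bool is_sing = false, is_feas = false;
      if (m == 1) {
        const double aii = A(idx[0], idx[0]);
        if (aii == 0.0) {
          is_sing = true;
          equilibria[row] = R_NilValue;
        } else {
          N = arma::vec(1);
          N[0] = r(idx[0]) / aii;
          is_feas = (aii > 0.0) && (r(idx[0]) > tol);
          equilibria[row] = NumericVector(N.begin(), N.end());
        }
      } else {
        const arma::mat Asub = A.submat(idx, idx);
        const arma::vec rsub = r.elem(idx);
        if (arma::rcond(Asub) < rcond_tol) {
          is_sing = true;
          equilibria[row] = R_NilValue;
        } else {
          bool ok = arma::solve(N, Asub, rsub,
                                arma::solve_opts::no_approx);
          if (!ok) {
            is_sing = true;
            equilibria[row] = R_NilValue;
          } else {
            is_feas = arma::all(N > tol);
            equilibria[row] = NumericVector(N.begin(), N.end());
          }
        }
      }
      feasible[row] = is_feas;
      singular[row] = is_sing;
      ++row;
    } while (next_combination(idx, S));
  }
  return List::create(_["mask"] = mask, _["size"] = size,
                      _["feasible"] = feasible, _["singular"] = singular,
                      _["equilibrium"] = equilibria);
}
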