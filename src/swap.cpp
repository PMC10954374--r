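#include <Rcpp.h>
using namespace Rcpp;

// Fixed-fixed swap null model for binary site-by-species matrices.
// Proposal: draw a uniform random (row pair, column pair); if the 2x2
// submatrix is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) swap it,
// otherwise stay. The proposal is symmetric and every swap preserves all
// row and column sums, so the chain's stationary distribution is uniform
// over the fixed-margin set. burn_in and thin count proposal attempts.
// Uses R's RNG, so set.seed() on the R side makes the stream reproducible.

static inline bool attempt_swap(IntegerMatrix &cur, int nr, int nc) {
  int r1 = (int)(unif_rand() * nr);
  int r2 = (int)(unif_rand() * nr);
  int c1 = (int)(unif_rand() * nc);
  int c2 = (int)(unif_rand() * nc);
  if (r1 == r2 || c1 == c2) return false;
  int a = cur(r1, c1), b = cur(r1, c2), c = cur(r2, c1), d = cur(r2, c2);
  if (a == 1 && d == 1 && b == 0 && c == 0) {
    cur(r1, c1) = 0; cur(r2, c2) = 0; cur(r1, c2) = 1; cur(r2, c1) = 1;
    return true;
  }
  if (a == 0 && d == 0 && b == 1 && c == 1) {
    cur(r1, c1) = 1; cur(r2, c2) = 1; cur(r1, c2) = 0; cur(r2, c1) = 0;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List swap_chain_cpp(IntegerMatrix m, int n_sim, int burn_in, int thin) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix cur = clone(m);
  List out(n_sim);
  long long n_swaps = 0;
  for (int i = 0; i < burn_in; ++i)
    if (attempt_swap(cur, nr, nc)) ++n_swaps;
  for (int s = 0; s < n_sim; ++s) {
    for (int i = 0; i < thin; ++i)
      if (attempt_swap(cur, nr, nc)) ++n_swaps;
    out[s] = clone(cur);
  }
  return List::create(_["matrices"] = out, _["n_swaps"] = (double)n_swaps);
}

// Exhaustive scan for any 2x2 checkerboard submatrix. A binary matrix has
// no checkerboard iff it is the unique matrix with its margins (the swap
// chain connects the fixed-margin set), which makes the null degenerate.
// [[Rcpp::export]]
bool has_checkerboard_cpp(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  for (int r1 = 0; r1 < nr - 1; ++r1)
    for (int r2 = r1 + 1; r2 < nr; ++r2)
      for (int c1 = 0; c1 < nc - 1; ++c1)
        for (int c2 = c1 + 1; c2 < nc; ++c2) {
          int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
          if ((a == 1 && d == 1 && b == 0 && c == 0) ||
              (a == 0 && d == 0 && b == 1 && c == 1))
            return true;
        }
  return false;
}
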