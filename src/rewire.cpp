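#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving rewiring of a binary sample x gene matrix by repeated
// checkerboard swaps: pick two 1-entries (r1,c1), (r2,c2) with the opposite
// corners (r1,c2), (r2,c1) empty and exchange the columns. Row and column
// sums are invariant under every accepted swap. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix rewire_checkerboard_cpp(IntegerMatrix mat, int n_swaps,
                                      double max_tries) {
  IntegerMatrix A = clone(mat);
  const int nr = A.nrow(), nc = A.ncol();
  std::vector<int> er, ec;
  er.reserve(256); ec.reserve(256);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (A(i, j) == 1) { er.push_back(i); ec.push_back(j); }
  const int ne = (int) er.size();
  int done = 0;
  double tries = 0;
  if (ne >= 2) {
    while (done < n_swaps && tries < max_tries) {
      tries += 1;
      int e1 = (int) (unif_rand() * ne); if (e1 == ne) --e1;
      int e2 = (int) (unif_rand() * ne); if (e2 == ne) --e2;
      const int r1 = er[e1], c1 = ec[e1], r2 = er[e2], c2 = ec[e2];
      if (r1 == r2 || c1 == c2) continue;
      if (A(r1, c2) == 1 || A(r2, c1) == 1) continue;
      A(r1, c1) = 0; A(r2, c2) = 0;
      A(r1, c2) = 1; A(r2, c1) = 1;
      ec[e1] = c2; ec[e2] = c1;
      ++done;
    }
  }
  A.attr("swaps_done") = done;
  return A;
}
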