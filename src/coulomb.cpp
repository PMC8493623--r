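#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Pairwise sum of q_i q_j / r_ij over all cross pairs of two charge clouds.
// Pairs with r < rmin are skipped and counted. Returns the raw sum in
// e^2/Angstrom; the Coulomb constant is applied on the R side.
// [[Rcpp::export]]
List coulomb_pair_sum(NumericVector qa, NumericVector xa, NumericVector ya,
                      NumericVector za, NumericVector qb, NumericVector xb,
                      NumericVector yb, NumericVector zb, double rmin) {
  const R_xlen_t na = qa.size(), nb = qb.size();
  const double rmin2 = rmin * rmin;
  double total = 0.0;
  R_xlen_t skipped = 0;
  for (R_xlen_t i = 0; i < na; ++i) {
    const double qi = qa[i], xi = xa[i], yi = ya[i], zi = za[i];
    double acc = 0.0;
    double nskip = 0.0;
    // branchless inner loop so the compiler can vectorize the sqrt
    for (R_xlen_t j = 0; j < nb; ++j) {
      const double dx = xb[j] - xi;
      const double dy = yb[j] - yi;
      const double dz = zb[j] - zi;
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double ok = (r2 >= rmin2) ? 1.0 : 0.0;
      acc += ok * qb[j] / std::sqrt(r2 + (1.0 - ok));
      nskip += 1.0 - ok;
    }
    total += qi * acc;
    skipped += (R_xlen_t)nskip;
  }
  return List::create(_["sum"] = total, _["skipped"] = (double)skipped);
}
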