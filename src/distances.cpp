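#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// symmetric mean-of-mean-closest-point distance between two polylines:
// d(A,B) = 0.5 * (mean_a min_b ||a-b|| + mean_b min_a ||b-a||)
static double mcp(const NumericMatrix &A, const NumericMatrix &B) {
  const int na = A.nrow(), nb = B.nrow();
  double sab = 0.0;
  std::vector<double> minb(nb, R_PosInf);
  for (int i = 0; i < na; ++i) {
    double mina = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mina) mina = d2;
      if (d2 < minb[j]) minb[j] = d2;
    }
    sab += std::sqrt(mina);
  }
  double sba = 0.0;
  for (int j = 0; j < nb; ++j) sba += std::sqrt(minb[j]);
  return 0.5 * (sab / na + sba / nb);
}

// [[Rcpp::export]]
NumericMatrix mcp_dist_matrix_cpp(List streamlines) {
  const int n = streamlines.size();
  NumericMatrix D(n, n);
  std::vector<NumericMatrix> sl;
  sl.reserve(n);
  for (int i = 0; i < n; ++i) sl.push_back(as<NumericMatrix>(streamlines[i]));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double d = mcp(sl[i], sl[j]);
      D(i, j) = d; D(j, i) = d;
    }
  return D;
}
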