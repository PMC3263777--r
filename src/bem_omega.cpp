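#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solid angles subtended by triangles at observation points (van Oosterom &
// Strackee 1983). Sign follows the triangle winding: positive when the
// outward face is seen from inside. Rows: observation points; columns:
// triangles.
// [[Rcpp::export(name = ".solid_angles")]]
NumericMatrix solid_angles(NumericMatrix obs, NumericMatrix v1,
                           NumericMatrix v2, NumericMatrix v3) {
  const int M = obs.nrow(), T = v1.nrow();
  NumericMatrix out(M, T);
  for (int m = 0; m < M; ++m) {
    const double ox = obs(m, 0), oy = obs(m, 1), oz = obs(m, 2);
    for (int t = 0; t < T; ++t) {
      const double x1 = v1(t, 0) - ox, y1 = v1(t, 1) - oy, z1 = v1(t, 2) - oz;
      const double x2 = v2(t, 0) - ox, y2 = v2(t, 1) - oy, z2 = v2(t, 2) - oz;
      const double x3 = v3(t, 0) - ox, y3 = v3(t, 1) - oy, z3 = v3(t, 2) - oz;
      const double r1 = std::sqrt(x1 * x1 + y1 * y1 + z1 * z1);
      const double r2 = std::sqrt(x2 * x2 + y2 * y2 + z2 * z2);
      const double r3 = std::sqrt(x3 * x3 + y3 * y3 + z3 * z3);
      const double det = x1 * (y2 * z3 - z2 * y3) -
                         y1 * (x2 * z3 - z2 * x3) +
                         z1 * (x2 * y3 - y2 * x3);
      const double d12 = x1 * x2 + y1 * y2 + z1 * z2;
      const double d13 = x1 * x3 + y1 * y3 + z1 * z3;
      const double d23 = x2 * x3 + y2 * y3 + z2 * z3;
      const double denom = r1 * r2 * r3 + d12 * r3 + d13 * r2 + d23 * r1;
      out(m, t) = 2.0 * std::atan2(det, denom);
    }
  }
  return out;
}
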