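#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Entropy (bits) of the normalized Gaussian densities of one neighbourhood
// half. With unnormalized densities d = exp(-z^2/2), z = (v - mean)/sd,
// the entropy of p = d / sum(d) is
//   H = log2(sum(d)) + (1 / (2 ln 2)) * sum(d * z^2) / sum(d);
// the 1/(sqrt(2 pi) sd) prefactor cancels in the normalization.
static double half_entropy(const std::vector<double>& vals, int n,
                           double s1, double s2, double sigma_floor) {
  if (n == 0) return NA_REAL;
  double mu = s1 / n;
  double var = n > 1 ? (s2 - n * mu * mu) / (n - 1) : 0.0;
  if (var < 0.0) var = 0.0;
  double sig = std::sqrt(var);
  if (sig < sigma_floor) sig = sigma_floor;
  double sumd = 0.0, sumdz = 0.0;
  for (int j = 0; j < n; ++j) {
    double z = (vals[j] - mu) / sig;
    double z2 = z * z;
    double d = std::exp(-0.5 * z2);
    sumd += d;
    sumdz += d * z2;
  }
  const double inv_ln2 = 1.4426950408889634; // 1 / ln 2
  return std::log2(sumd) + 0.5 * inv_ln2 * sumdz / sumd;
}

// For each band pixel (0-based linear index into the column-major raster),
// split the disk neighbourhood given by (dr, dc) offsets into the
// phi >= 0 and phi < 0 halves and return each half's SUV entropy and size.
// [[Rcpp::export(name = ".guide_entropies")]]
List guide_entropies(NumericMatrix suv, LogicalMatrix pos,
                     IntegerVector idx0, IntegerVector dr, IntegerVector dc,
                     double sigma_floor) {
  int nr = suv.nrow(), nc = suv.ncol();
  int m = dr.size(), np = idx0.size();
  NumericVector h3(np), h4(np);
  IntegerVector n3v(np), n4v(np);
  std::vector<double> v3(m), v4(m);
  for (int p = 0; p < np; ++p) {
    int lin = idx0[p];
    int c = lin / nr, r = lin - c * nr;
    int n3 = 0, n4 = 0;
    double s3 = 0.0, s33 = 0.0, s4 = 0.0, s44 = 0.0;
    for (int j = 0; j < m; ++j) {
      int rr = r + dr[j], cc = c + dc[j];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double v = suv(rr, cc);
      if (pos(rr, cc)) {
        v3[n3++] = v; s3 += v; s33 += v * v;
      } else {
        v4[n4++] = v; s4 += v; s44 += v * v;
      }
    }
    h3[p] = half_entropy(v3, n3, s3, s33, sigma_floor);
    h4[p] = half_entropy(v4, n4, s4, s44, sigma_floor);
    n3v[p] = n3;
    n4v[p] = n4;
  }
  return List::create(_["h3"] = h3, _["h4"] = h4,
                      _["n3"] = n3v, _["n4"] = n4v);
}
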