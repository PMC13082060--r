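#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3-D median with truncated edge neighborhoods over an array of dims
// (n1, n2, n3) with radii (r1, r2, r3). Used for (t, y, x) activity movies.
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector arr, int r1, int r2, int r3) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("median3d_cpp expects a 3-D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(arr.size());
  out.attr("dim") = dims;
  std::vector<double> buf;
  buf.reserve((size_t)(2 * r1 + 1) * (2 * r2 + 1) * (2 * r3 + 1));
  for (int k = 0; k < n3; ++k) {
    const int k0 = std::max(0, k - r3), k1 = std::min(n3 - 1, k + r3);
    for (int j = 0; j < n2; ++j) {
      const int j0 = std::max(0, j - r2), j1 = std::min(n2 - 1, j + r2);
      for (int i = 0; i < n1; ++i) {
        const int i0 = std::max(0, i - r1), i1 = std::min(n1 - 1, i + r1);
        buf.clear();
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            const R_xlen_t base = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1;
            for (int ii = i0; ii <= i1; ++ii) buf.push_back(arr[base + ii]);
          }
        const size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = (med + lo) / 2.0;
        }
        out[(R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1 + i] = med;
      }
    }
  }
  return out;
}
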