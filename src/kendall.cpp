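#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Knight's O(m log m) algorithm for Kendall rank correlation, tau-a
// variant: S = C - D over the full m(m-1)/2 pair denominator, ties
// contributing zero to the numerator.
//
// With n0 = m(m-1)/2, n1 = pairs tied in x, n2 = pairs tied in y,
// n3 = pairs tied in both, and D = discordant pairs (inversions of y after
// sorting by x, ties in x broken by y):
//   C = n0 - n1 - n2 + n3 - D,  S = C - D = n0 - n1 - n2 + n3 - 2D.

static double merge_count(std::vector<double>& y, std::vector<double>& buf) {
  const size_t n = y.size();
  double inv = 0.0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo + width < n; lo += 2 * width) {
      size_t mid = lo + width;
      size_t hi = std::min(lo + 2 * width, n);
      size_t a = lo, b = mid, k = lo;
      while (a < mid && b < hi) {
        if (y[b] < y[a]) {             // strict: ties are not inversions
          inv += (double)(mid - a);
          buf[k++] = y[b++];
        } else {
          buf[k++] = y[a++];
        }
      }
      while (a < mid) buf[k++] = y[a++];
      while (b < hi) buf[k++] = y[b++];
      std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    }
  }
  return inv;
}

// [[Rcpp::export(name = ".tau_a_cpp")]]
double tau_a_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const R_xlen_t m = x.size();
  if (y.size() != m) Rcpp::stop("x and y must have equal length");
  if (m < 2) Rcpp::stop("need length >= 2");

  std::vector<size_t> ord(m);
  for (R_xlen_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> ys(m);
  for (R_xlen_t i = 0; i < m; ++i) ys[i] = y[ord[i]];

  const double n0 = (double)m * (m - 1) / 2.0;
  double n1 = 0.0, n3 = 0.0;
  {
    R_xlen_t i = 0;
    while (i < m) {
      R_xlen_t j = i;
      while (j < m && x[ord[j]] == x[ord[i]]) ++j;
      double t = (double)(j - i);
      n1 += t * (t - 1) / 2.0;
      // within a tied-x run, count pairs also tied in y
      R_xlen_t a = i;
      while (a < j) {
        R_xlen_t b = a;
        while (b < j && ys[b] == ys[a]) ++b;
        double u = (double)(b - a);
        n3 += u * (u - 1) / 2.0;
        a = b;
      }
      i = j;
    }
  }

  std::vector<double> buf(m);
  double D = merge_count(ys, buf);   // ys is sorted afterwards

  double n2 = 0.0;
  {
    R_xlen_t i = 0;
    while (i < m) {
      R_xlen_t j = i;
      while (j < m && ys[j] == ys[i]) ++j;
      double t = (double)(j - i);
      n2 += t * (t - 1) / 2.0;
      i = j;
    }
  }

  double S = n0 - n1 - n2 + n3 - 2.0 * D;
  return S / n0;
}
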