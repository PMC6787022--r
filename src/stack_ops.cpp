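#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-pixel temporal median and MAD over a frame stack.
// `stack` is a 3-D array (row x col x frame); treated as npix x nframes.
// Works on integer or numeric storage without coercing the whole stack.
template <typename V>
static List median_mad_impl(const V& stack, int npix, int nframes) {
  NumericVector med(npix), mad(npix);
  std::vector<double> buf(nframes);
  const int h = nframes / 2;
  const bool even = (nframes % 2 == 0);
  for (int p = 0; p < npix; ++p) {
    for (int f = 0; f < nframes; ++f)
      buf[f] = stack[(R_xlen_t)f * npix + p];
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (even) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = 0.5 * (m + lo);
    }
    med[p] = m;
    for (int f = 0; f < nframes; ++f)
      buf[f] = std::abs(stack[(R_xlen_t)f * npix + p] - m);
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double md = buf[h];
    if (even) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      md = 0.5 * (md + lo);
    }
    mad[p] = md;
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}

// [[Rcpp::export(name = ".stack_median_mad")]]
List stack_median_mad(SEXP stack, int npix, int nframes) {
  if (TYPEOF(stack) == INTSXP)
    return median_mad_impl(IntegerVector(stack), npix, nframes);
  return median_mad_impl(NumericVector(stack), npix, nframes);
}

// 8-connected component labeling of a logical matrix (flood fill).
// Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export(name = ".label_8connect")]]
IntegerMatrix label_8connect(const LogicalMatrix& fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stackv;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      ++next;
      stackv.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stackv.empty()) {
        int idx = stackv.back(); stackv.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (fg(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stackv.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
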