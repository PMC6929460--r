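#include <Rcpp.h>
using namespace Rcpp;

// Per-set unscaled W sums.
//
// For each row of `sets` (1-based column indices into `g`), subjects with a
// missing genotype in any member of the set are dropped, the remaining
// subjects are cross-tabulated into joint genotype categories against the
// binary phenotype, and the sum over non-empty categories of
// (log OR_i / SE_i)^2 is returned together with the non-empty category count
// k.  Categories touching the table margin (n1i or n0i equal to 0 or to its
// column total) get the Haldane-Anscombe 0.5 correction on all four counts
// entering that category's odds ratio; other categories are untouched.
//
// Entries of `g` must be 0, 1, 2 or NA (any negative value is treated as
// missing).  Sets with k < 2, or where one phenotype class vanishes after
// listwise deletion, yield NA.
// [[Rcpp::export]]
List w_set_sums_cpp(IntegerMatrix g, IntegerVector y, IntegerMatrix sets) {
  const int n = g.nrow();
  const int order = sets.ncol();
  const int nsets = sets.nrow();
  if (y.size() != n) stop("phenotype length does not match genotype rows");
  if (order < 1 || order > 10) stop("set order must be between 1 and 10");

  int ncell = 1;
  for (int j = 0; j < order; ++j) ncell *= 3;

  std::vector<double> n1(ncell), n0(ncell);
  IntegerVector k_out(nsets);
  NumericVector s_out(nsets);

  for (int r = 0; r < nsets; ++r) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    double N1 = 0.0, N0 = 0.0;

    for (int i = 0; i < n; ++i) {
      int code = 0;
      bool ok = true;
      for (int j = 0; j < order; ++j) {
        int v = g(i, sets(r, j) - 1);
        if (v == NA_INTEGER || v < 0 || v > 2) { ok = false; break; }
        code = code * 3 + v;
      }
      if (!ok) continue;
      int yi = y[i];
      if (yi == NA_INTEGER) continue;
      if (yi == 1) { n1[code] += 1.0; N1 += 1.0; }
      else         { n0[code] += 1.0; N0 += 1.0; }
    }

    if (N1 < 1.0 || N0 < 1.0) {
      k_out[r] = NA_INTEGER; s_out[r] = NA_REAL;
      continue;
    }

    int k = 0;
    double S = 0.0;
    for (int c = 0; c < ncell; ++c) {
      double a = n1[c], cc = n0[c];
      if (a + cc <= 0.0) continue;
      ++k;
      double b = N1 - a, d = N0 - cc;
      if (a <= 0.0 || b <= 0.0 || cc <= 0.0 || d <= 0.0) {
        a += 0.5; b += 0.5; cc += 0.5; d += 0.5;
      }
      double lor = std::log(a / b) - std::log(cc / d);
      double se2 = 1.0 / a + 1.0 / b + 1.0 / cc + 1.0 / d;
      S += lor * lor / se2;
    }

    if (k < 2) { k_out[r] = NA_INTEGER; s_out[r] = NA_REAL; }
    else       { k_out[r] = k;          s_out[r] = S; }
  }

  return List::create(_["k"] = k_out, _["s"] = s_out);
}
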