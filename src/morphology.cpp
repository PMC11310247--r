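#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with an arbitrary (possibly non-flat)
// structuring element given as row/col offsets and heights. Out-of-bounds
// offsets are skipped, which for erosion/dilation corresponds to +Inf/-Inf
// padding; the origin offset must be included so constant images are
// reproduced exactly by the opening.
// [[Rcpp::export]]
NumericMatrix morph_nonflat_cpp(NumericMatrix img, IntegerVector dr,
                                IntegerVector dc, NumericVector h,
                                bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int i = 0; i < k; ++i) {
        const int rr = r + dr[i], cc = c + dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = dilate ? img(rr, cc) + h[i] : img(rr, cc) - h[i];
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}
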