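#include <Rcpp.h>
using namespace Rcpp;

// Batch extraction of 4-quadrant LBP histograms.
//
// `padded` is the LBP code map replicate-padded by `half` pixels on every
// side (codes 0..255). `rows`/`cols` are 0-based center coordinates in the
// unpadded map. For an even window w = 2*half the window rows of center r
// are r-half .. r+half-1 in unpadded coordinates, i.e. r .. r+w-1 in the
// padded map. Each quadrant contributes a 256-bin histogram; the quadrants
// are concatenated top-left, top-right, bottom-left, bottom-right, giving a
// 1024-long descriptor per center (one column of the returned matrix).
// [[Rcpp::export(name = ".desc_matrix_cpp")]]
IntegerMatrix desc_matrix_cpp(IntegerMatrix padded, IntegerVector rows,
                              IntegerVector cols, int window) {
  const int half = window / 2;
  const int n = rows.size();
  const int np = padded.nrow();
  IntegerMatrix out(1024, n);
  for (int k = 0; k < n; ++k) {
    const int r0 = rows[k]; // top row of window in padded coordinates
    const int c0 = cols[k];
    int *col = &out(0, k);
    for (int dc = 0; dc < window; ++dc) {
      const int qc = (dc < half) ? 0 : 1;
      const int *p = &padded(r0, c0 + dc);
      for (int dr = 0; dr < window; ++dr) {
        const int q = ((dr < half) ? 0 : 2) + qc; // TL=0, TR=1, BL=2, BR=3
        ++col[(q << 8) + p[dr]];
      }
      (void)np;
    }
  }
  return out;
}
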