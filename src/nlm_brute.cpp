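#include <Rcpp.h>
using namespace Rcpp;

// Naive sliding-window non-local means on a boundary-extended image.
// `ext` is (H + 2m) x (W + 2m) with m = K + P; output is H x W. For every
// pixel and every translation in the (2K+1)^2 search window the flat-patch
// sum of squared differences is accumulated by explicit loops over the
// (2P+1)^2 patch, the weight is g_h(ssd) = 1 / (1 + (ssd/h)^2), and the
// weighted average is normalized at the end. Deterministic row-major order.
// [[Rcpp::export]]
NumericMatrix nlm_brute_cpp(NumericMatrix ext, int H, int W, int K, int P,
                            double h) {
  const int m = (ext.nrow() - H) / 2;
  if (ext.nrow() != H + 2 * m || ext.ncol() != W + 2 * m || m < K + P)
    stop("extended image does not match the requested margin");
  NumericMatrix out(H, W);
  const double h2 = h * h;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int ci = i + m, cj = j + m;  // center in ext coordinates
      double num = 0.0, den = 0.0;
      for (int dr = -K; dr <= K; ++dr) {
        for (int dc = -K; dc <= K; ++dc) {
          double ssd = 0.0;
          for (int pr = -P; pr <= P; ++pr) {
            for (int pc = -P; pc <= P; ++pc) {
              const double a = ext(ci + pr, cj + pc);
              const double b = ext(ci + dr + pr, cj + dc + pc);
              ssd += (a - b) * (a - b);
            }
          }
          const double w = 1.0 / (1.0 + (ssd * ssd) / h2);
          num += w * ext(ci + dr, cj + dc);
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
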