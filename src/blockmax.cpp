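#include <Rcpp.h>
using namespace Rcpp;

// Max-pool over positions for a stacked convolution response.
// Y is (B*T) x F with row index b + t*B (b fastest); returns the pooled
// pre-activations (B x F) and the 1-based argmax position per (b, f).
// [[Rcpp::export(name = ".dc_blockmax")]]
List dc_blockmax(NumericMatrix Y, int B, int T) {
  const int F = Y.ncol();
  NumericMatrix z(B, F);
  IntegerMatrix mf(B, F);
  for (int f = 0; f < F; ++f) {
    const double* col = &Y(0, f);
    double* zf = &z(0, f);
    int* mff = &mf(0, f);
    for (int b = 0; b < B; ++b) {
      zf[b] = col[b];
      mff[b] = 1;
    }
    for (int t = 1; t < T; ++t) {
      const double* block = col + (std::size_t)t * B;
      for (int b = 0; b < B; ++b) {
        if (block[b] > zf[b]) {
          zf[b] = block[b];
          mff[b] = t + 1;
        }
      }
    }
  }
  return List::create(_["zpre"] = z, _["mf"] = mf);
}
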