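// Scatter-add used by the col2im step of the convolution backward pass.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_index_accumulate(NumericVector values, IntegerVector index,
                                   int out_length) {
  NumericVector out(out_length);
  int n = values.size();
  for (int i = 0; i < n; ++i) out[index[i] - 1] += values[i];
  return out;
}
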