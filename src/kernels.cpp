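#include <Rcpp.h>
using namespace Rcpp;

// Gather patch rows for convolution/pooling as an im2col step.
// V: (n_vox x C) activation matrix, rows = voxels (sample-stacked),
// P: (n_out x K) 1-based voxel indices of each patch element.
// Output: (n_out x K*C), column (c-1)*K + k holds V[P[, k], c].
// [[Rcpp::export]]
NumericMatrix gather_patches(const NumericMatrix& V, const IntegerMatrix& P) {
  const int n = P.nrow(), K = P.ncol(), C = V.ncol();
  NumericMatrix out(n, K * C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int oc = c * K + k;
      for (int i = 0; i < n; ++i) {
        out(i, oc) = V(P(i, k) - 1, c);
      }
    }
  }
  return out;
}

// Adjoint of gather_patches: accumulate patch gradients back onto voxels.
// dP: (n_out x K*C) patch gradient, P as above; returns (n_vox x C).
// [[Rcpp::export]]
NumericMatrix scatter_patches(const NumericMatrix& dP, const IntegerMatrix& P,
                              const int n_vox) {
  const int n = P.nrow(), K = P.ncol(), C = dP.ncol() / K;
  NumericMatrix out(n_vox, C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int oc = c * K + k;
      for (int i = 0; i < n; ++i) {
        out(P(i, k) - 1, c) += dP(i, oc);
      }
    }
  }
  return out;
}
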