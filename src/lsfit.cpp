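// Least-squares objective and gradient for the star-phylogeny substitution
// model: 52 unconstrained logits (4 for the ancestral vector, 16 per branch
// matrix, row-major) mapped through row-wise softmax onto the simplex, then
// compared with the 64 observed triple frequencies.
//
// Hot path of model fitting and of every bootstrap refit; the R fallbacks
// in substitution_model.R define the reference semantics.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void softmax4(const double* x, double* out) {
  double m = x[0];
  for (int i = 1; i < 4; ++i) if (x[i] > m) m = x[i];
  double s = 0.0;
  for (int i = 0; i < 4; ++i) { out[i] = std::exp(x[i] - m); s += out[i]; }
  for (int i = 0; i < 4; ++i) out[i] /= s;
}

static void unpack(const double* th, double* pZ, double A[4][4],
                   double B[4][4], double C[4][4]) {
  softmax4(th, pZ);
  for (int r = 0; r < 4; ++r) softmax4(th + 4 + 4 * r, A[r]);
  for (int r = 0; r < 4; ++r) softmax4(th + 20 + 4 * r, B[r]);
  for (int r = 0; r < 4; ++r) softmax4(th + 36 + 4 * r, C[r]);
}

// [[Rcpp::export]]
double cpp_ls_obj(NumericVector theta, NumericVector Q) {
  double pZ[4], A[4][4], B[4][4], C[4][4];
  unpack(theta.begin(), pZ, A, B, C);
  double f = 0.0;
  for (int d = 0; d < 4; ++d)
    for (int m = 0; m < 4; ++m)
      for (int h = 0; h < 4; ++h) {
        double e = 0.0;
        for (int r = 0; r < 4; ++r)
          e += pZ[r] * A[r][h] * B[r][m] * C[r][d];
        double diff = e - Q[h + 4 * m + 16 * d];
        f += diff * diff;
      }
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_ls_grad(NumericVector theta, NumericVector Q) {
  double pZ[4], A[4][4], B[4][4], C[4][4];
  unpack(theta.begin(), pZ, A, B, C);
  double E[4][4][4];
  for (int d = 0; d < 4; ++d)
    for (int m = 0; m < 4; ++m)
      for (int h = 0; h < 4; ++h) {
        double e = 0.0;
        for (int r = 0; r < 4; ++r)
          e += pZ[r] * A[r][h] * B[r][m] * C[r][d];
        E[h][m][d] = 2.0 * (e - Q[h + 4 * m + 16 * d]);
      }
  double dpZ[4] = {0, 0, 0, 0};
  double dA[4][4] = {{0}}, dB[4][4] = {{0}}, dC[4][4] = {{0}};
  for (int r = 0; r < 4; ++r)
    for (int d = 0; d < 4; ++d)
      for (int m = 0; m < 4; ++m)
        for (int h = 0; h < 4; ++h) {
          double e = E[h][m][d];
          dpZ[r]  += e * A[r][h] * B[r][m] * C[r][d];
          dA[r][h] += e * pZ[r] * B[r][m] * C[r][d];
          dB[r][m] += e * pZ[r] * A[r][h] * C[r][d];
          dC[r][d] += e * pZ[r] * A[r][h] * B[r][m];
        }
  // chain through softmax: dlogit_i = p_i * (g_i - sum_j p_j g_j)
  NumericVector out(52);
  double dot = 0.0;
  for (int i = 0; i < 4; ++i) dot += pZ[i] * dpZ[i];
  for (int i = 0; i < 4; ++i) out[i] = pZ[i] * (dpZ[i] - dot);
  double (*mats[3])[4] = {A, B, C};
  double (*grads[3])[4] = {dA, dB, dC};
  for (int k = 0; k < 3; ++k)
    for (int r = 0; r < 4; ++r) {
      double d2 = 0.0;
      for (int j = 0; j < 4; ++j) d2 += mats[k][r][j] * grads[k][r][j];
      for (int j = 0; j < 4; ++j)
        out[4 + 16 * k + 4 * r + j] =
          mats[k][r][j] * (grads[k][r][j] - d2);
    }
  return out;
}
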