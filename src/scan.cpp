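// Selective-scan recurrence kernels.
//
// The input-dependent projections (delta, B_t, C_t) are computed in R as
// dense matrix products; these kernels run only the per-step state
// recurrence and its backpropagation-through-time, which are elementwise
// and therefore interpreter-bound in pure R.
//
// Layouts match the R caller:
//   delta, U, gY : (N*B) x Dm, row r = t + (b-1)*N
//   Bm, Cm       : (N*B) x S
//   A            : Dm x S (negative entries)
//   state rows   : r = b + (d-1)*B  (flattened (B, Dm))
//   H store      : B*Dm x S x N, column-major

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List scan_fwd_cpp(const NumericMatrix& delta, const NumericMatrix& U,
                  const NumericMatrix& Bm, const NumericMatrix& Cm,
                  const NumericMatrix& A, const NumericVector& Dvec,
                  int N, int B) {
  const int Dm = delta.ncol();
  const int S = A.ncol();
  const int BD = B * Dm;
  NumericMatrix Y(N * B, Dm);
  NumericVector H(static_cast<R_xlen_t>(BD) * S * N);
  std::vector<double> h(static_cast<size_t>(BD) * S, 0.0);

  for (int t = 0; t < N; ++t) {
    double* Ht = REAL(H) + static_cast<R_xlen_t>(t) * BD * S;
    for (int d = 0; d < Dm; ++d) {
      for (int b = 0; b < B; ++b) {
        const int rin = t + b * N;       // row in delta/U/Bm/Cm
        const int rst = b + d * B;       // row in the flattened state
        const double del = delta(rin, d);
        const double u = U(rin, d);
        const double du = del * u;
        double y = Dvec[d] * u;
        for (int s = 0; s < S; ++s) {
          const size_t k = static_cast<size_t>(s) * BD + rst;
          const double hk = std::exp(del * A(d, s)) * h[k] + du * Bm(rin, s);
          h[k] = hk;
          Ht[k] = hk;
          y += hk * Cm(rin, s);
        }
        Y(rin, d) = y;
      }
    }
  }
  return List::create(_["Y"] = Y, _["H"] = H);
}

// [[Rcpp::export]]
List scan_bwd_cpp(const NumericMatrix& gY, const NumericMatrix& delta,
                  const NumericMatrix& U, const NumericMatrix& Bm,
                  const NumericMatrix& Cm, const NumericMatrix& A,
                  const NumericVector& Dvec, const NumericVector& H,
                  int N, int B) {
  const int Dm = delta.ncol();
  const int S = A.ncol();
  const int BD = B * Dm;
  NumericMatrix gdelta(N * B, Dm), gU(N * B, Dm);
  NumericMatrix gBm(N * B, S), gCm(N * B, S);
  NumericMatrix gA(Dm, S);
  NumericVector gD(Dm);
  std::vector<double> gh(static_cast<size_t>(BD) * S, 0.0);

  for (int t = N - 1; t >= 0; --t) {
    const double* Ht = REAL(H) + static_cast<R_xlen_t>(t) * BD * S;
    const double* Hp = (t > 0) ? REAL(H) + static_cast<R_xlen_t>(t - 1) * BD * S
                               : nullptr;
    for (int d = 0; d < Dm; ++d) {
      for (int b = 0; b < B; ++b) {
        const int rin = t + b * N;
        const int rst = b + d * B;
        const double del = delta(rin, d);
        const double u = U(rin, d);
        const double gy = gY(rin, d);
        gD[d] += gy * u;
        double gu = gy * Dvec[d];
        double gdel = 0.0;
        for (int s = 0; s < S; ++s) {
          const size_t k = static_cast<size_t>(s) * BD + rst;
          const double ht = Ht[k];
          const double hprev = Hp ? Hp[k] : 0.0;
          const double dA = std::exp(del * A(d, s));
          gCm(rin, s) += gy * ht;
          double g = gh[k] + gy * Cm(rin, s);
          const double gdAdA = g * hprev * dA;
          gdel += gdAdA * A(d, s) + g * u * Bm(rin, s);
          gu += g * del * Bm(rin, s);
          gBm(rin, s) += g * del * u;
          gA(d, s) += gdAdA * del;
          gh[k] = g * dA;
        }
        gdelta(rin, d) = gdel;
        gU(rin, d) = gu;
      }
    }
  }
  return List::create(_["gdelta"] = gdelta, _["gU"] = gU, _["gBm"] = gBm,
                      _["gCm"] = gCm, _["gA"] = gA, _["gD"] = gD);
}
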