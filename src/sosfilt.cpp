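#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// One biquad, direct form II transposed, with given initial state (scaled
// copy of zi).
static void biquad(std::vector<double>& x, double b0, double b1, double b2,
                   double a1, double a2, double zi1, double zi2) {
  double z1 = zi1 * x[0];
  double z2 = zi2 * x[0];
  for (size_t n = 0; n < x.size(); ++n) {
    double xn = x[n];
    double yn = b0 * xn + z1;
    z1 = b1 * xn - a1 * yn + z2;
    z2 = b2 * xn - a2 * yn;
    x[n] = yn;
  }
}

// steady-state unit-step state of a biquad (lfilter_zi): solve (I - A) z = B
static void step_zi(double b0, double b1, double b2, double a1, double a2,
                    double& zi1, double& zi2) {
  // A = [[-a1, 1], [-a2, 0]], B = [b1 - a1 b0, b2 - a2 b0]
  double B1 = b1 - a1 * b0, B2 = b2 - a2 * b0;
  // (I - A) = [[1 + a1, -1], [a2, 1]]
  double det = (1 + a1) * 1 - (-1) * a2;
  if (det == 0) { zi1 = zi2 = 0; return; }
  zi1 = (B1 * 1 - (-1) * B2) / det;
  zi2 = ((1 + a1) * B2 - a2 * B1) / det;
}

// Zero-phase (forward-backward) filtering of each row of X through a cascade
// of biquads; sos rows are (b0, b1, b2, a1, a2).  Edges are handled with
// odd-reflection padding and steady-state initial conditions per pass.
// [[Rcpp::export]]
NumericMatrix sosfiltfilt_cpp(NumericMatrix X, NumericMatrix sos, int pad) {
  const int nr = X.nrow(), nc = X.ncol(), ns = sos.nrow();
  if (nc < 2) stop("need >= 2 samples");
  const int nfact = std::min(pad, nc - 1);
  NumericMatrix out(nr, nc);

  std::vector<double> ext(nc + 2 * nfact);
  for (int r = 0; r < nr; ++r) {
    // odd reflection: 2*x[0] - x[k], 2*x[end] - x[end-k]
    for (int k = 0; k < nfact; ++k)
      ext[k] = 2 * X(r, 0) - X(r, nfact - k);
    for (int t = 0; t < nc; ++t) ext[nfact + t] = X(r, t);
    for (int k = 0; k < nfact; ++k)
      ext[nfact + nc + k] = 2 * X(r, nc - 1) - X(r, nc - 2 - k);

    for (int s = 0; s < ns; ++s) {
      double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      double a1 = sos(s, 3), a2 = sos(s, 4);
      double zi1, zi2;
      step_zi(b0, b1, b2, a1, a2, zi1, zi2);
      biquad(ext, b0, b1, b2, a1, a2, zi1, zi2);        // forward
      std::reverse(ext.begin(), ext.end());
      biquad(ext, b0, b1, b2, a1, a2, zi1, zi2);        // backward
      std::reverse(ext.begin(), ext.end());
    }
    for (int t = 0; t < nc; ++t) out(r, t) = ext[nfact + t];
  }
  return out;
}
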