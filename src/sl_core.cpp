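#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Synchronization likelihood over all channel pairs.
//
// Per channel c and reference index i, the critical distance eps_{c,i} is the
// p_ref-quantile (linear interpolation) of the Euclidean distances between
// delay-embedded vectors X_i and X_j over valid j with w1 < |i-j| <= w2.
// Recurrences (d <= eps) are stored as bit masks; the pairwise statistic is
//   SL(x,y) = mean_i [ (1/(p_ref * n_i)) * sum_j theta_x(i,j) theta_y(i,j) ],
// a coincident-recurrence count normalized so that independent series give
// ~p_ref and identical series give 1.
//
// X: channels x N data matrix. Returns the channels x channels SL matrix.
// [[Rcpp::export]]
NumericMatrix sl_matrix_cpp(NumericMatrix X, int m, int tau, int w1, int w2,
                            double p_ref) {
  const int nch = X.nrow();
  const int N = X.ncol();
  const int M = N - (m - 1) * tau;
  if (M < 2 * (w2 + 1))
    stop("usable vectors M = %d < 2*(w2+1) = %d; use longer epochs or concatenation",
         M, 2 * (w2 + 1));
  const int K = w2 - w1;          // offsets per side
  const int cols = 2 * K;         // negative side then positive side
  const int words = (cols + 63) / 64;

  // per-channel hit masks (M rows x `words` uint64) and shared row weights
  std::vector<std::vector<uint64_t>> hits(nch,
      std::vector<uint64_t>(static_cast<size_t>(M) * words, 0ULL));
  std::vector<double> wrow(M);

  std::vector<double> dist(cols);
  std::vector<double> buf(cols);

  for (int i = 0; i < M; ++i) {
    int nv = 0;
    for (int c = 0; c < cols; ++c) {
      int d = (c < K) ? -(w1 + 1 + c) : (w1 + 1 + (c - K));
      int j = i + d;
      if (j >= 0 && j < M) ++nv;
    }
    wrow[i] = 1.0 / (p_ref * nv);
  }

  std::vector<double> xs(N);
  // distance table D(i, c) for one channel, filled offset-by-offset so the
  // inner loops stream contiguously (vectorizable)
  std::vector<double> D(static_cast<size_t>(M) * cols);
  std::vector<double> e(N);
  for (int ch = 0; ch < nch; ++ch) {
    // contiguous copy of the channel (X is column-major, channels as rows)
    for (int t = 0; t < N; ++t) xs[t] = X(ch, t);
    for (int dd = w1 + 1; dd <= w2; ++dd) {
      // squared component differences at offset dd, then the m-term
      // embedded sum; D holds Euclidean distances
      const int nd = N - dd;
      for (int t = 0; t < nd; ++t) {
        double diff = xs[t] - xs[t + dd];
        e[t] = diff * diff;
      }
      const int mi = M - dd;              // pairs (i, i+dd) with both in range
      const int cneg = dd - w1 - 1;       // column for j = i - dd
      const int cpos = K + dd - w1 - 1;   // column for j = i + dd
      for (int i = 0; i < mi; ++i) {
        double s = e[i];
        for (int k = 1; k < m; ++k) s += e[i + k * tau];
        double dst = std::sqrt(s);
        D[static_cast<size_t>(i) * cols + cpos] = dst;        // j = i + dd
        D[static_cast<size_t>(i + dd) * cols + cneg] = dst;   // j = i - dd
      }
      for (int i = mi; i < M; ++i)
        D[static_cast<size_t>(i) * cols + cpos] = -1.0;
      for (int i = 0; i < std::min(dd, M); ++i)
        D[static_cast<size_t>(i) * cols + cneg] = -1.0;
    }
    for (int i = 0; i < M; ++i) {
      int nv = 0;
      const double* Di = D.data() + static_cast<size_t>(i) * cols;
      for (int c = 0; c < cols; ++c) {
        dist[c] = Di[c];
        if (dist[c] >= 0.0) buf[nv++] = dist[c];
      }
      // p_ref-quantile with linear interpolation (type 7)
      double h = (nv - 1) * p_ref;
      int lo = static_cast<int>(std::floor(h));
      std::nth_element(buf.begin(), buf.begin() + lo, buf.begin() + nv);
      double vlo = buf[lo];
      double eps;
      if (lo + 1 < nv && h > lo) {
        double vhi = *std::min_element(buf.begin() + lo + 1, buf.begin() + nv);
        eps = vlo + (h - lo) * (vhi - vlo);
      } else {
        eps = vlo;
      }
      uint64_t* row = &hits[ch][static_cast<size_t>(i) * words];
      for (int c = 0; c < cols; ++c) {
        if (dist[c] >= 0.0 && dist[c] <= eps)
          row[c >> 6] |= (1ULL << (c & 63));
      }
    }
  }

  NumericMatrix out(nch, nch);
  for (int a = 0; a < nch; ++a) {
    out(a, a) = 1.0;
    for (int b = a + 1; b < nch; ++b) {
      const uint64_t* ha = hits[a].data();
      const uint64_t* hb = hits[b].data();
      double acc = 0.0;
      for (int i = 0; i < M; ++i) {
        int joint = 0;
        const uint64_t* ra = ha + static_cast<size_t>(i) * words;
        const uint64_t* rb = hb + static_cast<size_t>(i) * words;
        for (int w = 0; w < words; ++w) {
#if defined(__GNUC__) || defined(__clang__)
          joint += __builtin_popcountll(ra[w] & rb[w]);
#else
          uint64_t v = ra[w] & rb[w];
          while (v) { v &= v - 1; ++joint; }
#endif
        }
        acc += wrow[i] * joint;
      }
      out(a, b) = out(b, a) = acc / M;
    }
  }
  return out;
}
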