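// Compiled kernels for the wavelet decomposition and cluster labelling.
// The wavelet transform is evaluated as a product in the discrete Fourier
// domain. Two devices keep the cost manageable at trial-level stacks:
//  - only the spectral band where the Morlet kernel spectrum is
//    non-negligible is multiplied and accumulated;
//  - when power is only needed on a decimated time grid (every m-th
//    sample), the product spectrum is folded modulo N/m and a length-N/m
//    inverse FFT recovers exactly the decimated samples of the full
//    convolution (aliasing identity of the DFT).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// sig: padded signals, N x nobs (zero-padded beyond the epoch).
// k1: 0-based first spectral bin per frequency; kv: kernel spectrum values
// on that band (already scaled and phase-rotated for the output offset).
// m: output decimation factor (N must be divisible by m).
// out_idx: 0-based indices into the decimated frame (length n_out).
// Returns power, (n_out * n_freq) x nobs, frequency-major blocks.
// [[Rcpp::export]]
arma::mat tf_power_core(const arma::mat& sig, const arma::ivec& k1,
                        const Rcpp::List& kv, int m,
                        const arma::uvec& out_idx) {
  const uword N = sig.n_rows, nobs = sig.n_cols, nf = kv.size();
  if (N % m != 0) Rcpp::stop("N must be divisible by m");
  const uword M = N / m;
  const uword nout = out_idx.n_elem;
  cx_mat X = fft(conv_to<cx_mat>::from(sig));
  mat out(nout * nf, nobs);
  cx_mat F(M, nobs);
  for (uword f = 0; f < nf; ++f) {
    cx_vec band = Rcpp::as<cx_vec>(kv[f]);
    const uword L = band.n_elem;
    const uword start = (uword)k1[f];
    F.zeros();
    const cx_double* bp = band.memptr();
    for (uword j = 0; j < nobs; ++j) {
      const cx_double* xc = X.colptr(j);
      cx_double* fc = F.colptr(j);
      uword k = start % N, km = start % M;
      for (uword t = 0; t < L; ++t) {
        fc[km] += xc[k] * bp[t];
        if (++k == N) k = 0;
        if (++km == M) km = 0;
      }
    }
    cx_mat Y = ifft(F) * (1.0 / m);  // ifft is 1/M-normalized; total 1/N
    for (uword j = 0; j < nobs; ++j) {
      const cx_double* yc = Y.colptr(j);
      double* oc = out.colptr(j) + f * nout;
      for (uword t = 0; t < nout; ++t) {
        const cx_double v = yc[out_idx[t]];
        oc[t] = v.real() * v.real() + v.imag() * v.imag();
      }
    }
  }
  return out;
}

// Row-wise maximum absolute value (per-trial/channel amplitude peaks).
// [[Rcpp::export]]
arma::vec row_abs_max(const arma::mat& x) {
  return max(abs(x), 1);
}

static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Label connected suprathreshold components of a statistic image.
// conn = 4 or 8. Returns an integer matrix, 0 = below threshold.
// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components(const arma::mat& stat, double thresh,
                                     int conn) {
  const int nr = stat.n_rows, nc = stat.n_cols;
  const int ndir = (conn == 4) ? 4 : 8;
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) != 0 || !(stat(r, c) > thresh)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int d = 0; d < ndir; ++d) {
          int qr = pr + DR8[d], qc = pc + DC8[d];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (lab(qr, qc) == 0 && stat(qr, qc) > thresh) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Largest suprathreshold component size in pixels (0 if none).
// [[Rcpp::export]]
int max_cluster_extent(const arma::mat& stat, double thresh, int conn) {
  Rcpp::IntegerMatrix lab = label_components(stat, thresh, conn);
  int mx = 0;
  std::vector<int> cnt;
  for (int i = 0; i < lab.length(); ++i) {
    int l = lab[i];
    if (l == 0) continue;
    if ((int)cnt.size() < l) cnt.resize(l, 0);
    if (++cnt[l - 1] > mx) mx = cnt[l - 1];
  }
  return mx;
}
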