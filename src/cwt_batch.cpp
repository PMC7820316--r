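// Batched FFT cross-correlation backend for the db7 continuous wavelet
// transform.  For each scale the zero-padded waveforms are correlated with
// the sampled, dilated wavelet kernel; the translation axis is re-indexed
// so that b is the centre of the dilated support.  Each scale uses the
// smallest adequate transform length (short kernels get short FFTs), and
// cross-correlations of real inputs are real, so two waveforms are packed
// into the real and imaginary parts of a single inverse transform.

// The per-element gather in the hot loop makes Armadillo's debug-mode
// bounds checks the dominant cost; sizes are validated up front instead.
#define ARMA_NO_DEBUG

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct CwtPlan {
  int n, m, S;
  std::vector<arma::vec> kernels;
  std::vector<int> centers, Ls;
  std::vector<int> Lset;                  // distinct transform lengths
  std::vector<arma::cx_mat> FX;           // forward FFTs per length
  std::vector<arma::uvec> idx;            // gather index per scale
};

CwtPlan make_plan(const arma::mat& X, const List& kernels,
                  const IntegerVector& centers, const IntegerVector& Ls) {
  CwtPlan pl;
  pl.n = X.n_rows; pl.m = X.n_cols; pl.S = kernels.size();
  if (centers.size() != pl.S || Ls.size() != pl.S)
    stop("kernels, centers and Ls must have equal length");
  for (int s = 0; s < pl.S; ++s) {
    NumericVector kv = kernels[s];
    const int K = kv.size(), C = centers[s];
    // only lags b - C for b in [0, n) are read back, so aliases must stay
    // outside the kernel-signal overlap for those lags alone
    if (Ls[s] < pl.n + std::max(C, K - C - 1))
      stop("transform length too short at scale index %d", s + 1);
    pl.kernels.push_back(arma::vec(kv.begin(), kv.size()));
    pl.centers.push_back(centers[s]);
    pl.Ls.push_back(Ls[s]);
  }
  for (int s = 0; s < pl.S; ++s)
    if (std::find(pl.Lset.begin(), pl.Lset.end(), pl.Ls[s]) == pl.Lset.end())
      pl.Lset.push_back(pl.Ls[s]);
  for (int L : pl.Lset) {
    arma::cx_mat F(L, pl.m);
    arma::vec xp(L, arma::fill::zeros);
    for (int j = 0; j < pl.m; ++j) {
      xp.zeros();
      xp.subvec(0, pl.n - 1) = X.col(j);
      F.col(j) = arma::fft(xp);
    }
    pl.FX.push_back(std::move(F));
  }
  for (int s = 0; s < pl.S; ++s) {
    const int L = pl.Ls[s], C = pl.centers[s];
    arma::uvec id(pl.n);
    for (int b = 0; b < pl.n; ++b) {
      int ii = (b - C) % L;
      if (ii < 0) ii += L;
      id(b) = static_cast<arma::uword>(ii);
    }
    pl.idx.push_back(std::move(id));
  }
  return pl;
}

// Visit |T(a, b)| for scale s, all waveforms; f(j, b, value).
template <typename F>
void scan_scale(const CwtPlan& pl, int s, F f) {
  const int L = pl.Ls[s];
  const arma::cx_mat& FX =
      pl.FX[std::find(pl.Lset.begin(), pl.Lset.end(), L) - pl.Lset.begin()];
  // kernels longer than L are folded modulo L (their circular aliases
  // fall outside the read-back lag range by construction)
  arma::vec kp(L, arma::fill::zeros);
  for (arma::uword i = 0; i < pl.kernels[s].n_elem; ++i)
    kp(i % static_cast<arma::uword>(L)) += pl.kernels[s](i);
  const arma::cx_vec Kf = arma::conj(arma::fft(kp));
  const arma::uvec& idx = pl.idx[s];
  const arma::cx_double I(0.0, 1.0);
  for (int j = 0; j < pl.m; j += 2) {
    if (j + 1 < pl.m) {
      arma::cx_vec z =
          arma::ifft(arma::cx_vec(FX.col(j) % Kf + I * (FX.col(j + 1) % Kf)));
      for (int b = 0; b < pl.n; ++b) {
        f(j, b, std::abs(std::real(z(idx(b)))));
        f(j + 1, b, std::abs(std::imag(z(idx(b)))));
      }
    } else {
      arma::cx_vec z = arma::ifft(arma::cx_vec(FX.col(j) % Kf));
      for (int b = 0; b < pl.n; ++b)
        f(j, b, std::abs(std::real(z(idx(b)))));
    }
  }
}

}  // namespace

// Full modulus cube: (scales x samples x waveforms).
// [[Rcpp::export]]
arma::cube cwt_batch_cpp(const arma::mat& X, const List& kernels,
                         const IntegerVector& centers,
                         const IntegerVector& Ls) {
  CwtPlan pl = make_plan(X, kernels, centers, Ls);
  arma::cube out(pl.S, pl.n, pl.m);
  for (int s = 0; s < pl.S; ++s)
    scan_scale(pl, s, [&](int j, int b, double v) { out(s, b, j) = v; });
  return out;
}

// Location of the modulus maximum per waveform without materialising the
// cube; ties take the smallest translation, then the smallest scale.
// Returns a 3 x m matrix: 1-based scale index, 1-based sample index, max.
// [[Rcpp::export]]
NumericMatrix cwt_argmax_cpp(const arma::mat& X, const List& kernels,
                             const IntegerVector& centers,
                             const IntegerVector& Ls) {
  CwtPlan pl = make_plan(X, kernels, centers, Ls);
  std::vector<double> best(pl.m, -1.0);
  std::vector<int> bs(pl.m, 0), bb(pl.m, 0);
  for (int s = 0; s < pl.S; ++s)
    scan_scale(pl, s, [&](int j, int b, double v) {
      // scales ascend and b ascends within a scale, so strict > keeps the
      // smallest scale at ties and > on b keeps the smallest translation
      if (v > best[j] || (v == best[j] && b < bb[j])) {
        best[j] = v; bs[j] = s; bb[j] = b;
      }
    });
  NumericMatrix out(3, pl.m);
  for (int j = 0; j < pl.m; ++j) {
    out(0, j) = bs[j] + 1;
    out(1, j) = bb[j] + 1;
    out(2, j) = best[j];
  }
  return out;
}
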