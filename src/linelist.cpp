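// Fast evaluation of the pulse-acquire line list and its sampled FID for
// the least-squares fitting loop. The Hamiltonian is block-diagonal over
// per-isotope total-projection sectors; each block is real symmetric.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// secInfo: list of list(msec [k x n], mprod [k x P], flips: list of
//          list(at [m x 2, 1-based], pid [1-based scalar]))
// links:   list of list(s1, s2 [1-based], Ob [k2 x k1])
// offsets: rotating-frame offsets (Hz) per spin; jvec: couplings (Hz) per
// pair (upper triangle order as in the context); returns the apodized FID.
// [[Rcpp::export]]
ComplexVector cpp_ctx_fid(List secInfo, List links, arma::vec offsets,
                          arma::vec jvec, double ampNorm, double decay,
                          double dwell, int nPoints,
                          double amplitudeCut = 1e-12) {
  const double twopi = 2.0 * M_PI;
  arma::vec off = twopi * offsets;
  arma::vec jv = twopi * jvec;

  int nSec = secInfo.size();
  std::vector<arma::vec> evals(nSec);
  std::vector<arma::mat> evecs(nSec);
  for (int s = 0; s < nSec; ++s) {
    List si = secInfo[s];
    arma::mat msec = si["msec"];
    arma::mat mprod = si["mprod"];
    arma::vec d = msec * off + mprod * jv;
    int k = d.n_elem;
    if (k == 1) {
      evals[s] = d;
      evecs[s] = arma::mat(1, 1, arma::fill::ones);
      continue;
    }
    arma::mat H = arma::diagmat(d);
    List flips = si["flips"];
    for (int f = 0; f < flips.size(); ++f) {
      List fl = flips[f];
      arma::imat at = fl["at"];
      int pid = as<int>(fl["pid"]) - 1;
      double v = 0.5 * jv(pid);
      for (arma::uword r = 0; r < at.n_rows; ++r)
        H(at(r, 0) - 1, at(r, 1) - 1) += v;
    }
    arma::eig_sym(evals[s], evecs[s], H);
  }

  std::vector<double> freq, amp;
  freq.reserve(1024); amp.reserve(1024);
  double maxA = 0.0;
  for (int li = 0; li < links.size(); ++li) {
    List lk = links[li];
    int s1 = as<int>(lk["s1"]) - 1;
    int s2 = as<int>(lk["s2"]) - 1;
    arma::mat Ob = lk["Ob"];
    arma::mat Ot = evecs[s2].t() * Ob * evecs[s1];
    for (arma::uword i = 0; i < Ot.n_rows; ++i)
      for (arma::uword j = 0; j < Ot.n_cols; ++j) {
        double a = Ot(i, j) * Ot(i, j);
        if (a <= 0) continue;
        if (a > maxA) maxA = a;
        amp.push_back(a);
        freq.push_back((evals[s2](i) - evals[s1](j)) / twopi);
      }
  }

  // FID accumulation over lines above the amplitude cut
  std::vector<std::complex<double> > cur, u;
  cur.reserve(amp.size()); u.reserve(amp.size());
  double damp = std::exp(-decay * dwell);
  for (size_t l = 0; l < amp.size(); ++l) {
    if (amp[l] <= amplitudeCut * maxA) continue;
    cur.push_back(std::complex<double>(amp[l] / ampNorm, 0.0));
    double ang = -twopi * freq[l] * dwell;
    u.push_back(std::complex<double>(damp * std::cos(ang),
                                     damp * std::sin(ang)));
  }
  ComplexVector out(nPoints);
  size_t L = cur.size();
  for (int k = 0; k < nPoints; ++k) {
    std::complex<double> acc(0.0, 0.0);
    for (size_t l = 0; l < L; ++l) {
      acc += cur[l];
      cur[l] *= u[l];
    }
    out[k].r = acc.real();
    out[k].i = acc.imag();
  }
  return out;
}
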