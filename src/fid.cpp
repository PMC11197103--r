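#include <Rcpp.h>
using namespace Rcpp;

// Sampled FID of a line list: samples[k] = sum_l A_l * u_l^k with
// u_l = exp((-2i*pi*nu_l - R) * dwell). Evaluated by geometric
// progression, one complex multiply-add per line and point.
// [[Rcpp::export]]
ComplexVector cpp_fid_lines(NumericVector amplitude, NumericVector freqHz,
                            double decay, double dwell, int nPoints) {
  int L = amplitude.size();
  std::vector<std::complex<double> > cur(L), u(L);
  for (int l = 0; l < L; ++l) {
    cur[l] = std::complex<double>(amplitude[l], 0.0);
    double ang = -2.0 * M_PI * freqHz[l] * dwell;
    double damp = std::exp(-decay * dwell);
    u[l] = std::complex<double>(damp * std::cos(ang), damp * std::sin(ang));
  }
  ComplexVector out(nPoints);
  for (int k = 0; k < nPoints; ++k) {
    std::complex<double> acc(0.0, 0.0);
    for (int l = 0; l < L; ++l) {
      acc += cur[l];
      cur[l] *= u[l];
    }
    out[k].r = acc.real();
    out[k].i = acc.imag();
  }
  return out;
}
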