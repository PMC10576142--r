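// Numerical propagation of methyl multiple-quantum coherences through a
// constant-time CPMG train under n-site chemical exchange.
//
// The coherence vector holds one complex amplitude per exchanging state.
// Zero-quantum (H+C-) amplitudes evolve under
//   L_ZQ = K - R2*I - i*diag(wH - wC)
// and double-quantum (H+C+) amplitudes under
//   L_DQ = K - R2*I - i*diag(wH + wC),
// where K is the exchange generator (columns sum to zero), wH/wC are the
// 1H/13C offsets in rad/s relative to the major state, and R2 the
// intrinsic MQ relaxation rate (shared across states, so it factors out
// of the propagation exactly).  A 13C 180-degree pulse interchanges
// ZQ <-> DQ; the single 1H 180-degree pulse at the centre of the train
// conjugates the amplitudes and interchanges ZQ <-> DQ (H+C- -> H-C-,
// the conjugate of H+C+).
//
// Free-precession delays are applied as exact matrix exponentials, so
// there is no time-step discretisation error.

#include <RcppArmadillo.h>

using namespace arma;

static arma::vec mq_r2eff_impl(const arma::mat& K,
                               double r2_mq0,
                               const arma::vec& dwC_rad,
                               const arma::vec& dwH_rad,
                               const arma::vec& p0,
                               const arma::ivec& npulses,
                               double T_relax) {
  const uword n = K.n_rows;
  const cx_double I(0.0, 1.0);
  cx_mat Kc = conv_to<cx_mat>::from(K);
  Kc.diag() -= r2_mq0;
  cx_mat LZ = Kc;
  cx_mat LD = Kc;
  for (uword s = 0; s < n; ++s) {
    LZ(s, s) -= I * (dwH_rad(s) - dwC_rad(s));
    LD(s, s) -= I * (dwH_rad(s) + dwC_rad(s));
  }
  cx_vec p = conv_to<cx_vec>::from(p0);

  vec out(npulses.n_elem);
  for (uword k = 0; k < npulses.n_elem; ++k) {
    const int np = npulses(k);           // even number of 13C 180 pulses
    const double delta = T_relax / (2.0 * np);
    cx_mat EZ = expmat(LZ * delta);
    cx_mat ED = expmat(LD * delta);
    cx_vec v = p;
    int frame = 0;                       // 0 = ZQ, 1 = DQ
    for (int b = 1; b <= np; ++b) {
      v = (frame == 0 ? EZ : ED) * v;    // first half-echo delay
      frame = 1 - frame;                 // 13C 180
      v = (frame == 0 ? EZ : ED) * v;    // second half-echo delay
      if (2 * b == np) {                 // central 1H 180
        v = conj(v);
        frame = 1 - frame;
      }
    }
    double sig = std::abs(accu(v));
    double s0 = std::abs(accu(p));
    out(k) = -std::log(sig / s0) / T_relax;
  }
  return out;
}

RcppExport SEXP excat_mq_r2eff(SEXP Ks, SEXP r2s, SEXP dwCs, SEXP dwHs,
                               SEXP p0s, SEXP nps, SEXP Ts) {
  BEGIN_RCPP
  arma::mat K = Rcpp::as<arma::mat>(Ks);
  double r2 = Rcpp::as<double>(r2s);
  arma::vec dwC = Rcpp::as<arma::vec>(dwCs);
  arma::vec dwH = Rcpp::as<arma::vec>(dwHs);
  arma::vec p0 = Rcpp::as<arma::vec>(p0s);
  arma::ivec np = Rcpp::as<arma::ivec>(nps);
  double T = Rcpp::as<double>(Ts);
  return Rcpp::wrap(mq_r2eff_impl(K, r2, dwC, dwH, p0, np, T));
  END_RCPP
}
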