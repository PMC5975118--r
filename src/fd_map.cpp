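#include <Rcpp.h>
using namespace Rcpp;

// Iterate the facilitation-depression map over a vector of inter-spike
// intervals. State convention: (C_n, P_n, R_n) just after spike n, with R_n
// the pre-release pool at spike n; the update uses (1 - P_n) R_n as the
// post-release initial condition of the recovery ODE.
// [[Rcpp::export]]
List fd_simulate_cpp(NumericVector isis, double C0, double P0, double R0,
                     double tau_ca, double delta, double p_max, double K,
                     double K_r, double k_min, double exponent) {
  const int n = isis.size();
  NumericVector C(n), P(n), R(n), Pr(n);
  const double K4 = K * K * K * K;
  double c = C0, p = P0, r = R0;
  for (int i = 0; i < n; ++i) {
    const double T = isis[i];
    const double dec = std::exp(-T / tau_ca);
    const double c_dec = c * dec;
    const double c_new = c_dec + delta;
    const double c4 = c_new * c_new * c_new * c_new;
    const double p_new = p_max * c4 / (c4 + K4);
    const double r_new = 1.0 - (1.0 - (1.0 - p) * r) *
      std::pow((c_dec + K_r) / (K_r + c), exponent) *
      std::exp(-k_min * T);
    c = c_new; p = p_new; r = r_new;
    C[i] = c; P[i] = p; R[i] = r; Pr[i] = p * r;
  }
  return List::create(_["C"] = C, _["P"] = P, _["R"] = R, _["Pr"] = Pr);
}

// Stationary samples of the calcium recurrence C_n = C_{n-1} e^{-T_n/tau} + delta_n
// alone (no release machinery), for goodness-of-fit against the gamma law.
// deltas may be constant or i.i.d. draws, one per spike.
// [[Rcpp::export]]
NumericVector calcium_recurrence_cpp(NumericVector isis, NumericVector deltas,
                                     double C0, double tau_ca) {
  const int n = isis.size();
  if (deltas.size() != n) stop("need one influx value per ISI");
  NumericVector C(n);
  double c = C0;
  for (int i = 0; i < n; ++i) {
    c = c * std::exp(-isis[i] / tau_ca) + deltas[i];
    C[i] = c;
  }
  return C;
}
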