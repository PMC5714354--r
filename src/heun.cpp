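#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared with R/params.R (as_par_vector):
// 0 He, 1 Hi, 2 tau_e, 3 tau_i, 4 N_EP, 5 N_PE, 6 N_IP, 7 N_PI,
// 8 N_PP, 9 N_II, 10 e0, 11 r, 12 v0, 13 b1, 14 b2

static inline double sigm(double V, const double* P) {
  double z = P[11] * (P[12] - V);
  if (z > 500.0) z = 500.0; else if (z < -500.0) z = -500.0;
  return 2.0 * P[10] / (1.0 + std::exp(z));
}

// dy/dt for one circuit; y = (V1..V5, W1..W5)
static inline void circuit_deriv(const double* y, double pext, double piin,
                                 const double* P, double* dy) {
  double phiP = sigm(y[1] - y[2], P);
  double phiE = sigm(y[0], P);
  double phiI = sigm(y[3] - y[4], P);
  double b1 = P[13], b2 = P[14];
  double u[5];
  u[0] = P[4] * phiP + b1 * pext;
  u[1] = b1 * P[5] * phiE + (1.0 - b1) * P[8] * phiP + (1.0 - b1) * pext;
  u[2] = P[7] * phiI;
  u[3] = P[6] * phiP + piin;
  u[4] = (1.0 - b2) * P[9] * phiI;
  // channels 1,2,4 excitatory; 3,5 inhibitory
  const int exc[5] = {1, 1, 0, 1, 0};
  for (int c = 0; c < 5; ++c) {
    double H = exc[c] ? P[0] : P[1];
    double tau = exc[c] ? P[2] : P[3];
    dy[c] = y[5 + c];
    dy[5 + c] = (H / tau) * u[c] - (2.0 / tau) * y[5 + c] - y[c] / (tau * tau);
  }
}

// [[Rcpp::export]]
NumericMatrix heun_circuit_cpp(NumericVector y0, NumericVector pars,
                               NumericVector pext, NumericVector piin,
                               double dt) {
  int n = pext.size();
  if (piin.size() != n) stop("pext and piin grids differ in length");
  if (y0.size() != 10) stop("state must have 10 components");
  NumericMatrix out(n, 10);
  double y[10], yp[10], k1[10], k2[10];
  const double* P = pars.begin();
  for (int j = 0; j < 10; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  for (int i = 0; i < n - 1; ++i) {
    double pe = pext[i], pi = piin[i];  // frozen over both stages
    circuit_deriv(y, pe, pi, P, k1);
    for (int j = 0; j < 10; ++j) yp[j] = y[j] + dt * k1[j];
    circuit_deriv(yp, pe, pi, P, k2);
    for (int j = 0; j < 10; ++j) y[j] += 0.5 * dt * (k1[j] + k2[j]);
    for (int j = 0; j < 10; ++j) {
      if (!std::isfinite(y[j]) || std::fabs(y[j]) > 1e8)
        stop("integration diverged at step %d (t = %g s)", i + 1, (i + 1) * dt);
      out(i + 1, j) = y[j];
    }
  }
  return out;
}

// Network of coupled circuits.  Excitatory inter-node input enters the
// target's p_ext route; inhibitory inter-node input drives the target's IIN
// (piin route).  Contextual inhibition is subtracted from the afferent
// p_ext with a floor at zero.
// [[Rcpp::export]]
List heun_network_cpp(NumericMatrix y0, NumericMatrix pars,
                      NumericMatrix wordin, NumericMatrix context,
                      NumericMatrix iin_in,
                      NumericMatrix w_exc, NumericMatrix w_inh,
                      double dt) {
  int nn = y0.nrow();
  int n = wordin.nrow();
  if (pars.nrow() != nn) stop("pars must have one row per node");
  NumericMatrix vpy(n, nn);
  std::vector<double> y(10 * nn), yp(10 * nn), k1(10 * nn), k2(10 * nn);
  std::vector<double> phi(nn), pe(nn), pi(nn), P(15 * nn);
  for (int k = 0; k < nn; ++k)
    for (int q = 0; q < 15; ++q) P[15 * k + q] = pars(k, q);
  for (int k = 0; k < nn; ++k)
    for (int j = 0; j < 10; ++j) y[10 * k + j] = y0(k, j);
  for (int k = 0; k < nn; ++k) vpy(0, k) = y[10 * k + 1] - y[10 * k + 2];

  for (int i = 0; i < n - 1; ++i) {
    // stage 1: drives from current state
    for (int k = 0; k < nn; ++k)
      phi[k] = sigm(y[10 * k + 1] - y[10 * k + 2], &P[15 * k]);
    for (int k = 0; k < nn; ++k) {
      double exc = 0.0, inh = 0.0;
      for (int s = 0; s < nn; ++s) {
        exc += w_exc(k, s) * phi[s];
        inh += w_inh(k, s) * phi[s];
      }
      pe[k] = wordin(i, k) + exc - context(i, k);
      if (pe[k] < 0.0) pe[k] = 0.0;
      pi[k] = iin_in(i, k) + inh;
    }
    for (int k = 0; k < nn; ++k)
      circuit_deriv(&y[10 * k], pe[k], pi[k], &P[15 * k], &k1[10 * k]);
    for (int j = 0; j < 10 * nn; ++j) yp[j] = y[j] + dt * k1[j];
    // stage 2: firing rates from predictor state; external drives frozen
    for (int k = 0; k < nn; ++k)
      phi[k] = sigm(yp[10 * k + 1] - yp[10 * k + 2], &P[15 * k]);
    for (int k = 0; k < nn; ++k) {
      double exc = 0.0, inh = 0.0;
      for (int s = 0; s < nn; ++s) {
        exc += w_exc(k, s) * phi[s];
        inh += w_inh(k, s) * phi[s];
      }
      pe[k] = wordin(i, k) + exc - context(i, k);
      if (pe[k] < 0.0) pe[k] = 0.0;
      pi[k] = iin_in(i, k) + inh;
    }
    for (int k = 0; k < nn; ++k)
      circuit_deriv(&yp[10 * k], pe[k], pi[k], &P[15 * k], &k2[10 * k]);
    for (int j = 0; j < 10 * nn; ++j) y[j] += 0.5 * dt * (k1[j] + k2[j]);
    for (int k = 0; k < nn; ++k) {
      for (int j = 0; j < 10; ++j)
        if (!std::isfinite(y[10 * k + j]) || std::fabs(y[10 * k + j]) > 1e8)
          stop("network integration diverged at node %d, step %d", k + 1, i + 1);
      vpy(i + 1, k) = y[10 * k + 1] - y[10 * k + 2];
    }
  }
  NumericMatrix yfinal(nn, 10);
  for (int k = 0; k < nn; ++k)
    for (int j = 0; j < 10; ++j) yfinal(k, j) = y[10 * k + j];
  return List::create(_["vpy"] = vpy, _["final_state"] = yfinal);
}
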