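#include <Rcpp.h>
using namespace Rcpp;

// One trial (ITI + stimulation) of the coupled phase/rate dynamics.
//
// Per-step contract (mirrored exactly by the pure-R reference engine,
// including the RNG draw order):
//   1. if gating is on:
//      a. during the ITI and when a negative prediction error is pending,
//         draw unif for the Gaussian-windowed feedback burst to the pMFC;
//      b. draw unif for the pMFC Bernoulli burst output;
//      c. draw the shared standard-normal burst noise U;
//      d. advance the pMFC phase pair (with the feedback burst);
//      e. advance every processing-node phase pair with burst
//         sign_i * pMFC_out * U;
//      f. gains = G(E) of the updated excitatory activations;
//      otherwise gains are 1 and no random numbers are consumed.
//   2. net inputs from the PREVIOUS step's rate activations (synchronous
//      update); layer 1 is driven directly by the external input (only
//      during stimulation), deeper layers by f(net - bias) (sigmoid for the
//      BP network, identity without bias for RW).
//   3. x <- f(net - bias) * gain (the unit leak -x cancels the old value);
//      running trial maxima X are updated.
// [[Rcpp::export]]
List trial_dynamics_cpp(NumericVector E0, NumericVector I0, NumericVector x0,
                        double E_pmfc, double I_pmfc,
                        NumericMatrix W1, NumericMatrix W2,
                        NumericVector lfc_sign, NumericVector input,
                        double delta_min_prev,
                        double C_proc, double damp_proc, double rmin_proc,
                        double C_ctrl, double damp_ctrl, double rmin_ctrl,
                        bool sigmoid_act, double bias, bool gating_on,
                        int n_steps, int iti_steps, double dt_ms,
                        bool record) {
  const int n1 = input.size();
  const int n2 = W1.ncol();
  const int n3 = (W2.nrow() > 0) ? W2.ncol() : 0;
  const int n = n1 + n2 + n3;

  NumericVector E = clone(E0), I = clone(I0), x = clone(x0);
  NumericVector xnew(n), gains(n, 1.0), X(n);
  NumericMatrix traceE = record ? NumericMatrix(n_steps, n) : NumericMatrix(0, 0);
  NumericVector traceP = record ? NumericVector(n_steps) : NumericVector(0);

  const double rmin2p = rmin_proc * rmin_proc;
  const double rmin2c = rmin_ctrl * rmin_ctrl;

  for (int t = 1; t <= n_steps; ++t) {
    if (gating_on) {
      // Gaussian-windowed feedback bursts (peak 200 ms, sd 25 ms): per-step
      // Bernoulli kicks of size delta-minus to the pMFC excitatory neuron.
      double fb = 0.0;
      if (t <= iti_steps && delta_min_prev > 0.0) {
        double tms = t * dt_ms;
        double P = std::exp(-(tms - 200.0) * (tms - 200.0) / (2.0 * 25.0 * 25.0));
        if (unif_rand() < P) fb = delta_min_prev;
      }
      double p = 1.0 / (1.0 + std::exp(-10.0 * (E_pmfc - 1.0)));
      double pm_out = (unif_rand() < p) ? 1.0 : 0.0;
      double U = norm_rand();

      double Jm = (E_pmfc * E_pmfc + I_pmfc * I_pmfc > rmin2c) ? 1.0 : 0.0;
      double Ep = E_pmfc + (-C_ctrl * I_pmfc - damp_ctrl * Jm * E_pmfc + fb);
      double Ip = I_pmfc + (C_ctrl * E_pmfc - damp_ctrl * Jm * I_pmfc);
      E_pmfc = Ep;
      I_pmfc = Ip;

      for (int i = 0; i < n; ++i) {
        double J = (E[i] * E[i] + I[i] * I[i] > rmin2p) ? 1.0 : 0.0;
        double B = lfc_sign[i] * pm_out * U;
        double Ei = E[i] + (-C_proc * I[i] - damp_proc * J * E[i] + B);
        double Ii = I[i] + (C_proc * E[i] - damp_proc * J * I[i]);
        E[i] = Ei;
        I[i] = Ii;
        gains[i] = 1.0 / (1.0 + std::exp(-5.0 * (E[i] - 0.6)));
      }
    }

    // Within-step feedforward cascade: each layer reads the CURRENT step's
    // upstream activations, so communication is zero-lag. (A lagged update
    // would let one sign-flipping burst pair a pre-flip upstream activation
    // with a post-flip open gate, defeating the anti-phase protection.)
    bool stim = t > iti_steps;
    for (int i = 0; i < n1; ++i) {
      double net = stim ? input[i] : 0.0;
      xnew[i] = net * gains[i];
    }
    for (int j = 0; j < n2; ++j) {
      double net = 0.0;
      for (int k = 0; k < n1; ++k) net += W1(k, j) * xnew[k];
      double drive = sigmoid_act ? 1.0 / (1.0 + std::exp(-(net - bias))) : net;
      xnew[n1 + j] = drive * gains[n1 + j];
    }
    for (int o = 0; o < n3; ++o) {
      double net = 0.0;
      for (int j = 0; j < n2; ++j) net += W2(j, o) * xnew[n1 + j];
      double drive = sigmoid_act ? 1.0 / (1.0 + std::exp(-(net - bias))) : net;
      xnew[n1 + n2 + o] = drive * gains[n1 + n2 + o];
    }
    for (int i = 0; i < n; ++i) {
      x[i] = xnew[i];
      if (x[i] > X[i]) X[i] = x[i];
    }
    if (record) {
      for (int i = 0; i < n; ++i) traceE(t - 1, i) = E[i];
      traceP[t - 1] = E_pmfc;
    }
  }

  List out = List::create(_["E"] = E, _["I"] = I, _["x"] = x, _["X"] = X,
                          _["E_pmfc"] = E_pmfc, _["I_pmfc"] = I_pmfc);
  if (record) {
    out["trace_E"] = traceE;
    out["trace_pmfc"] = traceP;
  }
  return out;
}
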