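#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thresholded generalized sigmoid: sigmoid value if >= threshold, else 0.
static inline double resp(double x, double gain, double offset, double thr) {
  double s = 1.0 / (1.0 + std::exp(-gain * (x - offset)));
  return s >= thr ? s : 0.0;
}

// Two-phase synchronous Euler integration of the coupled rate equations.
// The option-value gate Phi_v(W_uv) is constant within a round and is
// precomputed by the caller. Must stay numerically identical to iterating
// euler_step() in R: same update order, both populations advanced from
// pre-step values.
// [[Rcpp::export]]
List integrate_phases_cpp(NumericVector u0, NumericVector v0,
                          NumericVector gate, int n_pre, int n_post,
                          double dt, double tau_u, double tau_v,
                          double i_ext, double u_gain, double u_offset,
                          double u_threshold, double v_gain, double v_offset,
                          double v_threshold) {
  int K = u0.size();
  NumericVector u = clone(u0), v = clone(v0);
  double au = dt / tau_u, av = dt / tau_v;
  for (int phase = 0; phase < 2; ++phase) {
    int n = phase == 0 ? n_pre : n_post;
    double inp = phase == 0 ? i_ext : 0.0;
    for (int s = 0; s < n; ++s) {
      for (int k = 0; k < K; ++k) {
        double u_old = u[k];
        u[k] = u[k] + au * (-u[k] + resp(v[k], v_gain, v_offset, v_threshold) + inp);
        v[k] = v[k] + av * (-v[k] + gate[k] * resp(u_old, u_gain, u_offset, u_threshold));
      }
    }
  }
  return List::create(_["u"] = u, _["v"] = v);
}
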