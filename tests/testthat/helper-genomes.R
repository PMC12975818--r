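# Genomes engineered for analytic checks.

# All response thresholds at 1: a finite sigmoid never reaches 1, so both
# populations are silenced and the coupling is inert. u then follows the
# scalar linear ODE driven by I_ext alone.
inert_genome <- function(tau_u = 25, tau_v = 40, i_ext = 1.5) {
  nsa_genome(
    tau_u = tau_u, tau_v = tau_v, i_ext = i_ext,
    dur_pre = 400, dur_post = 400, w_plus = 1,
    resp_u = response_params(gain = 5, offset = 0.5, threshold = 1),
    resp_v = response_params(gain = 5, offset = 0.5, threshold = 1),
    phi_v = gaussian_sigmoid_params(0.5, 4, 0.5, 0.2, 0.1),
    phi_eta = gaussian_sigmoid_params(1, 1, 0, 0, 0.5))
}

# Slope-0 sigmoid is constant 0.5 and the Gaussian bump is parked far from
# the weight range, so phi_eta = (1 - alpha) * 0.5 exactly: a constant
# learning rate of (1 - alpha) / 2, independent of the weight.
constant_eta_genome <- function(eta = 0.1, w_plus = 1) {
  stopifnot(eta >= 0, eta <= 0.5)
  nsa_genome(
    tau_u = 20, tau_v = 20, i_ext = 1,
    dur_pre = 400, dur_post = 400, w_plus = w_plus,
    resp_u = response_params(gain = 5, offset = 0.5, threshold = 0),
    resp_v = response_params(gain = 5, offset = 0.5, threshold = 0),
    phi_v = gaussian_sigmoid_params(0.5, 4, 0.5, 0.2, 0.1),
    phi_eta = gaussian_sigmoid_params(1 - 2 * eta, 0, 0, -100, 0.01))
}

# Hand-designed genome with a monotone option-value filter: strong weights
# gate the U-to-V pathway open, so a trained arm sustains the coupling loop
# through the autonomous phase and wins both argmaxes.
selective_genome <- function() {
  nsa_genome(
    tau_u = 20, tau_v = 20, i_ext = 1,
    dur_pre = 500, dur_post = 500, w_plus = 1,
    resp_u = response_params(gain = 12, offset = 0.35, threshold = 0.1),
    resp_v = response_params(gain = 12, offset = 0.35, threshold = 0.35),
    phi_v = gaussian_sigmoid_params(0.3, 12, 0.6, 0, 0.15),
    phi_eta = gaussian_sigmoid_params(0.95, 1, 2, 0, 0.4))
}

# Random but dynamically sane genome for property tests.
random_genome <- function() {
  nsa_genome(
    tau_u = runif(1, 5, 100), tau_v = runif(1, 5, 100),
    i_ext = runif(1, 0.1, 3),
    dur_pre = runif(1, 400, 800), dur_post = runif(1, 400, 800),
    w_plus = runif(1, 0.5, 3),
    resp_u = response_params(runif(1, 0.5, 20), runif(1, -0.5, 1.5),
                             runif(1)),
    resp_v = response_params(runif(1, 0.5, 20), runif(1, -0.5, 1.5),
                             runif(1)),
    phi_v = gaussian_sigmoid_params(runif(1), runif(1, 0.5, 20),
                                    runif(1, -0.5, 1.5), runif(1, -0.5, 1.5),
                                    runif(1, 0.05, 1)),
    phi_eta = gaussian_sigmoid_params(runif(1), runif(1, 0.5, 20),
                                      runif(1, -0.5, 1.5),
                                      runif(1, -0.5, 1.5),
                                      runif(1, 0.05, 1)))
}
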