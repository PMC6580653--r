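# Reference operating points used across the suite.

# High-potency silencing: beta ~ 0.5, Hopf delay ~ 3.359.
fig1_params <- function(tau1 = 3.3594, S = 30, tau2 = 1) {
  rnai_params(km = 10, dm = 0.05, kp = 1, dp = 0.01, r = 0.5062,
              theta = 10, n = 4, S = S, tau1 = tau1, tau2 = tau2)
}

# Low-potency silencing used by the dosage-selection problems (r = 0.02).
q_params <- function(tau1 = 2.5, tau2 = 1) {
  rnai_params(km = 10, dm = 0.05, kp = 1, dp = 0.01, r = 0.02,
              theta = 10, n = 4, S = 30, tau1 = tau1, tau2 = tau2)
}

ref_init <- function() initial_condition(160, 10000)

# Silencing switched off (S = 0 so beta = 0); the model is then linear.
no_rnai_params <- function(tau1 = 0, tau2 = 0) {
  rnai_params(km = 10, dm = 0.05, kp = 1, dp = 0.01, r = 0.02,
              theta = 10, n = 4, S = 0, tau1 = tau1, tau2 = tau2)
}
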