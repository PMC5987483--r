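# Small shared fixtures for the test suite (built in code, not stored).

tiny_spec <- function() sf6d_spec(c(2L, 2L, 2L, 2L, 2L, 2L))

# a three-state toy truth on the full lattice spec
toy_truth <- function(values = c("222222" = 0.8, "333333" = 0.6,
                                 "423455" = 0.45)) {
  structure(list(values = values, spec = sf6d_spec(), decrements = NULL,
                 perturbation_scale = 0, perturbation = NULL, floor = -1,
                 seed = NULL),
            class = "true_utility")
}

quick_ctl <- function(iterations = 1500, burn_in = 500, thin = 2, ...) {
  npb_control(iterations = iterations, burn_in = burn_in, thin = thin, ...)
}

# posterior-mean prediction function for the monotonicity audit
mean_predictor <- function(fit) {
  function(codes) predict(fit, codes)$mean
}
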