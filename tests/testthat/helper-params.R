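# Shared fixtures: a small fast parameter set and cheap simulation wrappers.
# All fixtures are built in code; nothing is read from disk except the
# package's own default configuration.

fast_params <- function() default_parameters()

# short simulation at a coarse (but spec-conformant) step for structural tests
quick_sim <- function(tau = 12, days = 3, type = "wild_type",
                      params = fast_params(), dt = 0.05, ...) {
  simulate_plant(tau, days, type, params, dt = dt, ...)
}

expect_all_finite <- function(df) {
  expect_true(all(vapply(df, function(col) all(is.finite(col)), logical(1))))
}
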