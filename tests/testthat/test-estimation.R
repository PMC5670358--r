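test_that("the cost is zero on model-generated data and quadratic in the residuals", {
  p <- fast_params()
  d <- generate_growth_dataset(p, noise_sigma = 0, seed = 1, dt = 0.05)
  P0 <- growth_cost(p$sink$alpha_max, p$sink$n_tilde, p$sink$K_tilde, d, p, dt = 0.05)
  expect_lt(P0, 1e-20)
  # a single perturbed observation contributes its squared residual
  d1 <- d
  d1$fresh_weight_g[3] <- d1$fresh_weight_g[3] + 0.01
  P1 <- growth_cost(p$sink$alpha_max, p$sink$n_tilde, p$sink$K_tilde, d1, p, dt = 0.05)
  expect_equal(P1, 1e-4, tolerance = 1e-6)
  # doubling every residual quadruples the cost
  d2 <- d
  d2$fresh_weight_g <- attr(d, "truth")$fresh_weight_g * 1.1
  d4 <- d
  d4$fresh_weight_g <- attr(d, "truth")$fresh_weight_g * 1.2
  P2 <- growth_cost(p$sink$alpha_max, p$sink$n_tilde, p$sink$K_tilde, d2, p, dt = 0.05)
  P4 <- growth_cost(p$sink$alpha_max, p$sink$n_tilde, p$sink$K_tilde, d4, p, dt = 0.05)
  expect_equal(P4 / P2, 4, tolerance = 1e-6)
})

test_that("the cost is invariant under record order and errors beyond the horizon", {
  p <- fast_params()
  d <- generate_growth_dataset(p, noise_sigma = 0.05, seed = 2, dt = 0.05)
  Pa <- growth_cost(2, 2, 1.5, d, p, dt = 0.05)
  Pb <- growth_cost(2, 2, 1.5, d[sample.int(nrow(d)), ], p, dt = 0.05)
  expect_equal(Pa, Pb)
  expect_error(growth_cost(2, 2, 1.5,
                           transform(d, time_h = time_h + 1e5), p, dt = 0.05),
               class = "phloemclock_config_error")
})

test_that("the fit recovers the generating kinetics from noise-free data", {
  # a close pair of starts keeps this unit fast; the full 8-corner multistart
  # recovery at 2% is exercised by the acceptance suite
  p <- fast_params()
  d <- generate_growth_dataset(p, noise_sigma = 0, seed = 1, dt = 0.05)
  truth <- c(p$sink$alpha_max, p$sink$n_tilde, p$sink$K_tilde)
  starts <- matrix(c(2, 3, 1.5, 3, 3, 3), 2, byrow = TRUE,
                   dimnames = list(NULL, c("alpha_max", "n_tilde", "K_tilde")))
  fit <- fit_growth_params(d, p, starts = starts, dt = 0.05)
  expect_s3_class(fit, "growth_fit")
  expect_lt(max(abs(fit$estimates / truth - 1)), 0.05)
  # optimizer contract: final cost not above the cost at any start
  start_cost <- growth_cost(2, 3, 1.5, d, p, dt = 0.05)
  expect_lte(fit$cost, start_cost)
})

test_that("fit results serialize to JSON", {
  fit <- structure(list(estimates = c(alpha_max = 2, n_tilde = 3, K_tilde = 1),
                        cost = 0.5, converged = TRUE, multiple_minima = FALSE,
                        n_starts = 1, starts = list()), class = "growth_fit")
  f <- tempfile(fileext = ".json")
  write_fit_result(fit, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$estimates$alpha_max, 2)
  expect_false(j$multiple_minima)
})
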