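test_that("light resets pin the phase to 0 at dawn and tau_L at dusk", {
  expect_equal(light_reset(5.3, "dawn", 16), 0)
  expect_equal(light_reset(14.0, "dusk", 16), 16)
  expect_equal(light_reset(9.9, "dusk", 8), 8)
})

test_that("the sucrose PRC advances before the subjective dusk and delays after", {
  for (ps in c(8, 10, 12, 16)) {
    expect_equal(sucrose_prc(0, ps), 0, tolerance = 1e-12)
    expect_equal(sucrose_prc(ps, ps), 0, tolerance = 1e-12)
    expect_gt(sucrose_prc(ps / 2, ps), 0)
    expect_lt(sucrose_prc((ps + 24) / 2, ps), 0)
    phi <- seq(0.01, ps - 0.01, length.out = 50)
    expect_true(all(sucrose_prc(phi, ps) > 0))
    phi <- seq(ps + 0.01, 23.99, length.out = 50)
    expect_true(all(sucrose_prc(phi, ps) < 0))
  }
  # continuity and 24-periodicity on a fine grid
  phi <- seq(0, 24, by = 0.01)
  z <- sucrose_prc(phi, 10, 0.7)
  expect_lt(max(abs(diff(z))), 0.01)
  expect_equal(sucrose_prc(phi, 10), sucrose_prc(phi + 24, 10))
})

test_that("the sugar input is a signed Hill, gated by light", {
  expect_equal(sugar_input(0, 0.5, 2), 0)
  expect_equal(sugar_input(3.7, 0.5, 2, is_light = FALSE), 0)
  expect_equal(sugar_input(0.5, 0.5, 2), 0.5)
  expect_equal(sugar_input(-0.5, 0.5, 2), -0.5)
  x <- seq(-5, 5, by = 0.1)
  v <- sugar_input(x, 0.5, 2)
  expect_true(all(abs(v) <= 1))
  expect_equal(v, -rev(v))                     # odd symmetry
  expect_true(all(diff(v) >= 0))               # monotone
})

test_that("the degradation schedule peaks at dawn, troughs at subjective dusk, stays positive", {
  for (ps in c(8, 10, 12, 16)) {
    b <- function(phi) starch_degradation_rate(phi, 0.05, 2, ps, 5, 0.3)
    expect_equal(b(ps), 0.05)
    expect_equal(b(0), 2)
    phi <- seq(0, 23.99, by = 0.01)
    v <- b(phi)
    expect_true(all(v > 0))
    # global minimum sits at the subjective dusk (the trough flattens to
    # machine precision around it, so compare by value, not by index)
    expect_lt(abs(phi[which.min(v)] - ps), 0.5)
    expect_gte(min(v), b(ps))
    expect_lt(max(abs(diff(v))), 0.2)          # continuity
    expect_equal(b(phi), b(phi + 24))          # periodicity
  }
  # both exponents equal to 1 give the plain half-cosine
  expect_equal(starch_degradation_rate(5, 0.1, 1, 10, 1, 1),
               0.1 + 0.9 * (1 + cos(pi * 0.5)) / 2)
})

test_that("the phase velocity reduces to omega for the mutant and in darkness", {
  ck <- clock_params(phi_star = 10, Z_amplitude = 0.6, fS_K = 0.5, fS_n = 2)
  mut <- ck; mut$sugar_response <- FALSE
  expect_equal(phase_derivative(3, -2, TRUE, mut), ck$omega)
  expect_equal(phase_derivative(3, -2, FALSE, ck), ck$omega)
  # falling sucrose before the subjective dusk delays the clock
  expect_lt(phase_derivative(5, -2, TRUE, ck), ck$omega)
  # rising sucrose before the subjective dusk advances it
  expect_gt(phase_derivative(5, 2, TRUE, ck), ck$omega)
})

test_that("mutant phase matches the closed form phi = t mod 24 over ten days", {
  tr <- simulate_plant(16, 10, "mutant", fast_params(), dt = 0.05)
  expect_lt(max(abs(tr$phi - tr$t %% 24)), 1e-6)
  # and wraps into [0, 24)
  expect_true(all(tr$phi >= 0 & tr$phi < 24))
})
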