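test_that("protocol validation rejects malformed schedules", {
  expect_error(light_protocol(25, 5), class = "phloemclock_config_error")
  expect_error(light_protocol(12, 0), class = "phloemclock_config_error")
  expect_error(light_protocol(12, 5, dt = 0.3), class = "phloemclock_config_error")
  expect_error(light_protocol(12.005, 5, dt = 0.01), class = "phloemclock_config_error")
  expect_error(light_protocol(12, 5, plant_type = "triffid"),
               class = "phloemclock_config_error")
})

test_that("a zero-dynamics parameterization is a fixed point of the integrator", {
  p <- fast_params()
  p$source$a <- 0; p$source$h_G <- 0; p$source$eta_G <- 0
  p$source$beta_min <- 1e-12; p$source$beta_max <- 1e-12
  p$sink$eta_Y <- 0; p$sink$h_Y <- 0; p$sink$alpha_max <- 0; p$sink$lambda <- 0
  p$sink$linear_slope <- 0
  y0 <- plant_state(S_G = 2, C = 5, g = 1, S_Y = 1, W_Y = 1e-3, params = p)
  tr <- simulate_plant(12, 1, "mutant", p, dt = 0.05, init = y0)
  last <- as.numeric(tr[nrow(tr), c("S_G", "C", "g0", "g4", "S_Y_sam", "W_sam")])
  expect_equal(last, c(2, 5, 1, 1, 1, 1e-3), tolerance = 1e-9)
})

test_that("trajectories have the documented grid, columns and metadata", {
  tr <- simulate_plant(14, 2, "wild_type", fast_params(), dt = 0.05)
  expect_equal(nrow(tr), 2 * 24 / 0.05 + 1)
  expect_true(all(diff(tr$t) > 0))
  expect_equal(tr$t[2] - tr$t[1], 0.05)
  expect_true(all(c("t", "phi", "S_G", "C", paste0("g", 0:5), "S_Y_sam",
                    "S_Y_ram", "W_sam", "W_ram", "beta", "gr_sam", "gr_ram",
                    paste0("J", 1:5), paste0("w", 0:5), "light") %in% names(tr)))
  # light column matches the photoperiod
  expect_equal(sum(tr$light[-nrow(tr)]) * 0.05, 2 * 14)
  # dawn rows carry the reset phase
  expect_equal(tr$phi[tr$t %in% c(0, 24)], c(0, 0))
  expect_equal(tr$phi[tr$t == 14], 14)   # dusk reset of day 1
})

test_that("the R reference stepper reproduces the compiled core step for step", {
  p <- fast_params()
  y <- plant_state(params = p)
  # one simulated day, stepping both routes side by side (dawn at t = 0,
  # dusk at 12 h; resets handled explicitly for the reference route)
  run <- phloemclock:::.run_segment(y, p, 12, dt = 0.1, record_stride = 1)
  m <- run$states
  yr <- y
  worst <- 0
  for (s in seq_len(240)) {
    t <- (s - 1) * 0.1
    if (t == 0) yr[["phi"]] <- 0
    if (t == 12) yr[["phi"]] <- 12
    worst <- max(worst, max(abs(yr - m[s, phloemclock:::.state_names])))
    yr <- step_rk4(yr, is_light = t < 12, dt = 0.1, params = p)
  }
  expect_lt(worst, 1e-10)
})

test_that("the compiled core agrees with an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  # with no assimilation and the sugar response silenced, the light schedule
  # is inert, so a single 24-h window can be integrated by both routes
  p <- fast_params()
  p$source$a <- 0
  p$clock$sugar_response <- FALSE
  # gentle degradation keeps starch clear of the finite-time extinction point,
  # where the core's negative-pool clamp and plain rk4 would differ
  p$source$beta_min <- 0.01
  p$source$beta_max <- 0.02
  y0 <- plant_state(S_G = 3, C = 20, g = 1, S_Y = 1, W_Y = 5e-4, params = p)
  rhs <- function(t, y, parms) {
    list(unname(plant_derivatives(setNames(y, phloemclock:::.state_names),
                                  is_light = TRUE, params = p)))
  }
  times <- seq(0, 24, by = 0.05)
  ref <- deSolve::rk4(unname(y0), times, rhs, NULL)
  run <- phloemclock:::.run_segment(y0, p, 12, dt = 0.05, record_stride = 1)
  m <- run$states
  for (j in c("S_G", "C", "g0", "g4", "S_Y_sam", "W_sam")) {
    k <- match(j, phloemclock:::.state_names) + 1L  # deSolve column offset
    expect_equal(m[, j], ref[, k], tolerance = 1e-9)
  }
})

test_that("halving the step changes the ten-day endpoint by less than 1e-5 relative", {
  p <- fast_params()
  end_state <- function(dt) {
    tr <- simulate_plant(16, 10, "wild_type", p, dt = dt, record_dt = 24)
    as.numeric(tr[nrow(tr), c("S_G", "C", "g0", "S_Y_sam", "W_sam")])
  }
  a <- end_state(0.02)
  b <- end_state(0.01)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-5)
})

test_that("simulation is deterministic and a null shift equals the constant run", {
  p <- fast_params()
  t1 <- simulate_plant(12, 4, "wild_type", p, dt = 0.05)
  t2 <- simulate_plant(12, 4, "wild_type", p, dt = 0.05)
  expect_identical(t1$S_G, t2$S_G)
  expect_identical(t1$W_sam, t2$W_sam)
  sh <- run_photoperiod_shift(12, 12, 2, 2, "wild_type", p, dt = 0.05)
  expect_equal(as.data.frame(sh), as.data.frame(simulate_plant(12, 4, "wild_type", p, dt = 0.05)),
               ignore_attr = TRUE)
})

test_that("the global carbon audit closes on representative runs", {
  for (tr in list(quick_sim(12, 3), quick_sim(16, 3, "mutant"),
                  run_photoperiod_shift(8, 16, 2, 2, "mutant", fast_params(), dt = 0.05))) {
    a <- carbon_audit(tr)
    expect_lt(abs(a$residual), 1e-5)
  }
})

test_that("after burn-in consecutive days repeat for the intensive variables", {
  p <- fast_params()
  p$clock$phi_star <- 12
  tr <- simulate_plant(12, 8, "wild_type", p, dt = 0.05)
  for (v in c("S_G", "C", "phi")) {
    d7 <- diel_profile(tr, v, 7)$value
    d8 <- diel_profile(tr, v, 8)$value
    expect_lt(max(abs(d7 - d8)) / max(abs(d8), 1), 0.01)
  }
})

test_that("ten-day growth is read at 240 h and is non-negative", {
  tr <- quick_sim(12, 10)
  expect_gte(ten_day_growth(tr), 0)
  expect_equal(ten_day_growth(tr),
               tr$W_sam[which.min(abs(tr$t - 240))] - tr$W_sam[1])
  expect_error(ten_day_growth(quick_sim(12, 3)), "at least 10 days")
})

test_that("growth difference tables cover all pairs and self-differences vanish", {
  p <- fast_params()
  tab <- growth_difference_table(photoperiods = 12, phi_stars = 10, params = p,
                                 days = 10, dt = 0.05)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$pair, c("wild_type - mutant", "homeostatic - mutant",
                              "homeostatic - wild_type"))
  expect_equal(tab$difference[tab$pair == "wild_type - mutant"] +
                 tab$difference[tab$pair == "homeostatic - wild_type"],
               tab$difference[tab$pair == "homeostatic - mutant"],
               tolerance = 1e-12)
  expect_error(growth_difference_table(photoperiods = numeric(0), params = p),
               class = "phloemclock_config_error")
})
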