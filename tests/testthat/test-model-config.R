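test_that("constructors enforce the subsystem invariants", {
  expect_s3_class(clock_params(), "clock_params")
  expect_error(clock_params(omega = 0), class = "phloemclock_config_error")
  expect_error(clock_params(phi_star = 25), class = "phloemclock_config_error")
  expect_error(source_params(kappa = 0), class = "phloemclock_config_error")
  expect_error(sink_params(K_tilde = 0), class = "phloemclock_config_error")
  expect_error(network_geometry(mu = -1), class = "phloemclock_config_error")
  expect_error(network_geometry(V = c(1, 1, 1, 1, 0.5, 0.7)),
               class = "phloemclock_config_error")
})

test_that("validate_parameters reports violations by field and passes defaults", {
  expect_identical(validate_parameters(default_parameters()), character(0))
  p <- default_parameters()
  p$source$gamma <- 1.2
  expect_match(validate_parameters(p), "^gamma", all = FALSE)
  p$source$gamma <- 0.5
  p$source$beta_min <- 0
  expect_match(validate_parameters(p), "^beta_min", all = FALSE)
  p$source$beta_max <- -1
  expect_length(validate_parameters(p), 2)
})

test_that("plant presets are pure and differ only as specified", {
  base <- default_parameters()
  wt <- plant_preset("wild_type", 16, base)
  mu <- plant_preset("mutant", 16, base)
  # wild type with a sugar-responsive base is the identity
  expect_equal(unclass(wt)[c("clock", "source", "sink", "network")],
               unclass(base)[c("clock", "source", "sink", "network")])
  # mutant differs from wild type only in the sugar-response flag
  expect_false(mu$clock$sugar_response)
  mu$clock$sugar_response <- TRUE
  expect_equal(mu, wt, ignore_attr = TRUE)
  # purity: identical inputs give identical outputs
  expect_identical(plant_preset("mutant", 16, base), plant_preset("mutant", 16, base))
  expect_error(plant_preset("gigantea", 12, base), class = "phloemclock_config_error")
  expect_error(plant_preset("wild_type", 30, base), class = "phloemclock_config_error")
})

test_that("homeostatic preset anchors the subjective dusk at the photoperiod", {
  base <- default_parameters()
  # a tiny search grid keeps this fast; correctness of the optimum is tested
  # in test-optimize-beta.R
  grid <- list(min_lo = 0.02, min_hi = 0.6, max_lo = 0.4, max_hi = 4, n_grid = 4)
  b <- optimize_beta(8, base, grid = grid, days = 4, dt = 0.1)
  expect_true(b[["beta_min"]] <= b[["beta_max"]])
  expect_gt(b[["beta_min"]], 0)
})

test_that("configuration round-trips through YAML and rejects unknown keys", {
  p <- default_parameters()
  f <- tempfile(fileext = ".yaml")
  write_model_config(p, f)
  q <- read_model_config(f)
  expect_equal(q$clock, p$clock)
  expect_equal(q$source, p$source)
  expect_equal(q$sink, p$sink)
  expect_equal(q$network$k, p$network$k)
  # unknown keys anywhere are rejected
  cfg <- yaml::read_yaml(f)
  cfg$source$frobnicate <- 1
  yaml::write_yaml(cfg, f)
  expect_error(read_model_config(f), "frobnicate",
               class = "phloemclock_config_error")
  cfg$source$frobnicate <- NULL
  cfg$mystery_section <- list(a = 1)
  yaml::write_yaml(cfg, f)
  expect_error(read_model_config(f), "mystery_section",
               class = "phloemclock_config_error")
})
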