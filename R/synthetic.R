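# Synthetic growth data and pre-integrated trajectory fixtures.

#' Validate a growth dataset
#'
#' @param data data frame with columns `genotype` (`wild_type` /
#'   `starchless`), `time_h` and `fresh_weight_g`.
#' @param canonical if `TRUE`, additionally require the canonical layout of
#'   exactly four observations for each of the two genotypes.
#' @return `data`, invisibly; errors on violation.
#' @export
validate_growth_dataset <- function(data, canonical = FALSE) {
  need <- c("genotype", "time_h", "fresh_weight_g")
  if (!all(need %in% names(data)))
    abort_config(paste0("growth dataset needs columns ", paste(need, collapse = ", ")))
  if (!all(data$genotype %in% c("wild_type", "starchless")))
    abort_config("genotype must be 'wild_type' or 'starchless'")
  for (gt in unique(data$genotype)) {
    tt <- data$time_h[data$genotype == gt]
    if (any(diff(tt) <= 0))
      abort_config(paste0("times must be strictly increasing within genotype ", gt))
  }
  if (any(data$time_h <= 0)) abort_config("times must be positive")
  if (any(data$fresh_weight_g <= 0)) abort_config("weights must be positive")
  if (canonical) {
    tab <- table(data$genotype)
    if (!identical(sort(names(tab)), c("starchless", "wild_type")) ||
        !all(tab == 4))
      abort_config("canonical layout requires four observations per genotype")
  }
  invisible(data)
}

# mean-one multiplicative log-normal noise factors
lognormal_factor <- function(n, sigma) exp(rnorm(n, -sigma^2 / 2, sigma))

#' Generate a synthetic fresh-weight growth dataset
#'
#' Emulates the whole-plant fresh-weight calibration data the growth-kinetics
#' fit assumes: both genotypes (wild type, and the starchless mutant with
#' `gamma = 0`) are simulated in a 12-h photoperiod with subjective dusk 12 h
#' and initial per-sink biomass 0.0005 gFW; whole-plant weight (twice the
#' per-sink biomass) is recorded at the four observation times under
#' multiplicative log-normal noise with mean-one correction, so the expected
#' weight equals the noiseless curve.  Fully reproducible from `seed`; the
#' global random-number state is left untouched.
#'
#' @param params true parameter set the data are generated from.
#' @param observation_times four positive increasing times (h); default days
#'   5, 10, 15, 20.
#' @param noise_sigma log-normal sigma (>= 0; 0 gives noiseless data).
#' @param seed integer seed.
#' @param dt RK4 step for the generating simulations.
#' @return a validated growth dataset (data frame), with the noiseless curve
#'   attached as attribute `truth`.
#' @export
generate_growth_dataset <- function(params = default_parameters(),
                                    observation_times = c(120, 240, 360, 480),
                                    noise_sigma = 0, seed = 1, dt = 0.05) {
  if (length(observation_times) != 4 || any(observation_times <= 0) ||
      any(diff(observation_times) <= 0))
    abort_config("observation_times: need four positive increasing times")
  if (noise_sigma < 0) abort_config("noise_sigma: must be >= 0")
  genos <- c("wild_type", "starchless")
  curve <- lapply(genos, function(gt)
    .genotype_weights(gt, observation_times, params, dt))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  noise <- if (noise_sigma > 0) lognormal_factor(8, noise_sigma) else rep(1, 8)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  out <- data.frame(
    genotype = rep(genos, each = 4),
    time_h = rep(observation_times, 2),
    fresh_weight_g = unlist(curve) * noise)
  attr(out, "truth") <- data.frame(genotype = out$genotype, time_h = out$time_h,
                                   fresh_weight_g = unlist(curve))
  validate_growth_dataset(out, canonical = TRUE)
  out
}

#' Pre-integrated trajectory fixtures
#'
#' Small named scenarios (registered in the `scenarios` section of the
#' configuration file) integrated on demand, for fast downstream tests of
#' reporting and diagnostics.  Regeneration is bit-identical: the simulator
#' is deterministic.
#'
#' @param scenario a registered scenario name, e.g. `"wt_16L8D"`,
#'   `"mutant_8L16D"`, `"shift_8to16"`.
#' @param params parameter set carrying the scenario registry.
#' @return a `plant_trajectory`.
#' @export
generate_trajectory_fixture <- function(scenario, params = default_parameters()) {
  reg <- attr(params, "scenarios")
  if (is.null(reg[[scenario]]))
    abort_config(paste0("unknown scenario '", scenario, "'; registered: ",
                        paste(names(reg), collapse = ", ")))
  sc <- reg[[scenario]]
  if (!is.null(sc$tau_before)) {
    run_photoperiod_shift(sc$tau_before, sc$tau_after, sc$days_before,
                          sc$days_after, sc$plant_type, params, dt = sc$dt)
  } else {
    simulate_plant(sc$photoperiod, sc$days, sc$plant_type, params, dt = sc$dt)
  }
}
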