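#' Light protocol
#'
#' A per-day photoperiod schedule plus integration settings.  Dawn of day 1 is
#' `t = 0`; dusk of day `d` falls at `24 (d - 1) + tau_L[d]`.
#'
#' @param photoperiods photoperiod per day (h), each in (0, 24]; recycled to
#'   `days` if a single value is given.
#' @param days number of simulated days (>= 1).
#' @param plant_type `"wild_type"`, `"mutant"` or `"homeostatic"`.
#' @param dt RK4 step (h); must divide 24 evenly and be <= 0.1, and every
#'   photoperiod must be a multiple of it (events sit on step boundaries).
#' @return a list of class `light_protocol`.
#' @export
light_protocol <- function(photoperiods, days = length(photoperiods),
                           plant_type = "wild_type", dt = 0.01) {
  if (days < 1) abort_config("duration_days: must be >= 1")
  photoperiods <- rep_len(as.numeric(photoperiods), days)
  if (any(photoperiods <= 0 | photoperiods > 24))
    abort_config("photoperiods: every tau_L must lie in (0, 24]")
  spd <- round(24 / dt)
  if (dt <= 0 || dt > 0.1 + 1e-12 || abs(spd * dt - 24) > 1e-9)
    abort_config("rk4_step: must divide 24 h evenly and be <= 0.1")
  if (any(abs(round(photoperiods / dt) * dt - photoperiods) > 1e-9))
    abort_config("photoperiods: every tau_L must be a multiple of rk4_step")
  if (!plant_type %in% c("wild_type", "mutant", "homeostatic"))
    abort_config(paste0("plant_type: unknown plant type '", plant_type, "'"))
  structure(list(photoperiods = photoperiods, days = days,
                 plant_type = plant_type, dt = dt),
            class = "light_protocol")
}

.flat_params <- function(p, freeze_sink = FALSE) {
  list(omega = p$clock$omega, phi_star = p$clock$phi_star,
       Z_amplitude = p$clock$Z_amplitude, fS_K = p$clock$fS_K,
       fS_n = p$clock$fS_n, sugar_response = p$clock$sugar_response,
       a = p$source$a, gamma = p$source$gamma, h_G = p$source$h_G,
       eta_G = p$source$eta_G, kappa = p$source$kappa,
       beta_min = p$source$beta_min, beta_max = p$source$beta_max,
       beta_shape_day = p$source$beta_shape_day,
       beta_shape_night = p$source$beta_shape_night,
       eta_Y = p$sink$eta_Y, h_Y = p$sink$h_Y, alpha_max = p$sink$alpha_max,
       n_tilde = p$sink$n_tilde, K_tilde = p$sink$K_tilde,
       lambda = p$sink$lambda, linear_slope = p$sink$linear_slope,
       linear_growth = identical(p$sink$growth_form, "linear"),
       V = p$network$V, keps = p$network$k * p$network$vant_hoff_eps,
       freeze_sink = isTRUE(freeze_sink))
}

.aux_names <- c("resp_source", "resp_sink", "consumed_growth", "loaded", "unloaded")

# integrate one constant-parameter segment with the compiled core
.run_segment <- function(y, params, photoperiods, dt, record_stride,
                         freeze_sink = FALSE, aux = numeric(5)) {
  stop_on_violation(validate_parameters(params))
  res <- .sim_core(c(y, aux), .flat_params(params, freeze_sink),
                   photoperiods, dt, as.integer(record_stride))
  m <- res$states
  colnames(m) <- c("t", "light", .state_names, .aux_names)
  list(states = m, clamps = res$clamps)
}

# derived columns for one constant-parameter block of rows
.derived_block <- function(m, params) {
  beta <- starch_degradation_rate(m[, "phi"], params$source$beta_min,
                                  params$source$beta_max, params$clock$phi_star,
                                  params$source$beta_shape_day,
                                  params$source$beta_shape_night)
  gr_sam <- params$sink$lambda * growth_consumption(m[, "S_Y_sam"], params$sink)
  gr_ram <- params$sink$lambda * growth_consumption(m[, "S_Y_ram"], params$sink)
  g <- m[, paste0("g", 0:5), drop = FALSE]
  keps <- params$network$k * params$network$vant_hoff_eps
  par <- params$network$parent[2:6] + 1L
  J <- sapply(1:5, function(e) keps[e] * (g[, par[e]] - g[, e + 1L]))
  if (is.null(dim(J))) J <- matrix(J, nrow = 1)
  colnames(J) <- paste0("J", 1:5)
  w <- matrix(0, nrow(J), 6, dimnames = list(NULL, paste0("w", 0:5)))
  for (e in 1:5) {            # columnwise version of water_exchange_diagnostics()
    w[, par[e]] <- w[, par[e]] + J[, e]
    w[, e + 1L] <- w[, e + 1L] - J[, e]
  }
  cbind(beta = beta, gr_sam = gr_sam, gr_ram = gr_ram, J, w)
}

.traj_columns <- c("t", "phi", "S_G", "C", paste0("g", 0:5),
                   "S_Y_sam", "S_Y_ram", "W_sam", "W_ram",
                   "beta", "gr_sam", "gr_ram", paste0("J", 1:5), paste0("w", 0:5),
                   "light", .aux_names)

#' Simulate a plant over a light protocol
#'
#' Integrates the full coupled system with fixed-step classical RK4.  Dawn of
#' day 1 is at `t = 0`; the phase is reset to 0 at every dawn and to the
#' day's photoperiod at every dusk, both exactly on step boundaries before the
#' step.  For the homeostatic plant the subjective dusk and the degradation
#' schedule are re-derived whenever the photoperiod changes (the run is split
#' into constant-photoperiod segments).
#'
#' @param photoperiod single photoperiod (h) applied every day, or use
#'   `protocol` for a per-day schedule.
#' @param days number of days.
#' @param plant_type `"wild_type"`, `"mutant"` or `"homeostatic"`.
#' @param params base parameter set (default [default_parameters()]); the
#'   plant-type preset is derived from it via [plant_preset()].
#' @param protocol a [light_protocol()]; overrides the previous four arguments.
#' @param dt RK4 step (h).
#' @param init initial state from [plant_state()]; defaults to the configured
#'   cold start (dawn, phase 0, no starch, small pools).
#' @param record_dt output sampling interval (h), a multiple of `dt` that
#'   divides 24; defaults to `dt`.
#' @return a `plant_trajectory`: a data frame with columns `t`, `phi`, `S_G`,
#'   `C`, `g0..g5`, `S_Y_sam`, `S_Y_ram`, `W_sam`, `W_ram`, `beta`, `gr_sam`,
#'   `gr_ram`, `J1..J5`, `w0..w5`, `light` and five cumulative bookkeeping
#'   integrals; protocol metadata and the parameter set are attached as
#'   attributes.
#' @export
simulate_plant <- function(photoperiod = 12, days = 10,
                           plant_type = "wild_type",
                           params = default_parameters(), protocol = NULL,
                           dt = 0.01, init = NULL, record_dt = dt) {
  if (is.null(protocol))
    protocol <- light_protocol(photoperiod, days, plant_type, dt)
  dt <- protocol$dt
  stride <- round(record_dt / dt)
  if (stride < 1 || abs(stride * dt - record_dt) > 1e-9)
    abort_config("record_dt: must be a multiple of rk4_step")
  y <- init %||% plant_state(params = params)
  pp <- protocol$photoperiods
  seg_id <- cumsum(c(TRUE, diff(pp) != 0))
  blocks <- list()
  clamps <- 0
  t_off <- 0
  aux <- numeric(5)
  for (s in unique(seg_id)) {
    tau <- pp[seg_id == s][1]
    pseg <- plant_preset(protocol$plant_type, tau, params)
    run <- .run_segment(y, pseg, pp[seg_id == s], dt, stride, aux = aux)
    m <- run$states
    clamps <- clamps + run$clamps
    y <- stats::setNames(m[nrow(m), .state_names], .state_names)
    aux <- unname(m[nrow(m), .aux_names])
    m[, "t"] <- m[, "t"] + t_off
    t_off <- m[nrow(m), "t"]
    blocks[[length(blocks) + 1]] <- cbind(m, .derived_block(m, pseg))
  }
  # at a parameter switch keep the new segment's boundary row (post-reset phase)
  if (length(blocks) > 1)
    for (i in seq_len(length(blocks) - 1))
      blocks[[i]] <- blocks[[i]][-nrow(blocks[[i]]), , drop = FALSE]
  m <- do.call(rbind, blocks)
  traj <- as.data.frame(m)[, .traj_columns]
  structure(traj, class = c("plant_trajectory", "data.frame"),
            params = params, plant_type = protocol$plant_type,
            photoperiods = pp, dt = dt, record_dt = stride * dt,
            clamps = clamps)
}

#' @export
print.plant_trajectory <- function(x, ...) {
  cat(sprintf("<plant_trajectory> %s, %d day(s), photoperiod(s) %s h, dt = %g h, %d rows\n",
              attr(x, "plant_type"), length(attr(x, "photoperiods")),
              paste(unique(attr(x, "photoperiods")), collapse = "/"),
              attr(x, "dt"), nrow(x)))
  invisible(x)
}

#' Photoperiod-shift (transfer) experiment
#'
#' Grows the plant `days_before` days at `tau_before`, then switches to
#' `tau_after` at dawn of the following day for `days_after` more days, as a
#' single continuous trajectory.  The homeostatic plant re-derives its
#' subjective dusk and degradation schedule at the switch.
#'
#' @param tau_before,tau_after photoperiods (h) before and after the switch.
#' @param days_before,days_after days in each regime (defaults 5 and 5).
#' @param plant_type,params,dt,init,record_dt as in [simulate_plant()].
#' @return a `plant_trajectory` spanning `days_before + days_after` days, with
#'   the switch day recorded in attribute `shift_day`.
#' @export
run_photoperiod_shift <- function(tau_before = 8, tau_after = 16,
                                  days_before = 5, days_after = 5,
                                  plant_type = "wild_type",
                                  params = default_parameters(), dt = 0.01,
                                  init = NULL, record_dt = dt) {
  proto <- light_protocol(c(rep(tau_before, days_before), rep(tau_after, days_after)),
                          days_before + days_after, plant_type, dt)
  traj <- simulate_plant(protocol = proto, params = params, init = init,
                         record_dt = record_dt)
  attr(traj, "shift_day") <- days_before + 1L
  traj
}
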