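# R reference implementation of the full coupled right-hand side and one RK4
# step.  It composes the exported subsystem operations and mirrors the
# compiled core exactly; the test suite holds the two routes equal.

.state_names <- c("phi", "S_G", "C", paste0("g", 0:5),
                  "S_Y_sam", "S_Y_ram", "W_sam", "W_ram")

#' Assemble an initial plant state
#'
#' Runs start at dawn with phase 0, no starch, a small positive source sucrose
#' pool, uniform small tube concentrations and sink pools, and the seedling
#' biomass used throughout (0.0005 gFW per sink unless overridden).
#'
#' @param S_G,C,g,S_Y,W_Y pool values; `g` is recycled over the six
#'   components, `S_Y` and `W_Y` over the two sinks.
#' @param phi initial phase (h).
#' @param params parameter set whose `initial_state` attribute (from the
#'   configuration file) supplies defaults for arguments left `NULL`.
#' @return named numeric state vector of length 13.
#' @export
plant_state <- function(S_G = NULL, C = NULL, g = NULL, S_Y = NULL, W_Y = NULL,
                        phi = 0, params = default_parameters()) {
  ini <- attr(params, "initial_state") %||%
    list(S_G = 1, C = 0, g = 0.5, S_Y = 0.5, W_Y = 5e-4)
  y <- c(phi,
         S_G %||% ini$S_G,
         C %||% ini$C,
         rep_len(g %||% ini$g, 6),
         rep_len(S_Y %||% ini$S_Y, 2),
         rep_len(W_Y %||% ini$W_Y, 2))
  stats::setNames(y, .state_names)
}

#' Full coupled derivative (R reference route)
#'
#' Composes [source_derivatives()], [phase_derivative()], [network_fluxes()],
#' [advection_rates()] and [sink_derivatives()] into the 13-component
#' right-hand side.  The sugar input to the clock uses the source sucrose
#' balance itself as `dS_G/dt` (exact, step-size independent), never a finite
#' difference of the trajectory.
#'
#' @param state named state vector as from [plant_state()].
#' @param is_light logical light indicator.
#' @param params a `plant_params` object.
#' @return named derivative vector of length 13.
#' @export
plant_derivatives <- function(state, is_light, params) {
  # RK4 sub-stages may probe marginally negative starch; the degradation term
  # is defined as 0 there, which floor-at-zero reproduces exactly
  src <- source_derivatives(state[["S_G"]], max(state[["C"]], 0), state[["phi"]],
                            is_light, params$source, params$clock$phi_star)
  dphi <- phase_derivative(state[["phi"]], src$dS_G, is_light, params$clock)
  g <- unname(state[4:9])
  J <- network_fluxes(g, params$network)
  dg <- advection_rates(g, J, loading_flux(state[["S_G"]], params$source$eta_G),
                        params$sink$eta_Y, params$network)
  sam <- sink_derivatives(state[["S_Y_sam"]], state[["W_sam"]], g[5], params$sink)
  ram <- sink_derivatives(state[["S_Y_ram"]], state[["W_ram"]], g[6], params$sink)
  stats::setNames(c(dphi, src$dS_G, src$dC, dg,
                    sam$dS_Y, ram$dS_Y, sam$dW_Y, ram$dW_Y), .state_names)
}

#' One classical RK4 step of the full system (R reference route)
#'
#' The light indicator is constant over the step: transitions sit exactly on
#' step boundaries, where the dawn/dusk resets fire before the step.  After
#' the update the phase is wrapped to \[0, 24) and tiny negative pools are
#' clamped to zero.
#'
#' @param state named state vector.
#' @param is_light logical light indicator for the whole step.
#' @param dt step size (h), > 0.
#' @param params a `plant_params` object.
#' @return the updated state vector.
#' @export
step_rk4 <- function(state, is_light, dt, params) {
  k1 <- plant_derivatives(state, is_light, params)
  k2 <- plant_derivatives(state + 0.5 * dt * k1, is_light, params)
  k3 <- plant_derivatives(state + 0.5 * dt * k2, is_light, params)
  k4 <- plant_derivatives(state + dt * k3, is_light, params)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out[["phi"]] <- out[["phi"]] %% 24
  pools <- 2:11
  out[pools] <- pmax(out[pools], 0)
  out
}
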