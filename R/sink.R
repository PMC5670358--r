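#' Growth-related sucrose consumption
#'
#' Saturating Hill kinetics `alpha_max * S_Y^n / (K^n + S_Y^n)` by default
#' (increasing, bounded by `alpha_max`), or the linear alternative
#' `linear_slope * S_Y` used for robustness runs; the default linear slope
#' `alpha_max / K_tilde` makes the two forms agree at low sucrose.
#'
#' @param S_Y sink sucrose (umolC6 / gFW), >= 0, vectorized.
#' @param sink a [sink_params()] object.
#' @return consumption rate (umolC6 / gFW / h).
#' @export
growth_consumption <- function(S_Y, sink) {
  S_Y <- pmax(S_Y, 0)
  if (sink$growth_form == "linear") return(sink$linear_slope * S_Y)
  sn <- S_Y^sink$n_tilde
  sink$alpha_max * sn / (sink$K_tilde^sink$n_tilde + sn)
}

#' Sink sucrose and biomass derivatives
#'
#' Sink sucrose gains unloading from the adjacent phloem tube (`eta_Y * g`,
#' with `eta_Y` carrying the per-volume to per-gram unit conversion) and loses
#' respiration and growth consumption; biomass grows multiplicatively at the
#' relative rate `lambda * alpha(S_Y)`.
#'
#' @param S_Y sink sucrose (umolC6 / gFW).
#' @param W_Y sink fresh biomass (gFW).
#' @param g_adj sucrose concentration of the adjacent phloem tube.
#' @param sink a [sink_params()] object.
#' @return list with `dS_Y`, `dW_Y` and the growth rate `growth_rate`
#'   (`lambda * alpha(S_Y)`, 1/h).
#' @export
sink_derivatives <- function(S_Y, W_Y, g_adj, sink) {
  alpha <- growth_consumption(S_Y, sink)
  list(dS_Y = sink$eta_Y * g_adj - sink$h_Y * S_Y - alpha,
       dW_Y = sink$lambda * alpha * W_Y,
       growth_rate = sink$lambda * alpha)
}
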