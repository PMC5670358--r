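#' Source-leaf carbon derivatives
#'
#' The two source balances: sucrose gains the non-starch share of assimilation
#' plus starch degradation and loses respiration and phloem loading; starch
#' gains the partitioned share of assimilation and loses degradation.  The
#' identical degradation term `beta(phi) * C^kappa` appears in both (it is
#' taken as 0 at `C = 0` for any `kappa`, so degradation stops when the
#' reserve is exhausted).
#'
#' @param S_G source sucrose (umolC6 / gFW), >= 0.
#' @param C starch (umolC6 / gFW), >= 0.
#' @param phi circadian phase (h).
#' @param is_light logical light indicator.
#' @param source a [source_params()] object.
#' @param phi_star subjective dusk used by the degradation schedule; defaults
#'   must be supplied by the caller (the clock owns it).
#' @return list with elements `dS_G` and `dC` (umolC6 / gFW / h).
#' @export
source_derivatives <- function(S_G, C, phi, is_light, source, phi_star) {
  if (any(C < 0)) stop("C must be >= 0 (C^kappa is undefined for negative starch)")
  beta <- starch_degradation_rate(phi, source$beta_min, source$beta_max, phi_star,
                                  source$beta_shape_day, source$beta_shape_night)
  # the power law is linearized below .starch_eps so the derivative stays
  # Lipschitz as the reserve empties (see the methods vignette)
  degr <- ifelse(C >= .starch_eps, beta * C^source$kappa,
                 beta * .starch_eps^source$kappa * (C / .starch_eps))
  degr[C <= 0] <- 0
  aL <- source$a * as.numeric(is_light)
  list(dS_G = aL * (1 - source$gamma) + degr - (source$h_G + source$eta_G) * S_G,
       dC = aL * source$gamma - degr)
}

# numerical regularization threshold for the starch power law (umolC6/gFW)
.starch_eps <- 0.2

#' Phloem loading flux
#'
#' Amount of sucrose per unit time loaded from the source leaf into the
#' adjacent phloem tube, `eta_G * S_G`.
#'
#' @param S_G source sucrose (umolC6 / gFW), >= 0.
#' @param eta_G loading rate (1/h).
#' @return loading flux (umolC6 / h).
#' @export
loading_flux <- function(S_G, eta_G) eta_G * S_G
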