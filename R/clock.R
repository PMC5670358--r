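#' Light resets of the circadian phase
#'
#' Light entrainment acts as instantaneous resets: the phase is set to 0 at
#' dawn and to the photoperiod `tau_L` at dusk.
#'
#' @param phi current phase (h); ignored, present for interface symmetry.
#' @param event `"dawn"` or `"dusk"`.
#' @param tau_L photoperiod (h).
#' @return the reset phase (h).
#' @export
light_reset <- function(phi, event = c("dawn", "dusk"), tau_L) {
  event <- match.arg(event)
  if (event == "dawn") 0 else tau_L
}

#' Sucrose phase-response curve
#'
#' Sine-lobe PRC: strictly positive (phase advance) on `(0, phi_star)`,
#' strictly negative (phase delay) on `(phi_star, 24)`, zero at 0 and at the
#' subjective dusk `phi_star`; continuous and 24-periodic.
#'
#' @param phi phase (h), vectorized; wrapped modulo 24.
#' @param phi_star subjective dusk (h), in (0, 24).
#' @param amplitude lobe amplitude (h per unit signal).
#' @return PRC value(s).
#' @export
sucrose_prc <- function(phi, phi_star, amplitude = 1) {
  phi <- phi %% 24
  ifelse(phi <= phi_star,
         amplitude * sin(pi * phi / phi_star),
         -amplitude * sin(pi * (phi - phi_star) / (24 - phi_star)))
}

#' Sugar input to the clock
#'
#' Signed Hill transform of the rate of change of source sucrose,
#' `sign(x) |x|^n / (K^n + |x|^n)`, gated to zero in the dark (the sugar
#' phase shift takes place only in the light period).
#'
#' @param dSG_dt rate of change of source sucrose (umolC6 / gFW / h), vectorized.
#' @param K half-saturation (> 0).
#' @param n Hill exponent (>= 1).
#' @param is_light logical light indicator.
#' @return dimensionless signal in \[-1, 1\].
#' @export
sugar_input <- function(dSG_dt, K, n, is_light = TRUE) {
  ax <- abs(dSG_dt)^n
  ifelse(rep_len(is_light, length(dSG_dt)),
         sign(dSG_dt) * ax / (K^n + ax), 0)
}

#' Clock-gated starch degradation rate
#'
#' Shaped piecewise half-cosine schedule: peak `beta_max` at dawn
#' (`phi = 0/24`), trough `beta_min` at the subjective dusk `phi_star`.  Each
#' branch is a half-cosine ramp `u` in \[0, 1\] (1 at dawn, 0 at the trough)
#' raised to a branch-specific exponent: a large day exponent holds the rate
#' near the trough through the subjective day, and a night exponent below 1
#' lifts it quickly after dusk, concentrating degradation where the starch
#' reserve must carry the supply.  Both exponents equal to 1 recover the plain
#' half-cosine.  Continuous, 24-periodic and strictly positive.
#'
#' @param phi phase (h), vectorized; wrapped modulo 24.
#' @param beta_min,beta_max trough and peak (1/h on the `C^kappa` scale).
#' @param phi_star subjective dusk (h).
#' @param shape_day,shape_night branch shape exponents (> 0).
#' @return degradation rate(s).
#' @export
starch_degradation_rate <- function(phi, beta_min, beta_max, phi_star,
                                    shape_day = 1, shape_night = 1) {
  phi <- phi %% 24
  day <- phi <= phi_star
  u <- ifelse(day,
              0.5 * (1 + cos(pi * phi / phi_star)),
              0.5 * (1 - cos(pi * (phi - phi_star) / (24 - phi_star))))
  beta_min + (beta_max - beta_min) * u^ifelse(day, shape_day, shape_night)
}

#' Phase velocity of the circadian oscillator
#'
#' `omega + Z_S(phi) * f_S(dS_G/dt)`, with the sugar term gated by light and
#' silenced entirely when the clock is sugar-insensitive.  Light entrainment
#' is realized as the discrete dawn/dusk resets ([light_reset()]), not as a
#' continuous term.
#'
#' @param phi phase (h).
#' @param dSG_dt rate of change of source sucrose, evaluated from the source
#'   balance itself (not by finite differencing).
#' @param is_light logical light indicator.
#' @param clock a [clock_params()] object.
#' @return phase velocity (h/h).
#' @export
phase_derivative <- function(phi, dSG_dt, is_light, clock) {
  if (!clock$sugar_response) return(rep_len(clock$omega, length(phi)))
  fs <- sugar_input(dSG_dt, clock$fS_K, clock$fS_n, is_light)
  clock$omega + sucrose_prc(phi, clock$phi_star, clock$Z_amplitude) * fs
}
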