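# Per-photoperiod optimization of the starch degradation schedule.

# diel CV of sink sucrose in near-steady state for one (beta_min, beta_max)
# candidate of the perfectly anticipating plant (phi_star = tau_L)
.beta_candidate_cv <- function(bmin, bmax, tau_L, params, days, dt) {
  p <- params
  p$clock$phi_star <- tau_L
  p$clock$sugar_response <- TRUE
  p$source$beta_min <- bmin
  p$source$beta_max <- bmax
  proto <- light_protocol(tau_L, days, "wild_type", dt)
  traj <- tryCatch(simulate_plant(protocol = proto, params = p, record_dt = 0.2),
                   error = function(e) NULL)
  if (is.null(traj)) return(NA_real_)  # diverged: excluded
  # non-convergent candidates are excluded too: a diel cycle that is still
  # drifting (e.g. a slowly ramping starch hoard) can masquerade as a smooth,
  # low-CV supply without ever being sustainable
  for (v in c("C", "S_Y_sam")) {
    a <- diel_profile(traj, v, day = -2)$value
    b <- diel_profile(traj, v, day = -1)$value
    if (max(abs(a - b)) > 0.02 * max(abs(b), 1e-8)) return(NA_real_)
  }
  diel_cv(traj, "S_Y_sam", day = -1)
}

#' Optimal starch degradation schedule for a photoperiod
#'
#' Finds the `(beta_min, beta_max)` pair of the half-cosine degradation
#' schedule that minimizes the steady-state diel coefficient of variation of
#' sink sucrose for a plant whose subjective dusk equals the photoperiod
#' (`phi_star = tau_L`) - the schedule the idealized homeostatic plant is
#' assumed to possess in every photoperiod.  The search is a log-spaced grid
#' (default 20 x 20, from the `calibration` section of the configuration)
#' followed by multiplicative coordinate descent; it is fully deterministic
#' given the grid specification, and results are cached per session.
#'
#' @param tau_L photoperiod (h), in (0, 24].
#' @param params base parameter set.
#' @param grid list with `min_lo`, `min_hi`, `max_lo`, `max_hi`, `n_grid`
#'   overriding the configured search grid.
#' @param days,dt burn-in length and step used for each candidate evaluation
#'   (defaults from the configuration: 8 days at 0.05 h).
#' @return named numeric vector `c(beta_min, beta_max)` with attributes `cv`
#'   (the achieved CV) and `grid_cv` (matrix of CVs over the search grid).
#' @export
optimize_beta <- function(tau_L, params = default_parameters(), grid = NULL,
                          days = NULL, dt = NULL) {
  if (!(tau_L > 0 && tau_L <= 24)) abort_config("tau_L: must lie in (0, 24]")
  cal <- attr(params, "calibration") %||%
    list(beta_grid = list(min_lo = 0.002, min_hi = 0.5, max_lo = 0.02,
                          max_hi = 5, n_grid = 20), days = 8, dt = 0.05)
  grid <- grid %||% cal$beta_grid
  days <- days %||% cal$days %||% 8
  dt <- dt %||% cal$dt %||% 0.05
  key <- paste(format(c(tau_L, days, dt, unlist(grid),
                        unlist(params$clock[c("omega", "Z_amplitude", "fS_K", "fS_n")]),
                        unlist(params$source[c("a", "gamma", "h_G", "eta_G", "kappa",
                                               "beta_shape_day", "beta_shape_night")]),
                        unlist(params$sink[1:6]), params$network$V, params$network$k,
                        params$network$vant_hoff_eps), digits = 15),
               collapse = "|")
  hit <- .pc_cache$beta[[key]]
  if (!is.null(hit)) return(hit)

  bmins <- exp(seq(log(grid$min_lo), log(grid$min_hi), length.out = grid$n_grid))
  bmaxs <- exp(seq(log(grid$max_lo), log(grid$max_hi), length.out = grid$n_grid))
  cvm <- matrix(NA_real_, grid$n_grid, grid$n_grid, dimnames = list(
    beta_min = format(bmins, digits = 4), beta_max = format(bmaxs, digits = 4)))
  for (i in seq_along(bmins)) for (j in seq_along(bmaxs)) {
    if (bmaxs[j] < bmins[i]) next
    cvm[i, j] <- .beta_candidate_cv(bmins[i], bmaxs[j], tau_L, params, days, dt)
  }
  if (all(is.na(cvm))) stop("optimize_beta: no grid candidate produced a finite simulation")
  best <- which(cvm == min(cvm, na.rm = TRUE), arr.ind = TRUE)[1, ]
  b <- c(bmins[best[1]], bmaxs[best[2]])
  bestcv <- cvm[best[1], best[2]]

  # multiplicative coordinate descent, shrinking from the grid spacing
  fac <- exp(log(grid$min_hi / grid$min_lo) / (grid$n_grid - 1))
  while (fac > 1.004) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in 1:2) for (f in c(fac, 1 / fac)) {
        cand <- b
        cand[k] <- cand[k] * f
        if (cand[2] < cand[1] || cand[1] <= 0) next
        cv <- .beta_candidate_cv(cand[1], cand[2], tau_L, params, days, dt)
        if (!is.na(cv) && cv < bestcv) {
          b <- cand
          bestcv <- cv
          improved <- TRUE
        }
      }
    }
    fac <- sqrt(fac)
  }
  out <- stats::setNames(b, c("beta_min", "beta_max"))
  attr(out, "cv") <- bestcv
  attr(out, "grid_cv") <- cvm
  if (is.null(.pc_cache$beta)) .pc_cache$beta <- list()
  .pc_cache$beta[[key]] <- out
  out
}
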