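#' Extract one day's diel profile of a trajectory column
#'
#' @param traj a `plant_trajectory`.
#' @param var column name.
#' @param day 1-based day index; negative counts from the end (-1 = last day).
#' @return data frame with `tod` (time of day, h, in \[0, 24)) and `value`;
#'   the terminal midnight sample belongs to the following day.
#' @export
diel_profile <- function(traj, var, day = -1) {
  ndays <- length(attr(traj, "photoperiods"))
  if (day < 0) day <- ndays + 1 + day
  if (day < 1 || day > ndays) stop("day out of range")
  lo <- 24 * (day - 1)
  sel <- traj$t >= lo - 1e-9 & traj$t < lo + 24 - 1e-9
  data.frame(tod = traj$t[sel] - lo, value = traj[[var]][sel])
}

#' Diel coefficient of variation
#'
#' Standard deviation over mean of a trajectory column across one day
#' (population sd, uniform sampling).
#'
#' @inheritParams diel_profile
#' @return the CV (dimensionless).
#' @export
diel_cv <- function(traj, var = "S_Y_sam", day = -1) {
  x <- diel_profile(traj, var, day)$value
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Ten-day growth increment
#'
#' Biomass gained by the SAM sink over the first ten simulated days,
#' `W(240 h) - W(0)`.  (SAM and RAM are exactly symmetric, so SAM stands for
#' the sink growth.)
#'
#' @param traj a `plant_trajectory` spanning at least 10 days.
#' @return growth increment (gFW).
#' @export
ten_day_growth <- function(traj) {
  if (max(traj$t) < 240 - 1e-9) stop("trajectory must span at least 10 days")
  w <- stats::approx(traj$t, traj$W_sam, xout = c(0, 240))$y
  w[2] - w[1]
}

#' Ten-day growth across photoperiods and plant types
#'
#' @param photoperiods photoperiods to sweep (h), default 8..16.
#' @param plant_types plant types to include.
#' @param params base parameter set.
#' @param days,dt protocol settings (default the 10-day runs).
#' @return data frame with columns `plant_type`, `photoperiod`, `growth`.
#' @export
photoperiod_sweep <- function(photoperiods = 8:16,
                              plant_types = c("mutant", "wild_type", "homeostatic"),
                              params = default_parameters(), days = 10, dt = 0.02) {
  grid <- expand.grid(plant_type = plant_types, photoperiod = photoperiods,
                      stringsAsFactors = FALSE)
  grid$growth <- mapply(function(ty, tau) {
    ten_day_growth(simulate_plant(tau, days, ty, params, dt = dt))
  }, grid$plant_type, grid$photoperiod)
  grid[order(grid$plant_type, grid$photoperiod), ]
}

#' Pairwise ten-day growth differences across photoperiods and subjective dusks
#'
#' For every combination of photoperiod and subjective dusk, simulates the
#' three plant types and tabulates the signed ten-day growth differences for
#' the pairs (wild type - mutant), (homeostatic - mutant) and
#' (homeostatic - wild type).  The homeostatic plant ignores `phi_star` (its
#' subjective dusk always equals the photoperiod).
#'
#' @param photoperiods photoperiods (h).
#' @param phi_stars subjective dusk values (h) applied to wild type and mutant.
#' @param params base parameter set.
#' @param days,dt protocol settings.
#' @return data frame with columns `photoperiod`, `phi_star`, `pair`,
#'   `difference` (gFW).
#' @export
growth_difference_table <- function(photoperiods = 8:16, phi_stars = 10,
                                    params = default_parameters(), days = 10,
                                    dt = 0.02) {
  if (!length(photoperiods) || !length(phi_stars))
    abort_config("photoperiods and phi_stars must be non-empty")
  pairs <- rbind(c("wild_type", "mutant"), c("homeostatic", "mutant"),
                 c("homeostatic", "wild_type"))
  out <- list()
  for (ps in phi_stars) {
    p <- params
    p$clock$phi_star <- ps
    for (tau in photoperiods) {
      g <- vapply(c("mutant", "wild_type", "homeostatic"), function(ty)
        ten_day_growth(simulate_plant(tau, days, ty, p, dt = dt)), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        photoperiod = tau, phi_star = ps,
        pair = paste(pairs[, 1], pairs[, 2], sep = " - "),
        difference = g[pairs[, 1]] - g[pairs[, 2]], row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Relative RMS distance between two diel profiles
#' @noRd
.profile_rms <- function(x, ref) {
  denom <- sqrt(mean(ref^2))
  if (denom == 0) return(ifelse(sqrt(mean((x - ref)^2)) == 0, 0, Inf))
  sqrt(mean((x - ref)^2)) / denom
}

#' Days to recover after a photoperiod shift
#'
#' Finds the first post-shift day whose diel profiles of sink sucrose and
#' growth rate are both within `tol` relative RMS of the eventual
#' steady-state diel profile (the final simulated day).
#'
#' @param traj a trajectory from [run_photoperiod_shift()].
#' @param vars columns whose diel profiles must have re-locked.
#' @param tol relative RMS tolerance (default 0.05).
#' @return number of days after the transfer (1 = the first post-shift day);
#'   `Inf` if even the penultimate day is outside tolerance.
#' @export
recovery_days <- function(traj, vars = c("S_Y_sam", "gr_sam"), tol = 0.05) {
  shift_day <- attr(traj, "shift_day")
  if (is.null(shift_day)) stop("trajectory has no shift_day attribute")
  ndays <- length(attr(traj, "photoperiods"))
  ref <- lapply(vars, function(v) diel_profile(traj, v, ndays)$value)
  for (d in shift_day:ndays) {
    ok <- all(vapply(seq_along(vars), function(i)
      .profile_rms(diel_profile(traj, vars[i], d)$value, ref[[i]]) <= tol,
      logical(1)))
    if (ok) return(d - shift_day + 1)
  }
  Inf
}

#' Global carbon audit of a trajectory
#'
#' Checks that every unit of assimilated carbon is accounted for: change in
#' source pools (sucrose + starch), phloem pools (`sum V_i g_i`), sink pools,
#' respiration in source and sinks, and growth consumption.  Also reports the
#' transport-only balance of the phloem (change in tube contents versus
#' loading minus unloading).  Both residuals are relative to total
#' assimilation and rely on bookkeeping integrals accumulated inside the RK4
#' steps, so they are exact up to the negative-pool clamp.
#'
#' @param traj a `plant_trajectory`.
#' @return list with `assimilated` (umolC6), `residual` and
#'   `transport_residual` (relative), and the audit components.
#' @export
carbon_audit <- function(traj) {
  params <- attr(traj, "params")
  first <- traj[1, ]
  last <- traj[nrow(traj), ]
  assim <- params$source$a * sum(attr(traj, "photoperiods"))
  V <- params$network$V
  gcols <- paste0("g", 0:5)
  d_source <- (last$S_G + last$C) - (first$S_G + first$C)
  d_phloem <- sum(V * as.numeric(last[gcols])) - sum(V * as.numeric(first[gcols]))
  d_sink <- (last$S_Y_sam + last$S_Y_ram) - (first$S_Y_sam + first$S_Y_ram)
  resp <- (last$resp_source - first$resp_source) + (last$resp_sink - first$resp_sink)
  invested <- last$consumed_growth - first$consumed_growth
  residual <- assim - (d_source + d_phloem + d_sink + resp + invested)
  loaded <- last$loaded - first$loaded
  unloaded <- last$unloaded - first$unloaded
  list(assimilated = assim,
       residual = if (assim > 0) residual / assim else residual,
       transport_residual = if (assim > 0) (d_phloem - (loaded - unloaded)) / assim
                            else d_phloem - (loaded - unloaded),
       delta_source = d_source, delta_phloem = d_phloem, delta_sink = d_sink,
       respired = resp, invested = invested,
       loaded = loaded, unloaded = unloaded,
       clamped_steps = attr(traj, "clamps"))
}

#' Starch exhaustion time after the last dawn
#'
#' On the chosen day, finds the diel starch peak and the first time after the
#' peak at which starch falls below `frac` of it; returns the time elapsed
#' since that day's dawn (h).  An entrained plant whose clock anticipates dusk
#' correctly exhausts its reserve at the following dawn, i.e. about 24 h.
#'
#' @param traj a `plant_trajectory`.
#' @param day day whose cycle is measured (default the last full day).
#' @param frac depletion threshold as a fraction of the diel peak.
#' @return hours from dawn to depletion, or `NA` if starch never crosses the
#'   threshold (searches into the following day if the trajectory continues).
#' @export
starch_exhaustion_time <- function(traj, day = -1, frac = 0.01) {
  ndays <- length(attr(traj, "photoperiods"))
  if (day < 0) day <- ndays + 1 + day
  dawn <- 24 * (day - 1)
  sel <- traj$t >= dawn - 1e-9
  tt <- traj$t[sel]
  cc <- traj$C[sel]
  in_day <- tt < dawn + 24 - 1e-9
  pk <- max(cc[in_day])
  t_pk <- tt[in_day][which.max(cc[in_day])]
  after <- tt >= t_pk & cc <= frac * pk
  if (!any(after)) return(NA_real_)
  tt[which(after)[1]] - dawn
}

#' Time of day of the steady-state growth-rate peak and trough
#'
#' Read from the chosen day's diel profile as argmax/argmin; ties are broken
#' by the earliest time.
#'
#' @param traj a `plant_trajectory`.
#' @param var growth-rate column (default the SAM sink).
#' @param day day to read (default the last).
#' @return list with `peak` and `trough` times of day (h in \[0, 24)).
#' @export
growth_peak_phase <- function(traj, var = "gr_sam", day = -1) {
  pr <- diel_profile(traj, var, day)
  list(peak = pr$tod[which.max(pr$value)], trough = pr$tod[which.min(pr$value)])
}

#' Run summary
#'
#' The headline diagnostics of a simulation: growth, diel variability, peak
#' timing, conservation residuals.
#'
#' @param traj a `plant_trajectory`.
#' @return a list suitable for JSON serialization.
#' @export
run_summary <- function(traj) {
  audit <- carbon_audit(traj)
  peaks <- growth_peak_phase(traj)
  ndays <- length(attr(traj, "photoperiods"))
  list(plant_type = attr(traj, "plant_type"),
       photoperiods = attr(traj, "photoperiods"),
       days = ndays, dt = attr(traj, "dt"),
       total_growth_sam = traj$W_sam[nrow(traj)] - traj$W_sam[1],
       ten_day_growth = if (max(traj$t) >= 240 - 1e-9) ten_day_growth(traj) else NULL,
       sink_sucrose_cv_last_day = diel_cv(traj, "S_Y_sam"),
       growth_rate_peak_tod = peaks$peak,
       growth_rate_trough_tod = peaks$trough,
       carbon_audit_residual = audit$residual,
       transport_residual = audit$transport_residual,
       clamped_steps = audit$clamped_steps)
}
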