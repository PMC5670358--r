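#' Clock parameters
#'
#' Parameters of the circadian phase oscillator and of its sucrose input
#' pathway.  The oscillator runs at angular speed `omega` (h of phase per h of
#' clock time; `omega = 1` gives a 24-h period), is reset to 0 at dawn and to
#' the day's photoperiod at dusk, and is advanced/delayed by the sucrose
#' phase-response curve whose sign flips at the subjective dusk `phi_star`.
#'
#' @param omega phase speed (h/h), > 0.
#' @param phi_star subjective dusk (h), in (0, 24].
#' @param Z_amplitude amplitude of the sucrose phase-response curve
#'   (h of phase shift per hour per unit signal).
#' @param fS_K half-saturation of the signed Hill sugar input, on the scale of
#'   `dS_G/dt` (umolC6 / gFW / h); > 0.
#' @param fS_n Hill exponent of the sugar input, >= 1.
#' @param sugar_response logical; `FALSE` silences the sugar input entirely
#'   (the sugar-insensitive mutant).
#' @return a list of class `clock_params`.
#' @export
clock_params <- function(omega = 1, phi_star = 10, Z_amplitude = 0.6,
                         fS_K = 0.5, fS_n = 2, sugar_response = TRUE) {
  p <- structure(list(omega = omega, phi_star = phi_star,
                      Z_amplitude = Z_amplitude, fS_K = fS_K, fS_n = fS_n,
                      sugar_response = isTRUE(sugar_response)),
                 class = "clock_params")
  stop_on_violation(validate_clock(p))
  p
}

#' Source-leaf parameters
#'
#' Carbon assimilation, partitioning into starch versus sucrose, respiration,
#' phloem loading, and the clock-gated starch degradation law
#' `beta(phi) * C^kappa` with `beta` running between `beta_min` (trough, at the
#' subjective dusk) and `beta_max` (peak, at dawn).
#'
#' @param a photosynthetic assimilation rate during light (umolC6 / gFW / h).
#' @param gamma fraction of assimilate partitioned into starch, in \[0, 1\].
#' @param h_G source respiration rate (1/h).
#' @param eta_G phloem loading rate (1/h).
#' @param kappa starch-degradation exponent (> 0); small values give
#'   near-zero-order degradation and hence near-linear nocturnal decline.
#' @param beta_min,beta_max trough and peak of the degradation schedule
#'   (1/h on the `C^kappa` scale), `0 < beta_min <= beta_max`.
#' @param beta_shape_day,beta_shape_night branch shape exponents of the
#'   schedule (> 0); see [starch_degradation_rate()].
#' @return a list of class `source_params`.
#' @export
source_params <- function(a = 6, gamma = 0.5, h_G = 0.1, eta_G = 0.4,
                          kappa = 0.5, beta_min = 0.18, beta_max = 1.198,
                          beta_shape_day = 3, beta_shape_night = 0.7) {
  p <- structure(list(a = a, gamma = gamma, h_G = h_G, eta_G = eta_G,
                      kappa = kappa, beta_min = beta_min, beta_max = beta_max,
                      beta_shape_day = beta_shape_day,
                      beta_shape_night = beta_shape_night),
                 class = "source_params")
  stop_on_violation(validate_source(p))
  p
}

#' Sink parameters
#'
#' Unloading, respiration, growth-related sucrose consumption (saturating Hill
#' kinetics by default, or a linear law for robustness runs) and the
#' sucrose-to-biomass conversion rate.  Both sinks (SAM and RAM) share one
#' parameter set.
#'
#' @param eta_Y unloading rate; multiplies the adjacent tube concentration and
#'   carries the per-volume to per-gram unit conversion.
#' @param h_Y sink respiration rate (1/h).
#' @param alpha_max maximal growth consumption (umolC6 / gFW / h).
#' @param n_tilde Hill exponent (>= 1).
#' @param K_tilde half-saturation sucrose (umolC6 / gFW).
#' @param lambda biomass conversion rate (gFW per umolC6).
#' @param growth_form `"saturating"` (Hill) or `"linear"`.
#' @param linear_slope slope of the linear law; defaults to
#'   `alpha_max / K_tilde` so the two forms agree at low sucrose.
#' @return a list of class `sink_params`.
#' @export
sink_params <- function(eta_Y = 0.5, h_Y = 0.1, alpha_max = 2.5, n_tilde = 4,
                        K_tilde = 2, lambda = 0.01,
                        growth_form = c("saturating", "linear"),
                        linear_slope = NULL) {
  growth_form <- match.arg(growth_form)
  p <- structure(list(eta_Y = eta_Y, h_Y = h_Y, alpha_max = alpha_max,
                      n_tilde = n_tilde, K_tilde = K_tilde, lambda = lambda,
                      growth_form = growth_form,
                      linear_slope = linear_slope %||% (alpha_max / K_tilde)),
                 class = "sink_params")
  stop_on_violation(validate_sink(p))
  p
}

#' Phloem network geometry
#'
#' The six-component rooted tree (source tube 0, connecting tubes 1-3, sink
#' tubes 4 = SAM and 5 = RAM, parent map `1->0, 2->1, 3->1, 4->2, 5->3`).
#' Every component is a rigid cylinder; each edge carries a hydraulic
#' conductance `pi r^4 / (8 mu l)` and pressures follow the local
#' van 't Hoff closure `p_i = vant_hoff_eps * g_i`.
#'
#' @param V volumes of components 0..5 (volume units); components 4 and 5 must
#'   be identical (symmetric sinks).
#' @param r,l tube radius and length (length units), shared by all five edges.
#' @param mu sap viscosity (pressure x time).
#' @param vant_hoff_eps osmotic pressure per unit concentration.
#' @return a list of class `network_geometry`; the derived per-edge
#'   conductance is stored as `k`.
#' @export
network_geometry <- function(V = c(1, 0.2, 0.2, 0.2, 0.5, 0.5), r = 1, l = 1,
                             mu = pi / 1.6, vant_hoff_eps = 1) {
  p <- structure(list(V = as.numeric(V), r = r, l = l, mu = mu,
                      vant_hoff_eps = vant_hoff_eps,
                      parent = c(NA_integer_, 0L, 1L, 1L, 2L, 3L),
                      k = rep(edge_conductance(r, l, mu), 5)),
                 class = "network_geometry")
  stop_on_violation(validate_network(p))
  p
}

#' Full model parameter set
#'
#' @param clock,source,sink,network subsystem parameter objects (see
#'   [clock_params()], [source_params()], [sink_params()],
#'   [network_geometry()]).
#' @return a list of class `plant_params`.
#' @export
model_parameters <- function(clock = clock_params(), source = source_params(),
                             sink = sink_params(), network = network_geometry()) {
  p <- structure(list(clock = clock, source = source, sink = sink,
                      network = network), class = "plant_params")
  stop_on_violation(validate_parameters(p))
  p
}

#' Default calibrated parameter set
#'
#' Reads the versioned default configuration shipped with the package
#' (`inst/extdata/default_params.yaml`).  The starch-degradation defaults
#' (`kappa`, `beta_min`, `beta_max`) are calibrated so that a fully entrained
#' plant (`phi_star = tau_L = 12`) accumulates starch near-linearly by day,
#' degrades it near-linearly by night, and exhausts it at the anticipated dawn.
#'
#' @return a `plant_params` object.
#' @export
default_parameters <- function() {
  if (is.null(.pc_cache$defaults)) {
    path <- system.file("extdata", "default_params.yaml", package = "phloemclock")
    .pc_cache$defaults <- read_model_config(path)
  }
  .pc_cache$defaults
}

# --- validation -------------------------------------------------------------

chk <- function(cond, field, rule) if (isTRUE(cond)) character() else paste0(field, ": ", rule)

validate_clock <- function(p) c(
  chk(is.numeric(p$omega) && p$omega > 0, "omega", "must be > 0"),
  chk(is.numeric(p$phi_star) && p$phi_star > 0 && p$phi_star <= 24,
      "phi_star", "must lie in (0, 24]"),
  chk(is.numeric(p$Z_amplitude) && p$Z_amplitude >= 0, "Z_amplitude", "must be >= 0"),
  chk(is.numeric(p$fS_K) && p$fS_K > 0, "fS_K", "must be > 0"),
  chk(is.numeric(p$fS_n) && p$fS_n >= 1, "fS_n", "must be >= 1"),
  chk(is.logical(p$sugar_response), "sugar_response", "must be logical"))

validate_source <- function(p) c(
  chk(p$a >= 0, "a", "must be >= 0"),
  chk(p$gamma >= 0 && p$gamma <= 1, "gamma", "must lie in [0, 1]"),
  chk(p$h_G >= 0, "h_G", "must be >= 0"),
  chk(p$eta_G >= 0, "eta_G", "must be >= 0"),
  chk(p$kappa > 0, "kappa", "must be > 0"),
  chk(p$beta_min > 0, "beta_min", "must be > 0"),
  chk(p$beta_max >= p$beta_min, "beta_max", "must be >= beta_min"),
  chk(p$beta_shape_day > 0, "beta_shape_day", "must be > 0"),
  chk(p$beta_shape_night > 0, "beta_shape_night", "must be > 0"))

validate_sink <- function(p) c(
  chk(p$eta_Y >= 0, "eta_Y", "must be >= 0"),
  chk(p$h_Y >= 0, "h_Y", "must be >= 0"),
  chk(p$alpha_max >= 0, "alpha_max", "must be >= 0"),
  chk(p$n_tilde >= 1, "n_tilde", "must be >= 1"),
  chk(p$K_tilde > 0, "K_tilde", "must be > 0"),
  chk(p$lambda >= 0, "lambda", "must be >= 0"),
  chk(p$growth_form %in% c("saturating", "linear"), "growth_form",
      "must be 'saturating' or 'linear'"),
  chk(p$linear_slope >= 0, "linear_slope", "must be >= 0"))

validate_network <- function(p) c(
  chk(length(p$V) == 6 && all(p$V > 0), "V", "must be 6 positive volumes"),
  chk(p$r > 0, "r", "must be > 0"),
  chk(p$l > 0, "l", "must be > 0"),
  chk(p$mu > 0, "mu", "must be > 0"),
  chk(p$vant_hoff_eps > 0, "vant_hoff_eps", "must be > 0"),
  chk(isTRUE(all.equal(p$V[5], p$V[6])), "V", "sink components 4 and 5 must be identical"),
  chk(identical(p$parent, c(NA_integer_, 0L, 1L, 1L, 2L, 3L)), "parent",
      "topology must be the rooted tree 1->0, 2->1, 3->1, 4->2, 5->3"))

#' Validate a full parameter set
#'
#' A pure reporting operation: returns a character vector of violations, one
#' entry per broken invariant naming the field and the rule; an empty vector
#' means the parameter set is valid.
#'
#' @param p a `plant_params` object (or any list with the same shape).
#' @return character vector of violations (possibly empty).
#' @export
validate_parameters <- function(p) {
  c(validate_clock(p$clock), validate_source(p$source),
    validate_sink(p$sink), validate_network(p$network))
}

stop_on_violation <- function(v) if (length(v)) abort_config(paste(v, collapse = "; "))

# --- plant-type presets -----------------------------------------------------

#' Build the parameter preset for one of the three plant types
#'
#' * `wild_type`: sugar response enabled, `phi_star` as in `base`.
#' * `mutant`: identical to the wild type except that the sugar input to the
#'   clock is silenced (`sugar_response = FALSE`); light resets are unchanged.
#' * `homeostatic`: the idealized plant that always anticipates dusk exactly:
#'   `phi_star` is set to `tau_L` and the degradation schedule
#'   `(beta_min, beta_max)` is re-optimized for that photoperiod with
#'   [optimize_beta()] to minimize the diel fluctuation of sink sucrose.
#'
#' Presets are pure: the same inputs always return the same parameters
#' (homeostatic optimizations are deterministic and cached per session).
#'
#' @param plant_type one of `"wild_type"`, `"mutant"`, `"homeostatic"`.
#' @param tau_L photoperiod (h), in (0, 24]; only used by the homeostatic type.
#' @param base base parameter set, defaults to [default_parameters()].
#' @return a `plant_params` object.
#' @export
plant_preset <- function(plant_type, tau_L = 12, base = default_parameters()) {
  if (!(is.numeric(tau_L) && tau_L > 0 && tau_L <= 24))
    abort_config("tau_L: must lie in (0, 24]")
  if (length(plant_type) != 1 || !plant_type %in% c("wild_type", "mutant", "homeostatic"))
    abort_config(paste0("plant_type: unknown plant type '",
                        paste(plant_type, collapse = ","), "'"))
  p <- base
  switch(plant_type,
    wild_type = {
      p$clock$sugar_response <- TRUE
    },
    mutant = {
      p$clock$sugar_response <- FALSE
    },
    homeostatic = {
      p$clock$sugar_response <- TRUE
      p$clock$phi_star <- tau_L
      b <- optimize_beta(tau_L, base)
      p$source$beta_min <- b[["beta_min"]]
      p$source$beta_max <- b[["beta_max"]]
    })
  p
}

# --- configuration files ----------------------------------------------------

.config_fields <- list(
  clock = c("omega", "phi_star", "Z_amplitude", "fS_K", "fS_n", "sugar_response"),
  source = c("a", "gamma", "h_G", "eta_G", "kappa", "beta_min", "beta_max",
             "beta_shape_day", "beta_shape_night"),
  sink = c("eta_Y", "h_Y", "alpha_max", "n_tilde", "K_tilde", "lambda",
           "growth_form", "linear_slope"),
  network = c("V", "r", "l", "mu", "vant_hoff_eps"))

#' Read a model configuration file
#'
#' Structured YAML with sections `clock`, `source`, `sink`, `network` and the
#' optional sections `calibration` (the [optimize_beta()] grid), `protocol`
#' (default rk4 step and burn-in), `initial_state` and `scenarios` (the
#' trajectory-fixture registry).  Unknown sections or keys are rejected.
#'
#' @param path path to a YAML file.
#' @return a `plant_params` object; the extra sections are attached as
#'   attributes `calibration`, `protocol`, `initial_state` and `scenarios`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  known <- c(names(.config_fields), "calibration", "protocol", "initial_state",
             "scenarios")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    abort_config(paste0("unknown configuration section(s): ",
                        paste(extra, collapse = ", ")))
  for (sec in names(.config_fields)) {
    if (is.null(cfg[[sec]])) abort_config(paste0("missing configuration section: ", sec))
    bad <- setdiff(names(cfg[[sec]]), .config_fields[[sec]])
    if (length(bad))
      abort_config(paste0("unknown key(s) in section '", sec, "': ",
                          paste(bad, collapse = ", ")))
  }
  p <- model_parameters(
    clock = do.call(clock_params, cfg$clock),
    source = do.call(source_params, cfg$source),
    sink = do.call(sink_params, cfg$sink),
    network = do.call(network_geometry, cfg$network))
  attr(p, "calibration") <- cfg$calibration
  attr(p, "protocol") <- cfg$protocol
  attr(p, "initial_state") <- cfg$initial_state
  attr(p, "scenarios") <- cfg$scenarios
  p
}

#' Write a model configuration file
#'
#' @param p a `plant_params` object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(p, path) {
  cfg <- list(
    clock = p$clock[.config_fields$clock],
    source = p$source[.config_fields$source],
    sink = p$sink[.config_fields$sink],
    network = p$network[.config_fields$network])
  for (sec in c("calibration", "protocol", "initial_state", "scenarios"))
    if (!is.null(attr(p, sec))) cfg[[sec]] <- attr(p, sec)
  cfg <- lapply(cfg, function(x) { class(x) <- NULL; x })
  yaml::write_yaml(cfg, path)
  invisible(path)
}
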