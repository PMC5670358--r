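# Default calibrated parameter set for phloemclock.
#
# Units: sucrose and starch in umolC6 / gFW, phloem concentrations in umolC6
# per volume unit, time in hours, biomass in gFW.  The source leaf is treated
# as 1 gFW of tissue, so per-gram pools double as amounts.
#
# kappa, the shape exponents and (beta_min, beta_max) are calibrated (see the
# methods vignette): beta_max is set by bisection, at beta_min/beta_max = 0.15,
# so that a fully entrained plant (phi_star = tau_L = 12) depletes starch to
# 1% of its diel peak 23.7 h after dawn; with kappa = 0.5 this gives
# near-linear accumulation by day and near-linear degradation by night.
clock:
  omega: 1.0
  phi_star: 10.0
  Z_amplitude: 0.6
  fS_K: 0.5
  fS_n: 2.0
  sugar_response: yes
source:
  a: 6.0
  gamma: 0.5
  h_G: 0.1
  eta_G: 0.4
  kappa: 0.5
  beta_min: 0.18
  beta_max: 1.198
  beta_shape_day: 3.0
  beta_shape_night: 0.7
sink:
  eta_Y: 0.5
  h_Y: 0.1
  alpha_max: 2.5
  n_tilde: 4.0
  K_tilde: 2.0
  lambda: 0.01
  growth_form: saturating
network:
  V: [1.0, 0.2, 0.2, 0.2, 0.5, 0.5]
  r: 1.0
  l: 1.0
  mu: 1.9634954084936207  # gives edge conductance pi r^4 / (8 mu l) = 0.2
  vant_hoff_eps: 1.0
calibration:
  # log-spaced 20 x 20 grid searched by optimize_beta(), then coordinate descent
  beta_grid:
    min_lo: 0.005
    min_hi: 2.0
    max_lo: 0.05
    max_hi: 20.0
    n_grid: 20
  days: 8
  dt: 0.05
protocol:
  rk4_step: 0.01
  burn_in_days: 3
initial_state:
  S_G: 1.0
  C: 0.0
  g: 0.5
  S_Y: 0.5
  W_Y: 0.0005
scenarios:
  wt_16L8D:   {plant_type: wild_type, photoperiod: 16.0, days: 4, dt: 0.05}
  mutant_8L16D: {plant_type: mutant, photoperiod: 8.0, days: 4, dt: 0.05}
  wt_12L12D:  {plant_type: wild_type, photoperiod: 12.0, days: 4, dt: 0.05}
  shift_8to16: {plant_type: wild_type, tau_before: 8.0, tau_after: 16.0,
                days_before: 5, days_after: 5, dt: 0.05}
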