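#' Positive part
#'
#' The upwind bracket `[x]_+ = max(x, 0)` used by the advection scheme.
#'
#' @param x numeric vector.
#' @return elementwise `max(x, 0)`.
#' @export
positive_part <- function(x) pmax(x, 0)

#' Hydraulic conductance of a tube edge
#'
#' `pi r^4 / (8 mu l)`, the Hagen-Poiseuille coefficient.
#'
#' @param r tube radius; @param l tube length; @param mu sap viscosity.
#' @return conductance (volume per time per pressure).
#' @export
edge_conductance <- function(r, l, mu) pi * r^4 / (8 * mu * l)

#' Component pressures under the local osmotic-equilibrium closure
#'
#' Each rigid component is assumed to be in instantaneous osmotic equilibrium
#' with a xylem of uniform water potential, so the hydrostatic pressure is the
#' van 't Hoff osmotic pressure of its own sap: `p_i = vant_hoff_eps * g_i`.
#' Muench flow then reduces to concentration-gradient-driven Hagen-Poiseuille
#' flux.  The closure is a function of its own, so a full hydraulic solve can
#' replace it without touching the advection code.
#'
#' @param g concentrations `g_0..g_5` (>= 0).
#' @param geom a [network_geometry()] object.
#' @return pressures `p_0..p_5`.
#' @export
component_pressures <- function(g, geom) geom$vant_hoff_eps * g

#' Hagen-Poiseuille flux through one edge
#'
#' `(pi r^4 / (8 mu l)) * (p_up - p_down)`; positive when sap runs from the
#' parent (`p_up`) toward the child (`p_down`).
#'
#' @param p_up,p_down pressures at the two ends.
#' @param r,l,mu tube radius, length and sap viscosity (> 0).
#' @return volumetric flux (volume / h).
#' @export
hagen_poiseuille_flux <- function(p_up, p_down, r, l, mu) {
  edge_conductance(r, l, mu) * (p_up - p_down)
}

#' Edge fluxes of the whole network
#'
#' @param g concentrations `g_0..g_5`.
#' @param geom a [network_geometry()] object.
#' @return fluxes `J_1..J_5`, `J_i` being the flow into component `i` from its
#'   parent (positive toward the sinks).
#' @export
network_fluxes <- function(g, geom) {
  p <- component_pressures(g, geom)
  par <- geom$parent[2:6] + 1L
  geom$k * (p[par] - p[2:6])
}

#' Upwind advection rates of the phloem concentrations
#'
#' Component 0 gains the loading flux and exchanges with its child through the
#' upwind brackets; internal tubes exchange with parent and children; the two
#' sink-adjacent tubes (leaves of the tree) additionally lose the unloading
#' term `eta_Y * g_i`.  Works for any rooted-tree parent map (leaves are the
#' childless components), which the tests exercise on a two-component chain.
#'
#' @param g concentrations (one per component).
#' @param J edge fluxes, `J[i]` into component `i` (root has none).
#' @param loading sucrose loading into the root component (amount / h), >= 0.
#' @param eta_Y unloading rate applied at every leaf component.
#' @param geom geometry with fields `V` and `parent` (root's parent is `NA`).
#' @return `dg/dt` per component.
#' @export
advection_rates <- function(g, J, loading, eta_Y, geom) {
  n <- length(g)
  parent <- geom$parent
  if (any(!is.na(parent) & (parent >= seq_len(n) - 1L)))
    abort_config("topology must be a rooted tree (parent index below child)")
  dg <- numeric(n)
  dg[1] <- loading
  leaves <- setdiff(seq_len(n) - 1L, parent[!is.na(parent)])
  for (i in seq_len(n - 1L)) {      # component index i (1-based position i+1)
    Ji <- J[i]
    pa <- parent[i + 1L] + 1L
    inout <- g[pa] * positive_part(Ji) - g[i + 1L] * positive_part(-Ji)
    dg[i + 1L] <- dg[i + 1L] + inout
    dg[pa] <- dg[pa] - inout
  }
  for (lf in leaves) dg[lf + 1L] <- dg[lf + 1L] - eta_Y * g[lf + 1L]
  dg / geom$V
}

#' Osmotic water-exchange diagnostics
#'
#' Under the rigid constant-volume assumption every component must exchange
#' pure water with the xylem to balance its sap throughput; `w_i` is the net
#' volumetric imbalance (sap outflow minus inflow) at component `i`.  Reported
#' for inspection only; the state never depends on it.
#'
#' @param J edge fluxes `J_1..J_n` (into each non-root component).
#' @param geom geometry with a `parent` map.
#' @return `w_0..w_n`, summing to zero.
#' @export
water_exchange_diagnostics <- function(J, geom) {
  n <- length(geom$parent)
  w <- numeric(n)
  for (i in seq_len(n - 1L)) {
    pa <- geom$parent[i + 1L] + 1L
    w[pa] <- w[pa] + J[i]    # outflow from the parent
    w[i + 1L] <- w[i + 1L] - J[i]  # inflow into the child
  }
  w
}
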