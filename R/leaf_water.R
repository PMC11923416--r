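#' Craig-Gordon evaporative-site enrichment
#'
#' Steady-state heavy-isotope enrichment of water at the evaporating sites
#' above source water:
#' \deqn{\Delta_e = \varepsilon^+ + \varepsilon_k + (\Delta_v - \varepsilon_k)\,e_a/e_i}
#' where `Delta_v` is the vapor enrichment above source water (per mil,
#' computed by exact ratio algebra, see [delta_above_source()]), and
#' `ea_over_ei` the ambient/intercellular vapor-pressure ratio.
#'
#' Ratios above 1 (dew-formation regime) are permitted; they are reported
#' with an attribute `"dew"` marking the affected elements.
#'
#' @param delta_v Vapor 2H enrichment above source, per mil.
#' @param eps_plus Equilibrium enrichment, per mil.
#' @param eps_k Kinetic enrichment, per mil.
#' @param ea_over_ei Dimensionless vapor-pressure ratio, >= 0.
#' @return Evaporative-site enrichment `Delta_e`, per mil.
#' @examples
#' craig_gordon(-80, 74, 25, 0.6)  # 36
#' @export
craig_gordon <- function(delta_v, eps_plus, eps_k, ea_over_ei) {
  if (any(ea_over_ei < 0, na.rm = TRUE)) {
    stop("ea/ei must be non-negative")
  }
  out <- eps_plus + eps_k + (delta_v - eps_k) * ea_over_ei
  dew <- which(ea_over_ei > 1)
  if (length(dew)) attr(out, "dew") <- dew
  out
}

#' Peclet number for advection-diffusion in the leaf lamina
#'
#' `peclet = E * L_eff / (C * D)` with transpiration `E` (mol m-2 s-1),
#' effective path length `L_eff` (m), molar water density `C` (mol m-3) and
#' HDO diffusivity `D` (m2 s-1, see [hdo_diffusivity()]).
#'
#' @param E Transpiration, mol m-2 s-1 (>= 0).
#' @param L_eff Effective path length, m; default 0.02 (package default, not
#'   a field-calibrated value).
#' @param C Molar density of water, mol m-3.
#' @param D Diffusivity of HDO in water, m2 s-1; default at 20 degrees C.
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(E, L_eff = 0.02, C = WATER_MOLAR_DENSITY,
                          D = hdo_diffusivity(20)) {
  stopifnot(all(E >= 0, na.rm = TRUE), L_eff > 0, C > 0, all(D > 0))
  E * L_eff / (C * D)
}

#' Peclet correction of evaporative-site enrichment
#'
#' Bulk lamina steady-state enrichment
#' `Delta_L = Delta_e * (1 - exp(-p)) / p`; for `p < 1e-6` the series limit
#' `Delta_e * (1 - p/2 + p^2/6)` is used to avoid cancellation.
#'
#' @param delta_e Evaporative-site enrichment, per mil.
#' @param peclet Peclet number, >= 0.
#' @return Bulk enrichment `Delta_L`, per mil.
#' @export
peclet_correction <- function(delta_e, peclet) {
  if (any(peclet < 0, na.rm = TRUE)) stop("Peclet number must be >= 0")
  damp <- ifelse(peclet < 1e-6,
                 1 - peclet / 2 + peclet^2 / 6,
                 (1 - exp(-peclet)) / peclet)
  delta_e * damp
}

#' Two-pool correction of evaporative-site enrichment
#'
#' Bulk leaf water treated as a mixture of an unenriched (vein) fraction
#' `phi` and an enriched fraction: `Delta_L = (1 - phi) * Delta_e`.
#'
#' @param delta_e Evaporative-site enrichment, per mil.
#' @param phi Unenriched water fraction in \[0, 1\]; default 0.2 (package
#'   default, not a field-calibrated value).
#' @return Bulk enrichment, per mil.
#' @export
two_pool_correction <- function(delta_e, phi = 0.2) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  (1 - phi) * delta_e
}

#' Compose/decompose needle-water delta from source delta and enrichment
#'
#' Exact isotope-ratio algebra (never the additive approximation):
#' `compose_needle_water` raises the source composition by an enrichment
#' `Delta` so that `(1000 + d2H_n) = (1 + Delta/1000) * (1000 + d2H_source)`;
#' `delta_above_source` is its exact inverse and is also used to express
#' vapor disequilibrium `Delta_v` relative to source water. The round trip
#' is exact to machine precision.
#'
#' @param d2H_source Source (twig) water composition, per mil VSMOW.
#' @param Delta Enrichment above source, per mil.
#' @return Needle-water composition, per mil VSMOW.
#' @examples
#' compose_needle_water(-84.8, 43.38)       # ~ -45.1
#' delta_above_source(-45.1, -84.8)         # ~ 43.38
#' @export
compose_needle_water <- function(d2H_source, Delta) {
  stopifnot(all(is.finite(d2H_source)), all(is.finite(Delta)))
  Delta / 1000 * (1 + d2H_source / 1000) * 1000 + d2H_source
}

#' @rdname compose_needle_water
#' @param d2H Absolute composition to express as enrichment above
#'   `d2H_source`, per mil VSMOW.
#' @export
delta_above_source <- function(d2H, d2H_source) {
  ((1000 + d2H) / (1000 + d2H_source) - 1) * 1000
}

#' Steady-state leaf-water enrichment for a forcing table
#'
#' Per-step steady-state bulk enrichment: Craig-Gordon `Delta_e` followed by
#' the chosen bulk correction. Columns required: `T_air`, `RH`, `p_air`,
#' `E`, `g_t`, `d2H_vapor` plus a per-step `d2H_source` vector.
#'
#' @param forcings Data frame of half-hourly forcings (see
#'   [simulate_forcings()]) with a `g_t` column.
#' @param d2H_source Source-water composition per step (recycled if daily),
#'   per mil.
#' @param variant One of `"peclet"`, `"two_pool"`, `"none"` (no bulk
#'   correction, `Delta_L = Delta_e`).
#' @param L_eff,phi,g_b Model constants, see [peclet_number()],
#'   [two_pool_correction()], [kinetic_fractionation()].
#' @return Data frame with `timestamp`, `Delta_e`, `Delta_L`, `d2H_n_water`,
#'   `peclet`.
#' @export
steady_state_leaf_water <- function(forcings, d2H_source, variant = "peclet",
                                    L_eff = 0.02, phi = 0.2, g_b = 2.4) {
  variant <- match.arg(variant, c("peclet", "two_pool", "none"))
  ep <- equilibrium_fractionation(forcings$T_air)
  gk <- pmax(forcings$g_t, 1e-6)
  ek <- kinetic_fractionation(gk, g_b = g_b)
  e_i <- leaf_intercellular_vapor(forcings$T_air)
  e_a <- forcings$e_a
  dv <- delta_above_source(forcings$d2H_vapor, d2H_source)
  de <- craig_gordon(dv, ep, ek, e_a / e_i)
  pe <- peclet_number(forcings$E, L_eff = L_eff,
                      D = hdo_diffusivity(forcings$T_air))
  dL <- switch(variant,
               peclet = peclet_correction(de, pe),
               two_pool = two_pool_correction(de, phi),
               none = as.numeric(de))
  data.frame(timestamp = forcings$timestamp,
             Delta_e = as.numeric(de),
             Delta_L = dL,
             d2H_n_water = compose_needle_water(d2H_source, dL),
             peclet = pe)
}

#' Nonsteady-state bulk leaf-water enrichment series
#'
#' Integrates the relaxation of bulk enrichment toward its steady-state
#' value,
#' \deqn{d\Delta_{Ln}/dt = (\Delta_{Ls} - \Delta_{Ln}) / \tau,\qquad
#'   \tau = W\,\alpha^+ \alpha_k / (g_t\, w_i)}
#' with leaf water content `W` (mol m-2) and intercellular vapor mole
#' fraction `w_i = e_i / p`. An explicit Euler scheme is used, sub-stepping
#' whenever the forcing step exceeds `tau / 2`; the initial condition is the
#' first steady-state value. When `g_t = 0` (no exchange, e.g. overnight)
#' `tau` is infinite and the enrichment is held constant across the step;
#' the number of such held steps is reported via attribute `"n_held"`.
#'
#' @param forcings Forcing data frame with `g_t` column (30-min step).
#' @param d2H_source Per-step source composition, per mil.
#' @param W Leaf water content, mol m-2; default 12 (package default).
#' @param variant Steady-state variant relaxed toward ("peclet" or
#'   "two_pool").
#' @inheritParams steady_state_leaf_water
#' @return Data frame `timestamp`, `Delta_Ls`, `Delta_Ln`, `d2H_n_water`,
#'   `tau_h` (time constant in hours).
#' @export
nonsteady_state_series <- function(forcings, d2H_source, W = 12,
                                   variant = "peclet",
                                   L_eff = 0.02, phi = 0.2, g_b = 2.4) {
  stopifnot(W > 0)
  variant <- match.arg(variant, c("peclet", "two_pool"))
  ss <- steady_state_leaf_water(forcings, d2H_source, variant = variant,
                                L_eff = L_eff, phi = phi, g_b = g_b)
  ep <- equilibrium_fractionation(forcings$T_air)
  gk <- pmax(forcings$g_t, 0)
  ek <- kinetic_fractionation(pmax(gk, 1e-6), g_b = g_b)
  alpha_p <- 1 + ep / 1000
  alpha_k <- 1 + ek / 1000
  w_i <- leaf_intercellular_vapor(forcings$T_air) / forcings$p_air
  tau_s <- ifelse(gk > 0, W * alpha_p * alpha_k / (gk * w_i), Inf)
  n <- nrow(forcings)
  dt <- if (n > 1) {
    as.numeric(difftime(forcings$timestamp[2], forcings$timestamp[1],
                        units = "secs"))
  } else {
    1800
  }
  dln <- numeric(n)
  dln[1] <- ss$Delta_L[1]
  n_held <- 0L
  for (i in seq_len(n - 1L)) {
    tau <- tau_s[i]
    if (!is.finite(tau)) {
      dln[i + 1L] <- dln[i]
      n_held <- n_held + 1L
      next
    }
    nsub <- max(1L, ceiling(dt / (tau / 2)))
    if (nsub > 10000L) {
      # stiff limit: enrichment equilibrates within the step
      dln[i + 1L] <- ss$Delta_L[i]
      next
    }
    h <- dt / nsub
    x <- dln[i]
    for (k in seq_len(nsub)) {
      x <- x + h / tau * (ss$Delta_L[i] - x)
    }
    dln[i + 1L] <- x
  }
  out <- data.frame(timestamp = forcings$timestamp,
                    Delta_Ls = ss$Delta_L,
                    Delta_Ln = dln,
                    d2H_n_water = compose_needle_water(d2H_source, dln),
                    tau_h = tau_s / 3600)
  attr(out, "n_held") <- n_held
  out
}
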