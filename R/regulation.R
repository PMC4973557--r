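#' Optical depth of the culture
#'
#' Lambert-Beer attenuation coefficient `K_e = k_e0 * (chlorophyll
#' concentration in g/m^3)`; chlorophyll concentration is `w_chl * x` with
#' `x` in g/L, hence the factor 1000.
#'
#' @param w_chl chlorophyll fraction (gChl/gDw).
#' @param x biomass dry weight (gDw/L).
#' @param params model parameters.
#' @return optical depth in m^-1.
#' @export
optical_depth <- function(w_chl, x, params) {
  if (any(w_chl < 0) || any(x < 0)) abort("optical_depth: inputs must be >= 0")
  params$k_e0 * 1000 * w_chl * x
}

#' Volume-averaged irradiance
#'
#' Average of the Lambert-Beer light field over the reactor depth:
#' `E_avg = E0 / (L_r K_e) * (1 - exp(-K_e L_r))`, with the transparent
#' limit `E_avg -> E0` as `K_e -> 0` evaluated by series expansion to keep
#' the function continuous.
#'
#' @param e0 incident intensity (umol photons m^-2 s^-1).
#' @param k_e optical depth (m^-1).
#' @param l_r reactor light path (m).
#' @return average intensity, same units as `e0`.
#' @export
average_irradiance <- function(e0, k_e, l_r) {
  stopifnot(all(e0 >= 0), all(k_e >= 0), l_r > 0)
  tau <- k_e * l_r
  ifelse(tau < 1e-6,
         e0 * (1 - tau / 2 + tau^2 / 6),
         e0 * (1 - exp(-tau)) / pmax(tau, .Machine$double.xmin))
}

#' Cell-specific light-use efficiency
#'
#' Affine in the chlorophyll fraction: `eta = theta_eff * (eta1 * w_chl +
#' eta0)`.
#'
#' @inheritParams optical_depth
#' @export
light_efficiency <- function(w_chl, params) {
  stopifnot(all(w_chl >= 0))
  params$theta_eff * (params$eta1 * w_chl + params$eta0)
}

#' Average biomass-specific light intensity
#'
#' `e_x = theta_dim * eta * E_avg / rho_A` with the areal biomass density
#' `rho_A = x * l_r` evaluated numerically in (g/L) * m; `theta_dim` (L/g)
#' makes the result mmol photons per gDw per h. This is the photon supply
#' the flux balance model sees.
#'
#' @param e_avg volume-averaged irradiance (umol photons m^-2 s^-1).
#' @param eta light-use efficiency (-).
#' @param x biomass (gDw/L), must be positive.
#' @param params model parameters.
#' @export
specific_light_intensity <- function(e_avg, eta, x, params) {
  if (any(x <= 0)) abort("specific_light_intensity: x must be positive")
  params$theta_dim * eta * e_avg / (x * params$l_r)
}

#' Chlorophyll-to-nitrogen ratio setpoint
#'
#' Inhibition curve of average irradiance, `gamma = gamma_max * k_e /
#' (E + k_e)`, with the argument capped at the saturation irradiance
#' `e_sat` (the ratio is constant above it).
#'
#' @param e_avg average irradiance (umol photons m^-2 s^-1).
#' @param params model parameters.
#' @return ratio in gChl/gN; non-increasing in `e_avg`.
#' @export
chl_nitrogen_ratio <- function(e_avg, params) {
  stopifnot(all(e_avg >= 0))
  e <- pmin(e_avg, params$e_sat)
  params$gamma_max * params$k_e / (e + params$k_e)
}

#' Lower bound of the chlorophyll accumulation flux
#'
#' Proportional tracking of the chlorophyll:nitrogen setpoint:
#' `v_chl_lb = gamma - w_chl / w_n` (implicit unit gain per hour). Positive
#' when the cell is below the setpoint (synthesis enforced), negative above
#' it (remobilization permitted).
#'
#' @param w_chl chlorophyll fraction (gChl/gDw).
#' @param w_n nitrogen quota (gN/gDw), must be positive.
#' @param gamma setpoint ratio from [chl_nitrogen_ratio()].
#' @export
chlorophyll_flux_lb <- function(w_chl, w_n, gamma) {
  if (any(w_n <= 0)) abort("chlorophyll_flux_lb: w_n must be positive")
  gamma - w_chl / w_n
}

#' Logistic smoothing step
#'
#' `Psi(u) = 1 / (1 + exp(-eta_s * u))`, evaluated in a numerically stable
#' two-branch form (no overflow for large `|eta_s * u|`).
#'
#' @param u argument.
#' @param eta_s smoothing factor.
#' @export
smooth_step <- function(u, eta_s) {
  z <- eta_s * u
  ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
}

#' Light-induced carotene generation bound
#'
#' Hill curve of the biomass-specific light intensity:
#' `v = v_car_max * e_x^n / (e_x_a^n + e_x^n)`.
#'
#' @param e_x biomass-specific light intensity (mmol photons/gDw/h).
#' @param params model parameters.
#' @export
carotene_generation_lb <- function(e_x, params) {
  stopifnot(all(e_x >= 0))
  en <- e_x^params$n_car
  params$v_car_max * en / (params$e_x_a^params$n_car + en)
}

#' Nitrogen-quota threshold for carotene induction
#'
#' The induction gate opens for quotas below `alpha1 * e_x + alpha0`.
#'
#' @inheritParams carotene_generation_lb
#' @return threshold quota (gN/gDw).
#' @export
carotene_quota_threshold <- function(e_x, params) {
  params$alpha1 * e_x + params$alpha0
}

#' Lower bound of the carotene accumulation flux
#'
#' Product of the light-driven generation term and the logistic
#' nitrogen gate: `v = v_gen * Psi(alpha1 * e_x + alpha0 - w_n)`. The upper
#' bound of this flux is infinite.
#'
#' @inheritParams carotene_generation_lb
#' @param w_n nitrogen quota (gN/gDw).
#' @export
carotene_flux_lb <- function(e_x, w_n, params) {
  stopifnot(all(e_x >= 0), all(w_n >= 0))
  carotene_generation_lb(e_x, params) *
    smooth_step(carotene_quota_threshold(e_x, params) - w_n, params$eta_s)
}

#' Lower bound of the nitrate metabolization flux
#'
#' `v = -v_no3_met_max * (1 - w_n_min / w_n)`: metabolization of the
#' internal store shuts down as the quota approaches its minimum. The upper
#' bound is zero (no nitrate is synthesized). Quotas below `w_n_min`
#' (integrator round-off) are clamped to zero flux with a warning.
#'
#' @param w_n nitrogen quota (gN/gDw).
#' @param params model parameters.
#' @return value in `[-v_no3_met_max, 0]` (mmol/gDw/h).
#' @export
nitrate_metabolization_lb <- function(w_n, params) {
  out <- -params$v_no3_met_max * (1 - params$w_n_min / pmax(w_n, params$w_n_min))
  if (any(w_n < params$w_n_min)) {
    warn("nitrogen quota below w_n_min; metabolization clamped to 0")
  }
  pmin(out, 0)
}

#' Lag-phase attenuation
#'
#' Hill rise from dormancy: `psi = t^n / (lambda^n + t^n)` with `t` in days
#' since inoculation. Multiplies the bounds of every exchange/accumulation
#' flux and the maintenance demand.
#'
#' @param t_d time since inoculation (d).
#' @param params model parameters.
#' @return value in `[0, 1)`.
#' @export
lag_factor <- function(t_d, params) {
  stopifnot(all(t_d >= 0))
  tn <- t_d^params$n_lag
  tn / (params$lambda^params$n_lag + tn)
}

#' Evaluate the light field at a reactor state
#'
#' @param state reactor state: list/row with `x`, `w_chl`.
#' @param e0 incident light (umol photons m^-2 s^-1).
#' @param params model parameters.
#' @return list with `e0`, `k_e`, `e_avg`, `eta`, `e_x`, `rho_a`.
#' @export
light_field <- function(state, e0, params) {
  k_e <- optical_depth(state$w_chl, state$x, params)
  e_avg <- average_irradiance(e0, k_e, params$l_r)
  eta <- light_efficiency(state$w_chl, params)
  e_x <- specific_light_intensity(e_avg, eta, state$x, params)
  list(e0 = e0, k_e = k_e, e_avg = e_avg, eta = eta, e_x = e_x,
       rho_a = state$x * params$l_r)
}

#' State-dependent flux bounds
#'
#' Composes every regulatory bound model at a reactor state and returns the
#' per-reaction bound overrides for the FBA: the photon exchange is fixed at
#' the (signed, uptake-negative) biomass-specific light intensity; nitrate
#' metabolization is bounded in `[v_no3_met_lb, 0]`; the chlorophyll and
#' carotene accumulation fluxes get their regulatory lower bounds with
#' infinite upper bounds; the ATP maintenance demand `ngam` is a lower
#' bound (its turnover is left open as the energy-dissipation route). All
#' bounds, and those of any other exchange reaction, are attenuated by the
#' lag factor `psi(t)`.
#'
#' @param state reactor state with `t` (h), `x`, `c_no3`, `w_chl`, `w_car`,
#'   `w_n`.
#' @param e0 incident light intensity.
#' @param params model parameters.
#' @param network a `stoich_network`.
#' @return tibble with columns `reaction`, `lb`, `ub` (only regulated
#'   reactions listed).
#' @export
regulated_bounds <- function(state, e0, params, network) {
  roles <- network_roles(network)
  lf <- light_field(state, e0, params)
  psi <- lag_factor(state$t / 24, params)
  gamma <- chl_nitrogen_ratio(lf$e_avg, params)
  v_chl_lb <- chlorophyll_flux_lb(state$w_chl, state$w_n, gamma)
  v_car_lb <- carotene_flux_lb(lf$e_x, state$w_n, params)
  v_no3_lb <- nitrate_metabolization_lb(state$w_n, params)

  out <- tibble(
    reaction = unname(roles[c("photon", "nitrate_met", "chl_acc", "car_acc", "ngam")]),
    lb = c(-psi * lf$e_x, psi * v_no3_lb, psi * v_chl_lb, psi * v_car_lb,
           psi * params$ngam),
    ub = c(-psi * lf$e_x, 0, Inf, Inf, Inf)
  )
  # any further plain exchange reactions are attenuated too
  other <- network$reactions$id[network$reactions$role %in% "exchange"]
  if (length(other)) {
    j <- match(other, network$reactions$id)
    sc <- function(b) ifelse(is.finite(b), psi * b, b)
    out <- bind_rows(out, tibble(reaction = other,
                                 lb = sc(network$reactions$lb[j]),
                                 ub = sc(network$reactions$ub[j])))
  }
  attr(out, "light") <- lf
  attr(out, "psi") <- psi
  out
}
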