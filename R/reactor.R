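#' Construct a reactor state
#'
#' @param x biomass dry weight (gDw/L), positive.
#' @param c_no3 extracellular nitrate (gNO3/L).
#' @param w_n nitrogen quota (gN/gDw).
#' @param w_chl,w_car pigment fractions (g/gDw); default `NULL` takes them
#'   from the network biomass composition when the state is used in
#'   [simulate_culture()].
#' @param t time since inoculation (h).
#' @export
reactor_state <- function(x, c_no3, w_n, w_chl = NULL, w_car = NULL, t = 0) {
  if (x <= 0) abort("biomass must be positive")
  if (c_no3 < 0 || w_n < 0) abort("concentrations must be non-negative")
  structure(list(t = t, x = x, c_no3 = c_no3, w_chl = w_chl, w_car = w_car,
                 w_n = w_n), class = "reactor_state")
}

#' Michaelis-Menten nitrate uptake with quota saturation
#'
#' `v = v_no3_max * c / (K_m + c) * (1 - w_n / w_n_max)`; zero when the
#' quota is full or nitrate exhausted. Quotas above `w_n_max` (integration
#' round-off) clamp the saturation factor to zero with a warning.
#'
#' @param c_no3 extracellular nitrate (gNO3/L).
#' @param w_n nitrogen quota (gN/gDw).
#' @param params model parameters.
#' @return uptake rate in gNO3 per gDw per h.
#' @export
nitrate_uptake <- function(c_no3, w_n, params) {
  stopifnot(all(c_no3 >= 0))
  if (any(w_n > params$w_n_max)) {
    warn("nitrogen quota above w_n_max; uptake clamped to 0")
  }
  sat <- pmax(0, 1 - w_n / params$w_n_max)
  params$v_no3_max * c_no3 / (params$k_m + c_no3) * sat
}

#' Photobioreactor right-hand side
#'
#' The five state derivatives, exactly the printed system: `dx/dt = mu x`,
#' `dc_no3/dt = -v_no3 x (+ feed)`, `dw_chl/dt = m_chl v_chl - mu w_chl`,
#' `dw_car/dt = m_car v_car - mu w_car`, `dw_n/dt = (m_n/m_no3) v_no3 -
#' mu w_n`. In fed-batch mode the nitrogen feed (gN/L/h) enters the nitrate
#' balance as a volumetric source after conversion to nitrate mass. With
#' `conservative_quota = TRUE` the quota additionally loses the nitrogen
#' metabolized into biomass, `+ m_n * v_no3_met` (the flux is non-positive),
#' which closes the nitrogen balance exactly.
#'
#' @param state list with `x`, `c_no3`, `w_chl`, `w_car`, `w_n`.
#' @param fluxes list with `mu` (h^-1), `v_chl`, `v_car`, `v_no3_met`
#'   (mmol/gDw/h) from the lexicographic FBA.
#' @param v_no3 uptake rate (gNO3/gDw/h), see [nitrate_uptake()].
#' @param feed nitrogen feed rate (gN/L/h).
#' @param params model parameters.
#' @param conservative_quota logical, see above.
#' @return named numeric vector of derivatives (per hour).
#' @export
reactor_rhs <- function(state, fluxes, v_no3 = 0, feed = 0, params,
                        conservative_quota = FALSE) {
  mu <- fluxes$mu
  dw_n <- (params$m_n / params$m_no3) * v_no3 - mu * state$w_n
  if (conservative_quota) dw_n <- dw_n + params$m_n * fluxes$v_no3_met
  c(x = mu * state$x,
    c_no3 = -v_no3 * state$x + feed * params$m_no3 / params$m_n,
    w_chl = params$m_chl * fluxes$v_chl - mu * state$w_chl,
    w_car = params$m_car * fluxes$v_car - mu * state$w_car,
    w_n = dw_n)
}

# fast internal regulatory-bounds evaluation (same numbers as
# regulated_bounds(), without the tibble wrapping)
reg_bounds_num <- function(t_h, x, c_no3, w_chl, w_car, w_n, e0, params) {
  k_e <- params$k_e0 * 1000 * w_chl * x
  tau <- k_e * params$l_r
  e_avg <- if (tau < 1e-6) e0 * (1 - tau / 2 + tau^2 / 6)
           else e0 * (1 - exp(-tau)) / tau
  eta <- params$theta_eff * (params$eta1 * w_chl + params$eta0)
  e_x <- params$theta_dim * eta * e_avg / (x * params$l_r)
  psi <- {
    td <- t_h / 24
    tn <- td^params$n_lag
    tn / (params$lambda^params$n_lag + tn)
  }
  gamma <- params$gamma_max * params$k_e / (min(e_avg, params$e_sat) + params$k_e)
  v_chl_lb <- gamma - w_chl / max(w_n, 1e-12)
  en <- e_x^params$n_car
  gen <- params$v_car_max * en / (params$e_x_a^params$n_car + en)
  u <- params$eta_s * (params$alpha1 * e_x + params$alpha0 - w_n)
  gate <- if (u >= 0) 1 / (1 + exp(-u)) else exp(u) / (1 + exp(u))
  v_car_lb <- gen * gate
  v_no3_lb <- min(0, -params$v_no3_met_max *
                    (1 - params$w_n_min / max(w_n, params$w_n_min)))
  list(e_x = e_x, e_avg = e_avg, psi = psi,
       photon = c(-psi * e_x, -psi * e_x),
       no3 = c(psi * v_no3_lb, 0),
       chl = c(psi * v_chl_lb, Inf),
       car = c(psi * v_car_lb, Inf),
       ngam = c(psi * params$ngam, Inf))
}

#' Simulate a batch or fed-batch cultivation
#'
#' Integrates the photobioreactor ODE system with the lexicographic flux
#' balance model solved at every right-hand-side evaluation (classic
#' fourth-order Runge-Kutta, fixed step). Infeasible LPs never abort the
#' simulation: the phase-I elastic relaxation is used and its penalty
#' recorded along the trajectory.
#'
#' @param network a [stoich_network()].
#' @param params model parameters, see [algal_parameters()].
#' @param initial a [reactor_state()]; `NULL` pigment fractions default to
#'   the network biomass composition.
#' @param light incident light program: a constant (umol photons m^-2 s^-1)
#'   or `function(t_h, state)`.
#' @param n_feed nitrogen feed program (gN/L/h): constant or
#'   `function(t_h, state)`; 0 for batch.
#' @param horizon simulated time (h).
#' @param step integration step (h); capped at 0.1 h by default to bound the
#'   kinks the embedded LPs introduce into the right-hand side.
#' @param priorities lexicographic [priority_list()].
#' @param conservative_quota see [reactor_rhs()].
#' @return a `culture_trajectory` tibble: states, resolved fluxes, light
#'   field, feed rates and the phase-I penalty per step. The time-integrated
#'   penalty is available via [culture_penalty()].
#' @examples
#' \donttest{
#' traj <- simulate_culture(toy_network(), algal_parameters("set_I"),
#'                          reactor_state(x = 0.2, c_no3 = 2.37, w_n = 0.08),
#'                          light = 178, horizon = 48, step = 0.5)
#' tail(traj, 3)
#' }
#' @export
simulate_culture <- function(network, params, initial, light, n_feed = 0,
                             horizon, step = 0.1,
                             priorities = default_priorities(network),
                             conservative_quota = FALSE) {
  stopifnot(horizon > 0, step > 0)
  light_fn <- if (is.function(light)) light else function(t, s) light
  feed_fn <- if (is.function(n_feed)) n_feed else function(t, s) n_feed

  if (is.null(initial$w_chl) || is.null(initial$w_car)) {
    comp <- biomass_composition(network, params)
    if (is.null(initial$w_chl)) initial$w_chl <- comp[["w_chl"]]
    if (is.null(initial$w_car)) initial$w_car <- comp[["w_car"]]
  }

  setup <- lex_setup(network, priorities)
  base <- resolve_bounds(network, NULL)
  roles <- network_roles(network)
  j_photon <- match(roles[["photon"]], setup$rxn)
  j_no3 <- match(roles[["nitrate_met"]], setup$rxn)
  j_chl <- match(roles[["chl_acc"]], setup$rxn)
  j_car <- match(roles[["car_acc"]], setup$rxn)
  j_ngam <- match(roles[["ngam"]], setup$rxn)
  j_bio <- match(roles[["biomass"]], setup$rxn)

  deriv <- function(t_h, y) {
    x <- y[1]; c_no3 <- max(y[2], 0); w_chl <- max(y[3], 0)
    w_car <- max(y[4], 0); w_n <- max(y[5], 1e-12)
    st <- list(t = t_h, x = x, c_no3 = c_no3, w_chl = w_chl,
               w_car = w_car, w_n = w_n)
    e0 <- light_fn(t_h, st)
    feed <- feed_fn(t_h, st)
    rb <- reg_bounds_num(t_h, x, c_no3, w_chl, w_car, w_n, e0, params)
    lb <- base$lb; ub <- base$ub
    lb[j_photon] <- rb$photon[1]; ub[j_photon] <- rb$photon[2]
    lb[j_no3] <- rb$no3[1]; ub[j_no3] <- rb$no3[2]
    lb[j_chl] <- rb$chl[1]; ub[j_chl] <- rb$chl[2]
    lb[j_car] <- rb$car[1]; ub[j_car] <- rb$car[2]
    lb[j_ngam] <- rb$ngam[1]; ub[j_ngam] <- rb$ngam[2]
    sol <- lex_run(setup, lb, ub)
    if (sol$status != "optimal") {
      abort(paste0("LP failed (", sol$status, ") at t = ", round(t_h, 3), " h"))
    }
    fl <- list(mu = sol$flux[j_bio], v_chl = sol$flux[j_chl],
               v_car = sol$flux[j_car], v_no3_met = sol$flux[j_no3])
    v_no3 <- params$v_no3_max * c_no3 / (params$k_m + c_no3) *
      max(0, 1 - w_n / params$w_n_max)
    dy <- reactor_rhs(st, fl, v_no3, feed, params, conservative_quota)
    list(dy = dy, fl = fl, v_no3 = v_no3, penalty = sol$penalty,
         e0 = e0, feed = feed, e_x = rb$e_x, e_avg = rb$e_avg)
  }

  n_steps <- ceiling(horizon / step)
  times <- seq(0, by = step, length.out = n_steps + 1L)
  times[n_steps + 1L] <- min(times[n_steps + 1L], horizon)
  rec <- matrix(NA_real_, n_steps + 1L, 16L)
  colnames(rec) <- c("time_h", "x", "c_no3", "w_chl", "w_car", "w_n",
                     "mu", "v_chl", "v_car", "v_no3_met", "v_no3_uptake",
                     "e0", "e_avg", "e_x", "n_feed_rate", "penalty")
  y <- c(initial$x, initial$c_no3, initial$w_chl, initial$w_car, initial$w_n)

  for (i in seq_len(n_steps + 1L)) {
    t_h <- times[i]
    k1 <- deriv(t_h, y)
    rec[i, ] <- c(t_h, y, k1$fl$mu, k1$fl$v_chl, k1$fl$v_car,
                  k1$fl$v_no3_met, k1$v_no3, k1$e0, k1$e_avg, k1$e_x,
                  k1$feed, k1$penalty)
    if (i > n_steps) break
    h <- times[i + 1L] - t_h
    k2 <- deriv(t_h + h / 2, y + h / 2 * k1$dy)
    k3 <- deriv(t_h + h / 2, y + h / 2 * k2$dy)
    k4 <- deriv(t_h + h, y + h * k3$dy)
    y <- y + h / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
    y[2] <- max(y[2], 0)          # nitrate cannot go negative
    y[3:4] <- pmax(y[3:4], 0)
    if (any(!is.finite(y))) {
      abort(paste0("non-finite state after t = ", round(t_h, 3),
                   " h; last valid state: ",
                   paste(round(rec[i, 2:6], 6), collapse = ", ")))
    }
  }

  traj <- as_tibble(as.data.frame(rec))
  theta <- sum(diff(traj$time_h) *
                 (head(traj$penalty, -1) + traj$penalty[-1]) / 2)
  structure(traj,
            class = c("culture_trajectory", class(traj)),
            params = params, step = step,
            conservative_quota = conservative_quota,
            theta = theta)
}

#' Aggregate phase-I penalty of a simulation
#'
#' Time integral of the instantaneous infeasibility penalty along the
#' trajectory; zero for an everywhere-feasible simulation.
#'
#' @param trajectory a `culture_trajectory`.
#' @export
culture_penalty <- function(trajectory) attr(trajectory, "theta")

#' @exportS3Method generics::glance
glance.culture_trajectory <- function(x, ...) {
  tibble(
    horizon_h = max(x$time_h),
    final_x = x$x[nrow(x)],
    max_x = max(x$x),
    max_w_car = max(x$w_car),
    max_beta = max(x$w_car * x$x),
    theta = culture_penalty(x)
  )
}

#' Standard batch cultivation scenarios
#'
#' The calibration/validation conditions: low light nitrogen-replete (`LL`,
#' 178 umol photons m^-2 s^-1, 2.37 gNO3/L), high light (`HL`, 1950, 2.76),
#' high light nitrogen-depleted (`HL_ND`, 1950, 0.07) in the 5 cm light-path
#' reactor, and medium light (`ML`, 250, 2.71) in the 2 cm validation
#' reactor. Inoculum defaults (not part of the printed conditions): 0.1
#' gDw/L from a low-light nitrogen-replete preculture, quota 0.08 gN/gDw,
#' pigment fractions from the network biomass composition.
#'
#' @param name scenario name.
#' @param x0 inoculum biomass (gDw/L).
#' @param w_n0 inoculum nitrogen quota (gN/gDw).
#' @return list with `initial` ([reactor_state()]), `light` (E0), `l_r`
#'   (light path, m) and `horizon` (h).
#' @export
batch_scenario <- function(name = c("LL", "HL", "HL_ND", "ML"),
                           x0 = 0.1, w_n0 = 0.08) {
  name <- match.arg(name)
  cfg <- switch(name,
    LL = list(light = 178, c_no3 = 2.37, l_r = 0.05),
    HL = list(light = 1950, c_no3 = 2.76, l_r = 0.05),
    HL_ND = list(light = 1950, c_no3 = 0.07, l_r = 0.05),
    ML = list(light = 250, c_no3 = 2.71, l_r = 0.02))
  list(initial = reactor_state(x = x0, c_no3 = cfg$c_no3, w_n = w_n0),
       light = cfg$light, l_r = cfg$l_r, horizon = 9 * 24)
}
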