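#' Define a fed-batch feed design
#'
#' Biomass-proportional light after a one-day adaptation phase plus a
#' Hill-type nitrogen feed driven by the internal quota.
#'
#' @param i0 light proportionality factor (umol photons m^-2 s^-1 L/gDw).
#' @param adapt_days duration of the adaptation phase (d).
#' @param adapt_e0 adaptation-phase incident intensity.
#' @param n_d nitrogen feeding factor (gN/L/h).
#' @param hill_n feed Hill coefficient.
#' @param w_n_ref reference quota of the feed law (gN/gDw).
#' @param e0_cap optional saturation cap on the light program (uncapped by
#'   default).
#' @return a `fedbatch_design` list.
#' @export
fedbatch_design <- function(i0 = 3000, adapt_days = 1, adapt_e0 = 100,
                            n_d = 0.02, hill_n = 10, w_n_ref = 0.02,
                            e0_cap = Inf) {
  stopifnot(i0 >= 0, adapt_days >= 0, adapt_e0 >= 0, n_d >= 0, hill_n > 0,
            w_n_ref > 0)
  structure(list(i0 = i0, adapt_days = adapt_days, adapt_e0 = adapt_e0,
                 n_d = n_d, hill_n = hill_n, w_n_ref = w_n_ref,
                 e0_cap = e0_cap),
            class = "fedbatch_design")
}

#' Biomass-proportional light program
#'
#' `E0 = adapt_e0` during the adaptation phase, then `E0 = i0 * x` (a fixed
#' incident light stress per cell while the culture is dilute), optionally
#' capped.
#'
#' @param t_h time since inoculation (h).
#' @param x biomass (gDw/L).
#' @param design a [fedbatch_design()].
#' @export
light_feed <- function(t_h, x, design) {
  stopifnot(all(t_h >= 0), all(x >= 0))
  ifelse(t_h < design$adapt_days * 24, design$adapt_e0,
         pmin(design$i0 * x, design$e0_cap))
}

#' Quota-driven nitrogen feed
#'
#' `N = n_d * r^h / (1 + r^h)` with `r = w_n_ref / w_n`: roughly `n_d/2`
#' when the quota has fallen to the reference and sharply smaller above it.
#'
#' @param w_n nitrogen quota (gN/gDw), positive.
#' @param design a [fedbatch_design()].
#' @return feed rate in gN/L/h, in `(0, n_d)`.
#' @export
nitrogen_feed <- function(w_n, design) {
  if (any(w_n <= 0)) abort("nitrogen_feed: w_n must be positive")
  r <- (design$w_n_ref / w_n)^design$hill_n
  design$n_d * r / (1 + r)
}

#' Feed functions of a design
#'
#' Closes a design over the state so it can be passed to
#' [simulate_culture()].
#'
#' @param design a [fedbatch_design()].
#' @return list with `light(t, state)` and `n_feed(t, state)`.
#' @export
design_feeds <- function(design) {
  list(light = function(t, s) light_feed(t, s$x, design),
       n_feed = function(t, s) nitrogen_feed(s$w_n, design))
}

#' Discretize continuous feed profiles into daily applications
#'
#' Converts the realized continuous input profiles of a simulated run into
#' open-loop daily programs: the light intensity becomes its daily mean and
#' the nitrogen dose is re-emitted either at constant rate over each day or
#' as a short bolus at the start of the day. Daily integrals are preserved
#' exactly (trapezoidal quadrature on the recorded grid).
#'
#' @param trajectory a `culture_trajectory` recording `e0` and
#'   `n_feed_rate`.
#' @param nitrogen_mode `"constant"` or `"bolus"` (dose delivered in the
#'   first `bolus_hours` of each day).
#' @param bolus_hours duration of the bolus window (h).
#' @return list with `light(t, state)`, `n_feed(t, state)` and a `daily`
#'   tibble (`day`, `e0_mean`, `n_dose` in gN/L).
#' @export
discretize_daily <- function(trajectory, nitrogen_mode = c("constant", "bolus"),
                             bolus_hours = 1) {
  nitrogen_mode <- match.arg(nitrogen_mode)
  tt <- trajectory$time_h
  day <- floor(tt / 24 - 1e-12)
  day[1] <- 0
  days <- sort(unique(pmax(day, 0)))
  trap <- function(t, v, a, b) {
    # integral of the piecewise-linear interpolant of (t, v) over [a, b]
    if (b <= a) return(0)
    grid <- sort(unique(c(a, b, t[t > a & t < b])))
    vv <- approx(t, v, xout = grid, rule = 2)$y
    sum(diff(grid) * (head(vv, -1) + vv[-1]) / 2)
  }
  daily <- purrr::map_dfr(days, function(d) {
    a <- d * 24; b <- min((d + 1) * 24, max(tt))
    tibble(day = d,
           e0_mean = trap(tt, trajectory$e0, a, b) / (b - a),
           n_dose = trap(tt, trajectory$n_feed_rate, a, b))
  })
  light <- function(t, s) {
    d <- min(max(floor(t / 24), 0), max(daily$day))
    daily$e0_mean[match(d, daily$day)]
  }
  n_feed <- if (nitrogen_mode == "constant") {
    function(t, s) {
      d <- min(max(floor(t / 24), 0), max(daily$day))
      daily$n_dose[match(d, daily$day)] / 24
    }
  } else {
    function(t, s) {
      d <- min(max(floor(t / 24), 0), max(daily$day))
      if (t - d * 24 < bolus_hours) daily$n_dose[match(d, daily$day)] / bolus_hours
      else 0
    }
  }
  list(light = light, n_feed = n_feed, daily = daily)
}

#' Two-factor fed-batch design scan
#'
#' Simulates the fed-batch design over a rectangular grid of inoculum
#' nitrogen status (initial quota or initial nitrate, see `inoculum_axis`)
#' and nitrogen feeding factor, and reports the maxima over the horizon of
#' biomass, carotene fraction and carotene concentration
#' `beta = w_car * x`.
#'
#' @param network a [stoich_network()].
#' @param params model parameters.
#' @param inoculum values of the inoculum axis.
#' @param n_d values of the nitrogen feeding factor (gN/L/h).
#' @param design base [fedbatch_design()] (its `n_d` is overridden by the
#'   grid).
#' @param initial baseline [reactor_state()].
#' @param inoculum_axis `"w_n"` (initial quota) or `"c_no3"` (initial
#'   nitrate).
#' @param horizon fed-batch duration (h), default 9 days.
#' @param step integration step (h).
#' @return a `design_scan` tibble: `inoculum`, `n_d`, `max_x`, `max_w_car`,
#'   `max_beta`, `theta`, `error` (NA on success); failed cells are
#'   recorded and the scan continues.
#' @export
design_scan <- function(network, params, inoculum, n_d,
                        design = fedbatch_design(),
                        initial = reactor_state(x = 0.2, c_no3 = 0.08,
                                                w_n = 0.08),
                        inoculum_axis = c("w_n", "c_no3"),
                        horizon = 9 * 24, step = 0.25) {
  inoculum_axis <- match.arg(inoculum_axis)
  grid <- tidyr::expand_grid(inoculum = inoculum, n_d = n_d)
  cells <- purrr::pmap_dfr(grid, function(inoculum, n_d) {
    st <- initial
    if (inoculum_axis == "w_n") st$w_n <- inoculum else st$c_no3 <- inoculum
    des <- design; des$n_d <- n_d
    feeds <- design_feeds(des)
    res <- tryCatch({
      traj <- simulate_culture(network, params, st, feeds$light,
                               n_feed = feeds$n_feed, horizon = horizon,
                               step = step)
      tibble(inoculum = inoculum, n_d = n_d,
             max_x = max(traj$x), max_w_car = max(traj$w_car),
             max_beta = max(traj$w_car * traj$x),
             final_w_n = traj$w_n[nrow(traj)],
             theta = culture_penalty(traj), error = NA_character_)
    }, error = function(e) {
      tibble(inoculum = inoculum, n_d = n_d, max_x = NA_real_,
             max_w_car = NA_real_, max_beta = NA_real_,
             final_w_n = NA_real_, theta = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  structure(cells, class = c("design_scan", class(cells)),
            inoculum_axis = inoculum_axis)
}

#' Improvement factors of an optimized fed-batch run
#'
#' Report utility: given a performance table with one row per property and
#' columns for the standard batch and the optimized fed-batch, computes the
#' optimized/standard ratio per property. The package ships the published
#' performance table of the experimentally realized design as
#' `system.file("extdata", "fedbatch_performance.csv", package =
#' "phycoflux")`.
#'
#' @param performance tibble/data frame with columns `property`, `unit`,
#'   `standard_batch`, `optimized_fed_batch`.
#' @return tibble with an added `factor` column.
#' @examples
#' perf <- readr::read_csv(system.file("extdata", "fedbatch_performance.csv",
#'                                     package = "phycoflux"),
#'                         show_col_types = FALSE)
#' fedbatch_improvement(perf)
#' @export
fedbatch_improvement <- function(performance) {
  stopifnot(all(c("property", "standard_batch", "optimized_fed_batch")
                %in% names(performance)))
  performance %>%
    mutate(factor = .data$optimized_fed_batch / .data$standard_batch)
}
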