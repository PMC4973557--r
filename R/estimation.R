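#' Weighted residual sum of squares
#'
#' `chi2 = sum_k sum_i (y_k(t_i) - yhat_k(t_i))^2 / sigma_ki^2` over all
#' measured outputs and time points; model values are interpolated linearly
#' onto the measurement times.
#'
#' @param dataset tibble with columns `output` (one of `x`, `c_no3`,
#'   `w_chl`, `w_car`), `time_h`, `value`, `sd` (> 0).
#' @param trajectory a `culture_trajectory` covering all measurement times.
#' @return non-negative scalar.
#' @export
chi_square <- function(dataset, trajectory) {
  stopifnot(all(c("output", "time_h", "value", "sd") %in% names(dataset)))
  if (any(dataset$sd <= 0)) abort("all measurement standard deviations must be positive")
  bad <- dataset$time_h < min(trajectory$time_h) - 1e-9 |
    dataset$time_h > max(trajectory$time_h) + 1e-9
  if (any(bad)) {
    abort(paste0("measurement time(s) outside the simulated horizon: ",
                 paste(unique(dataset$time_h[bad]), collapse = ", ")))
  }
  tot <- 0
  for (out in unique(dataset$output)) {
    if (!out %in% names(trajectory)) {
      abort(paste0("dataset output '", out, "' is not a trajectory column"))
    }
    d <- dataset[dataset$output == out, ]
    yhat <- approx(trajectory$time_h, trajectory[[out]], xout = d$time_h,
                   rule = 1)$y
    tot <- tot + sum(((d$value - yhat) / d$sd)^2)
  }
  tot
}

#' Define a parameter-estimation problem
#'
#' Penalized least squares: `J(p) = chi2(p) + alpha * Theta(p)^2`, where
#' `Theta` is the aggregate phase-I penalty of the DFBA simulation at `p`.
#' Several scenarios are fitted jointly by summing their chi-square
#' contributions with equal weight.
#'
#' @param network a [stoich_network()].
#' @param params baseline [algal_parameters()]; fixed values for everything
#'   not in `free`.
#' @param data measurement tibble with columns `scenario`, `output`,
#'   `time_h`, `value`, `sd`.
#' @param scenarios named list (names matching `data$scenario`); each
#'   element a list with `initial`, `light`, `horizon` (and optionally
#'   `n_feed`).
#' @param free character vector of free parameter names.
#' @param lower,upper box bounds for the free parameters (same order).
#' @param alpha penalty weight (default 1e6: large enough that any
#'   infeasible simulation is dominated).
#' @param step integration step used during fitting (h).
#' @return an `estimation_problem` list.
#' @export
estimation_problem <- function(network, params, data, scenarios, free,
                               lower, upper, alpha = 1e6, step = 0.5) {
  stopifnot(length(free) == length(lower), length(free) == length(upper),
            all(free %in% names(params)), alpha >= 0,
            all(is.finite(lower)), all(is.finite(upper)))
  miss <- setdiff(unique(data$scenario), names(scenarios))
  if (length(miss)) abort(paste0("no scenario definition for: ",
                                 paste(miss, collapse = ", ")))
  structure(list(network = network, params = params, data = data,
                 scenarios = scenarios, free = free, lower = lower,
                 upper = upper, alpha = alpha, step = step),
            class = "estimation_problem")
}

#' Penalized estimation cost at a parameter vector
#'
#' @param problem an [estimation_problem()].
#' @param par numeric vector of free-parameter values (order of
#'   `problem$free`).
#' @return list with `J`, `chi2`, `theta`; a failed simulation returns
#'   `J = Inf` with the diagnostic attached as attribute `"error"`.
#' @export
penalized_cost <- function(problem, par) {
  p <- problem$params
  for (i in seq_along(problem$free)) p[[problem$free[i]]] <- par[i]
  chi2 <- 0
  theta <- 0
  for (sc in unique(problem$data$scenario)) {
    def <- problem$scenarios[[sc]]
    traj <- tryCatch(
      simulate_culture(problem$network, p, def$initial, def$light,
                       n_feed = def$n_feed %||% 0,
                       horizon = def$horizon, step = problem$step),
      error = function(e) e)
    if (inherits(traj, "error")) {
      return(structure(list(J = Inf, chi2 = NA_real_, theta = NA_real_),
                       error = conditionMessage(traj)))
    }
    chi2 <- chi2 + chi_square(problem$data[problem$data$scenario == sc, ], traj)
    theta <- theta + culture_penalty(traj)
  }
  list(J = chi2 + problem$alpha * theta^2, chi2 = chi2, theta = theta)
}

#' Estimate model parameters by differential evolution
#'
#' Minimizes the penalized cost with a derivative-free evolutionary
#' optimizer (differential evolution); the estimation objective is
#' non-smooth because of the embedded linear programs, so gradient-based
#' methods are not offered. Deterministic for a fixed seed; no global
#' optimality is claimed.
#'
#' @param problem an [estimation_problem()].
#' @param seed integer RNG seed.
#' @param np population size (default `10 * n_free`).
#' @param itermax number of generations.
#' @param polish iterations of a derivative-free Nelder-Mead refinement of
#'   the best population member (0 to disable); the refinement stays inside
#'   the box by clamping.
#' @return an `estimation_result` with the best parameters, `J`, `chi2`,
#'   `theta`, the optimizer trace and the seed. Use [tidy()] / [glance()]
#'   to extract tidy summaries.
#' @export
estimate_parameters <- function(problem, seed = 1, np = NULL, itermax = 20,
                                polish = 60) {
  n <- length(problem$free)
  if (is.null(np)) np <- 10L * n
  set.seed(seed)
  fn <- function(par) {
    par <- pmin(pmax(par, problem$lower), problem$upper)
    res <- penalized_cost(problem, par)
    if (!is.finite(res$J)) 1e12 else res$J
  }
  ctrl <- DEoptim::DEoptim.control(NP = np, itermax = itermax, trace = FALSE)
  fit <- withCallingHandlers(
    DEoptim::DEoptim(fn, lower = problem$lower, upper = problem$upper,
                     control = ctrl),
    warning = function(w) {
      # optimizer's population-size advisory; np is an explicit choice here
      if (grepl("'NP'", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  best <- as.numeric(fit$optim$bestmem)
  if (polish > 0 && n >= 2) {
    nm <- stats::optim(best, fn, method = "Nelder-Mead",
                       control = list(maxit = polish, reltol = 1e-8))
    if (nm$value <= fit$optim$bestval) best <- nm$par
  }
  best <- pmin(pmax(best, problem$lower), problem$upper)
  names(best) <- problem$free
  at_best <- penalized_cost(problem, best)
  structure(list(par = best, J = at_best$J, chi2 = at_best$chi2,
                 theta = at_best$theta,
                 feasible = is.finite(at_best$theta) && at_best$theta <= 1e-6,
                 trace = as.numeric(fit$member$bestvalit),
                 seed = seed, problem = problem),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result>  J =", format(x$J), " chi2 =", format(x$chi2),
      " theta =", format(x$theta), if (!x$feasible) " [infeasible!]", "\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.estimation_result <- function(x, ...) {
  tibble(parameter = names(x$par), estimate = unname(x$par),
         lower = x$problem$lower, upper = x$problem$upper)
}

#' @exportS3Method generics::glance
glance.estimation_result <- function(x, ...) {
  tibble(J = x$J, chi2 = x$chi2, theta = x$theta, feasible = x$feasible,
         generations = length(x$trace), seed = x$seed)
}
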