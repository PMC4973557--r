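#' Generate a synthetic pseudo-experiment
#'
#' Simulates the "true" trajectory for a scenario, samples the four measured
#' outputs (biomass, extracellular nitrate, chlorophyll fraction,
#' beta-carotene fraction) on a measurement schedule and adds independent
#' Gaussian noise with output-specific relative standard deviation. The
#' attached `sd` column carries the nominal standard deviation used for the
#' noise, so the dataset plugs directly into [chi_square()]. Values driven
#' negative by noise are truncated at zero (a message reports how many).
#'
#' @param network a [stoich_network()] (ignored when `trajectory` is given).
#' @param params model parameters.
#' @param scenario list with `initial`, `light`, `horizon` (and optional
#'   `n_feed`).
#' @param times measurement times (h); default daily sampling over the
#'   horizon.
#' @param rel_sd relative standard deviation per output; a single number or
#'   a named vector over `c("x", "c_no3", "w_chl", "w_car")`. Also recorded
#'   as the `sd` column (the weights used in estimation).
#' @param noise logical; `FALSE` returns the exact trajectory samples
#'   (with the nominal `sd` column still attached), useful for
#'   recovery-oracle studies.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param step integration step (h).
#' @param trajectory optionally a precomputed truth trajectory (used
#'   instead of simulating; convenient for noise-replication studies).
#' @return tibble with columns `scenario`, `output`, `time_h`, `value`,
#'   `sd`, `truth`.
#' @export
generate_pseudo_experiment <- function(network, params, scenario,
                                       times = NULL, rel_sd = 0.05,
                                       noise = TRUE, seed = 1, step = 0.25,
                                       trajectory = NULL) {
  outputs <- c("x", "c_no3", "w_chl", "w_car")
  if (length(rel_sd) == 1L) rel_sd <- setNames(rep(rel_sd, 4L), outputs)
  stopifnot(all(outputs %in% names(rel_sd)), all(rel_sd >= 0))
  if (is.null(trajectory)) {
    trajectory <- simulate_culture(network, params, scenario$initial,
                                   scenario$light,
                                   n_feed = scenario$n_feed %||% 0,
                                   horizon = scenario$horizon, step = step)
  }
  if (is.null(times)) times <- seq(0, max(trajectory$time_h), by = 24)
  if (any(times < 0 | times > max(trajectory$time_h))) {
    abort("measurement times must lie within the simulated horizon")
  }
  set.seed(seed)
  rows <- purrr::map_dfr(outputs, function(out) {
    truth <- approx(trajectory$time_h, trajectory[[out]], xout = times)$y
    sd <- pmax(rel_sd[[out]] * abs(truth), 1e-12)
    eps <- if (noise) rnorm(length(times), 0, sd) else 0
    tibble(scenario = scenario$name %||% "scenario",
           output = out, time_h = times,
           value = truth + eps, sd = sd, truth = truth)
  })
  n_neg <- sum(rows$value < 0)
  if (n_neg > 0) {
    message(n_neg, " noisy value(s) truncated at 0")
    rows$value <- pmax(rows$value, 0)
  }
  rows
}

# ---------------------------------------------------------------------------
# CSV round trips with a versioned schema header
# ---------------------------------------------------------------------------

schema_header <- function(kind) paste0("# phycoflux ", kind, " v1")

write_versioned_csv <- function(df, path, kind) {
  # 17 significant digits: doubles survive the round trip bit-exactly
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sub("^NA$", "", sprintf("%.17g", col)))
  readr::write_lines(schema_header(kind), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_versioned_csv <- function(path, kind) {
  first <- readr::read_lines(path, n_max = 1)
  if (!identical(first, schema_header(kind))) {
    abort(paste0("file is not a phycoflux ", kind,
                 " v1 CSV (header: '", first, "')"))
  }
  # base R parser: correctly rounded doubles, so the round trip is bit-exact
  out <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  out[] <- lapply(out, function(col) if (is.integer(col)) as.double(col) else col)
  as_tibble(out)
}

#' Trajectory, dataset and scan CSV input/output
#'
#' Comma-separated, `.` decimal, UTF-8, with a one-line versioned schema
#' header (`# phycoflux <kind> v1`); numeric columns round-trip at full
#' double precision.
#'
#' @param trajectory,dataset,scan object to write.
#' @param path file path.
#' @name phycoflux-io
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write_versioned_csv(as_tibble(trajectory), path, "trajectory")
}

#' @rdname phycoflux-io
#' @export
read_trajectory_csv <- function(path) {
  out <- read_versioned_csv(path, "trajectory")
  class(out) <- c("culture_trajectory", class(out))
  out
}

#' @rdname phycoflux-io
#' @export
write_dataset_csv <- function(dataset, path) {
  write_versioned_csv(dataset, path, "dataset")
}

#' @rdname phycoflux-io
#' @export
read_dataset_csv <- function(path) read_versioned_csv(path, "dataset")

#' @rdname phycoflux-io
#' @export
write_scan_csv <- function(scan, path) {
  write_versioned_csv(as_tibble(scan), path, "design-scan")
}

#' @rdname phycoflux-io
#' @export
read_scan_csv <- function(path) read_versioned_csv(path, "design-scan")

#' Scenario YAML input/output
#'
#' A cultivation scenario (initial state, constant incident light, horizon,
#' optional constant nitrogen feed) serialized as YAML.
#'
#' @param scenario list with `initial` ([reactor_state()]), `light`,
#'   `horizon`, optional `n_feed`, `name`.
#' @param path file path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(list(
    name = scenario$name %||% "scenario",
    light = scenario$light, horizon = scenario$horizon,
    n_feed = scenario$n_feed %||% 0,
    initial = unclass(scenario$initial)), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0("malformed YAML: ",
                                                   conditionMessage(e))))
  init <- doc$initial
  st <- reactor_state(x = init$x, c_no3 = init$c_no3, w_n = init$w_n,
                      w_chl = init$w_chl, w_car = init$w_car,
                      t = init$t %||% 0)
  list(name = doc$name, initial = st, light = doc$light,
       horizon = doc$horizon, n_feed = doc$n_feed %||% 0)
}
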