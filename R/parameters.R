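#' Model parameters for the pigment-accumulation DFBA model
#'
#' Returns the complete parameter set: regulatory parameters (two presets,
#' the initial batch-calibrated set `"set_I"` and the fed-batch refined
#' `"set_II"`), physical constants, and reactor geometry. Any entry can be
#' overridden through `...`.
#'
#' Units: quotas and pigment fractions in g per g dry weight; fluxes in
#' mmol per gDw per h except the nitrate uptake `v_no3_max` (g NO3 per gDw
#' per h); irradiance in umol photons m^-2 s^-1; the biomass-specific light
#' intensity `e_x` in mmol photons per gDw per h; `lambda` in days;
#' `k_e0` in m^2 per g chlorophyll; `l_r` in m; molar masses in g per mmol.
#'
#' @param set `"set_I"` or `"set_II"`.
#' @param ... named overrides, e.g. `l_r = 0.02` for a 2 cm light path.
#' @return an `algal_parameters` list.
#' @examples
#' p <- algal_parameters("set_II")
#' p$alpha1 * 32 + p$alpha0   # nitrogen-quota stress threshold at e_x = 32
#' @export
algal_parameters <- function(set = c("set_I", "set_II"), ...) {
  set <- match.arg(set)
  base <- list(
    # regulatory / kinetic parameters (preset-dependent)
    alpha0 = 4.2e-2,        # offset, carotene induction gate (-)
    alpha1 = 3.47e-5,       # gain, carotene induction gate (per e_x unit)
    gamma_max = 0.69,       # max chlorophyll:nitrogen ratio (gChl/gN)
    eta0 = 8e-4,            # offset, light-use efficiency (-)
    eta1 = 3.2,             # gain on chlorophyll fraction (-)
    lambda = 1.37,          # lag-phase duration (d)
    w_n_min = 0.021,        # minimal nitrogen quota (gN/gDw)
    w_n_max = 0.101,        # maximal nitrogen quota (gN/gDw)
    e_x_a = 32,             # critical specific light for carotene (mmol/gDw/h)
    e_sat = 75.5,           # saturation irradiance for gamma (umol/m2/s)
    k_e = 12.5,             # gamma inhibition constant (umol/m2/s)
    k_m = 0.0013,           # Michaelis constant, nitrate uptake (gNO3/L)
    n_car = 4,              # Hill exponent, carotene generation (-)
    ngam = 0.183,           # non-growth ATP maintenance (mmol/gDw/h)
    v_car_max = 3e-3,       # max carotene synthesis flux (mmol/gDw/h)
    v_no3_max = 0.0309,     # max nitrate uptake (gNO3/gDw/h)
    v_no3_met_max = 0.19,   # max nitrate metabolization (mmol/gDw/h)
    theta_eff = 0.0375,     # photon efficiency factor (-)
    theta_dim = 3.6,        # unit conversion for e_x (L/g)
    eta_s = 4000,           # gate smoothing factor (-)
    # fixed constants
    n_lag = 4,              # lag Hill coefficient (-)
    k_e0 = 11.5,            # chlorophyll absorption coefficient (m2/gChl)
    l_r = 0.05,             # reactor light path (m)
    m_chl = 0.8935,         # chlorophyll molar mass (g/mmol)
    m_car = 0.53688,        # beta-carotene molar mass (g/mmol)
    m_n = 0.014007,         # nitrogen molar mass (g/mmol)
    m_no3 = 0.062005        # nitrate molar mass (g/mmol)
  )
  if (set == "set_II") {
    base <- modifyList(base, list(
      alpha0 = 6.5e-2, alpha1 = 7e-5, gamma_max = 0.75, eta0 = 0,
      e_x_a = 420, n_car = 2, v_car_max = 18e-3, eta_s = 40))
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown)) {
      abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    base <- modifyList(base, over)
  }
  validate_parameters(structure(base, class = "algal_parameters", set = set))
}

validate_parameters <- function(p) {
  num <- unlist(p[setdiff(names(p), character(0))])
  if (any(!is.finite(num)) || any(num < 0)) {
    abort("all model parameters must be finite and non-negative")
  }
  if (p$w_n_min >= p$w_n_max) abort("w_n_min must be below w_n_max")
  if (p$k_e <= 0) abort("k_e must be positive")
  p
}

#' @export
print.algal_parameters <- function(x, ...) {
  cat("<algal_parameters> preset:", attr(x, "set"), "\n")
  print(tibble(parameter = names(x), value = unlist(x)), n = length(x))
  invisible(x)
}

#' Write / read model parameters as YAML
#'
#' The full set round-trips losslessly, including the preset tag.
#'
#' @param params an [algal_parameters()] object.
#' @param path file path.
#' @export
write_parameters_yaml <- function(params, path) {
  yaml::write_yaml(c(list(preset = attr(params, "set") %||% "custom"),
                     unclass(params)), path)
  invisible(path)
}

#' @rdname write_parameters_yaml
#' @export
read_parameters_yaml <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0("malformed YAML: ",
                                                   conditionMessage(e))))
  preset <- doc$preset %||% "custom"
  doc$preset <- NULL
  validate_parameters(structure(doc, class = "algal_parameters", set = preset))
}
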