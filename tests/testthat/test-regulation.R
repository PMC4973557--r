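# Regulatory bound models: frozen arithmetic values, limits, monotonicity.

test_that("optical depth follows the chlorophyll concentration", {
  expect_equal(optical_depth(0, 1, PSET1), 0)
  expect_equal(optical_depth(0.02, 1, PSET1), 11.5 * 20)   # g/L -> g/m3
  expect_equal(optical_depth(0.02, 2, PSET1), 2 * optical_depth(0.02, 1, PSET1))
  expect_error(optical_depth(-0.01, 1, PSET1), ">= 0")
})

test_that("average irradiance matches quadrature of the attenuated field", {
  expect_equal(average_irradiance(100, 0, 0.05), 100)       # transparent
  expect_equal(average_irradiance(0, 30, 0.05), 0)
  # closed form against numerical quadrature of the Lambert-Beer profile
  quad <- function(e0, k_e, l_r)
    stats::integrate(function(z) e0 * exp(-k_e * z), 0, l_r,
                     rel.tol = 1e-12)$value / l_r
  expect_equal(average_irradiance(100, 100, 0.05), 20 * (1 - exp(-5)),
               tolerance = 1e-12)
  expect_equal(average_irradiance(100, 100, 0.05), quad(100, 100, 0.05),
               tolerance = 1e-10)
  # continuity through the series branch at k_e -> 0
  for (k_e in 10^seq(-9, 2, by = 1)) {
    expect_equal(average_irradiance(250, k_e, 0.05), quad(250, k_e, 0.05),
                 tolerance = 1e-8)
  }
  # non-increasing in the optical depth
  ks <- seq(0, 400, by = 10)
  expect_true(all(diff(average_irradiance(500, ks, 0.05)) <= 0))
})

test_that("light-use efficiency is affine in the chlorophyll fraction", {
  expect_equal(light_efficiency(0, PSET1), 0.0375 * 8e-4)
  expect_equal(light_efficiency(0, PSET2), 0)
  expect_equal(light_efficiency(0.03, PSET1), 0.0375 * (3.2 * 0.03 + 8e-4))
})

test_that("biomass-specific light intensity follows the stated convention", {
  p <- algal_parameters("set_I", l_r = 0.05)
  expect_equal(specific_light_intensity(0, 0.003, 1, p), 0)
  expect_equal(specific_light_intensity(1000, 0.00243, 1, p),
               3.6 * 0.00243 * 1000 / 0.05)
  expect_equal(specific_light_intensity(500, 0.004, 1, p),
               2 * specific_light_intensity(500, 0.002, 1, p))
  expect_error(specific_light_intensity(100, 0.003, 0, p), "positive")
})

test_that("chlorophyll:nitrogen setpoint is an inhibition curve with saturation", {
  expect_equal(chl_nitrogen_ratio(0, PSET1), PSET1$gamma_max)
  expect_equal(chl_nitrogen_ratio(PSET1$k_e, PSET1), PSET1$gamma_max / 2)
  plateau <- PSET1$gamma_max * PSET1$k_e / (PSET1$e_sat + PSET1$k_e)
  expect_equal(chl_nitrogen_ratio(75.5, PSET1), plateau)
  expect_equal(chl_nitrogen_ratio(5000, PSET1), plateau)   # capped argument
  es <- seq(0, 300, by = 5)
  expect_true(all(diff(chl_nitrogen_ratio(es, PSET1)) <= 0))
})

test_that("chlorophyll accumulation bound tracks the setpoint ratio", {
  expect_equal(chlorophyll_flux_lb(0.02, 0.1, 0.2), 0)
  expect_equal(chlorophyll_flux_lb(0.02, 0.1, 0.098), 0.098 - 0.2)
  expect_equal(chlorophyll_flux_lb(0.01, 0.1, 0.69), 0.59)
  expect_error(chlorophyll_flux_lb(0.02, 0, 0.1), "positive")
})

test_that("the logistic smoothing step has its stated identities", {
  expect_equal(smooth_step(0, 40), 0.5)
  expect_equal(smooth_step(1e6, 40), 1)
  expect_equal(smooth_step(-1e6, 40), 0)
  expect_equal(smooth_step(0.01, 40), 1 / (1 + exp(-0.4)))
  u <- seq(-2, 2, by = 0.05)
  expect_equal(smooth_step(u, 7) + smooth_step(-u, 7), rep(1, length(u)))
  expect_true(all(diff(smooth_step(u, 7)) > 0))
  # no overflow at extreme arguments
  expect_false(any(is.nan(smooth_step(c(-1e8, 1e8), 4000))))
})

test_that("carotene generation is a Hill function of specific light", {
  expect_equal(carotene_generation_lb(0, PSET2), 0)
  expect_equal(carotene_generation_lb(PSET2$e_x_a, PSET2), PSET2$v_car_max / 2)
  expect_equal(carotene_generation_lb(32, PSET2),
               0.018 * 32^2 / (420^2 + 32^2))
  es <- seq(0, 2000, by = 25)
  expect_true(all(diff(carotene_generation_lb(es, PSET2)) >= 0))
})

test_that("the carotene bound gates on the nitrogen quota", {
  thr <- carotene_quota_threshold(32, PSET2)
  expect_equal(thr, 7e-5 * 32 + 6.5e-2)
  # exactly half the generation value at the threshold quota
  expect_equal(carotene_flux_lb(32, thr, PSET2),
               carotene_generation_lb(32, PSET2) / 2)
  # nitrogen-replete, well-lit cells do not synthesize
  expect_lt(carotene_flux_lb(32, thr + 0.5, PSET2), 1e-10)
})

test_that("nitrate metabolization shuts down at the minimal quota", {
  expect_equal(nitrate_metabolization_lb(PSET1$w_n_min, PSET1), 0)
  expect_equal(nitrate_metabolization_lb(1e6, PSET1), -0.19, tolerance = 1e-4)
  expect_equal(nitrate_metabolization_lb(2 * PSET1$w_n_min, PSET1), -0.19 / 2)
  expect_warning(out <- nitrate_metabolization_lb(0.01, PSET1), "clamped")
  expect_equal(out, 0)
  ws <- seq(PSET1$w_n_min, 0.101, by = 0.002)
  expect_true(all(diff(nitrate_metabolization_lb(ws, PSET1)) <= 0))
})

test_that("the lag factor rises as a Hill function of days", {
  expect_equal(lag_factor(0, PSET1), 0)
  expect_equal(lag_factor(PSET1$lambda, PSET1), 0.5)
  expect_equal(lag_factor(2 * PSET1$lambda, PSET1), 16 / 17)
  ts <- seq(0, 10, by = 0.1)
  expect_true(all(diff(lag_factor(ts, PSET1)) >= 0))
})

test_that("the synthesis-rate surface has the expected qualitative shape", {
  # non-increasing in the quota, non-decreasing in specific light
  e_grid <- seq(0, 1500, length.out = 25)
  w_grid <- seq(0.021, 0.101, length.out = 25)
  surf <- outer(e_grid, w_grid,
                function(e, w) carotene_flux_lb(e, w, PSET1))
  expect_true(all(apply(surf, 1, function(r) all(diff(r) <= 1e-12))))
  expect_true(all(apply(surf, 2, function(cl) all(diff(cl) >= -1e-12))))
})

test_that("regulated bounds compose the constituent models", {
  st_ll <- list(t = 5 * 24, x = 0.3, c_no3 = 2, w_chl = 0.01, w_car = 0.001,
                w_n = 0.095)
  rb <- regulated_bounds(st_ll, 50, PSET1, toy)
  psi <- attr(rb, "psi")
  lf <- attr(rb, "light")
  # photon exchange pinned to the signed specific light intensity
  expect_equal(rb$lb[rb$reaction == "EX_photon"], -psi * lf$e_x)
  expect_equal(rb$ub[rb$reaction == "EX_photon"], -psi * lf$e_x)
  # nitrogen-replete, low light per cell: no carotene, chlorophyll forced up
  expect_lt(rb$lb[rb$reaction == "ACC_car"], 1e-8)
  expect_gt(rb$lb[rb$reaction == "ACC_chl"], 0)
  expect_equal(rb$ub[rb$reaction == "EX_no3"], 0)
  expect_equal(rb$lb[rb$reaction == "NGAM"], psi * PSET1$ngam)

  # full dormancy at inoculation
  st0 <- utils::modifyList(st_ll, list(t = 0))
  rb0 <- regulated_bounds(st0, 50, PSET1, toy)
  expect_equal(rb0$lb[rb0$reaction == "EX_photon"], 0)
  expect_equal(rb0$lb[rb0$reaction == "NGAM"], 0)

  # starved and bright: carotene bound near the lag-scaled generation term
  st_s <- list(t = 6 * 24, x = 0.3, c_no3 = 0, w_chl = 0.004, w_car = 0.02,
               w_n = 0.0215)
  rb_s <- regulated_bounds(st_s, 1950, PSET1, toy)
  lf_s <- attr(rb_s, "light")
  psi_s <- attr(rb_s, "psi")
  expect_equal(rb_s$lb[rb_s$reaction == "ACC_car"],
               psi_s * carotene_generation_lb(lf_s$e_x, PSET1),
               tolerance = 1e-6)
  expect_gt(rb_s$lb[rb_s$reaction == "EX_no3"], -0.005)   # ~ [0, 0]
  # agreement with the fast path used inside the integrator
  fast <- phycoflux:::reg_bounds_num(st_s$t, st_s$x, st_s$c_no3, st_s$w_chl,
                                     st_s$w_car, st_s$w_n, 1950, PSET1)
  expect_equal(rb_s$lb[rb_s$reaction == "ACC_chl"], fast$chl[1])
  expect_equal(rb_s$lb[rb_s$reaction == "EX_photon"], fast$photon[1])
})
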