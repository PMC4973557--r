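# Droop-quota reactor dynamics with the embedded flux balance model.

test_that("nitrate uptake kinetics hit their half-saturation identities", {
  expect_equal(nitrate_uptake(PSET1$k_m, 0, PSET1), 0.0309 / 2)
  expect_equal(nitrate_uptake(1, PSET1$w_n_max, PSET1), 0)
  expect_equal(nitrate_uptake(100, PSET1$w_n_max / 2, PSET1), 0.0309 / 2,
               tolerance = 1e-4)
  expect_warning(out <- nitrate_uptake(1, 0.2, PSET1), "clamped")
  expect_equal(out, 0)
})

test_that("the right-hand side reproduces the printed balance structure", {
  st <- list(x = 0.5, c_no3 = 1, w_chl = 0.02, w_car = 0.002, w_n = 0.05)
  quiet <- reactor_rhs(st, list(mu = 0, v_chl = 0, v_car = 0, v_no3_met = 0),
                       v_no3 = 0, feed = 0, params = PSET1)
  expect_equal(unname(quiet), rep(0, 5))
  # growth without synthesis dilutes every fraction at rate mu
  dil <- reactor_rhs(st, list(mu = 0.05, v_chl = 0, v_car = 0,
                              v_no3_met = 0), 0, 0, PSET1)
  expect_equal(dil[["w_chl"]], -0.05 * st$w_chl)
  expect_equal(dil[["w_car"]], -0.05 * st$w_car)
  expect_equal(dil[["w_n"]], -0.05 * st$w_n)
  expect_equal(dil[["x"]], 0.05 * st$x)
  # uptake feeds the quota with the molar-mass conversion
  up <- reactor_rhs(st, list(mu = 0, v_chl = 0, v_car = 0, v_no3_met = 0),
                    v_no3 = 0.01, feed = 0, params = PSET1)
  expect_equal(up[["w_n"]], PSET1$m_n / PSET1$m_no3 * 0.01)
  expect_equal(up[["c_no3"]], -0.01 * st$x)
  # fed-batch source term in nitrate mass
  fd <- reactor_rhs(st, list(mu = 0, v_chl = 0, v_car = 0, v_no3_met = 0),
                    0, feed = 0.002, params = PSET1)
  expect_equal(fd[["c_no3"]], 0.002 * PSET1$m_no3 / PSET1$m_n)
})

test_that("trajectory slopes are consistent with the right-hand side", {
  st <- reactor_state(x = 0.1, c_no3 = 0.5, w_n = 0.08)
  tr <- simulate_culture(toy, PSET1, st, 178, horizon = 36, step = 0.1)
  # central finite differences on the interior grid against mu * x
  i <- seq(5, nrow(tr) - 4)
  dxdt <- (tr$x[i + 1] - tr$x[i - 1]) / (tr$time_h[i + 1] - tr$time_h[i - 1])
  expect_lt(max(abs(dxdt - tr$mu[i] * tr$x[i])), 5e-4 * max(tr$x))
})

test_that("a closed dark reactor is quiescent and conserves nitrogen", {
  st <- reactor_state(x = 0.5, c_no3 = 0.1, w_n = 0.05)
  tr <- simulate_culture(toy, PSET1, st, 0, horizon = 48, step = 0.5,
                         conservative_quota = TRUE)
  expect_lt(max(abs(tr$x - 0.5)) / 0.5, 1e-6)        # mu = 0, no growth
  total_n <- tr$x * tr$w_n + PSET1$m_n / PSET1$m_no3 * tr$c_no3
  expect_lt(max(abs(total_n - total_n[1])) / total_n[1], 1e-9)
})

test_that("batch nitrogen bookkeeping closes within 1 percent over 9 days", {
  sc <- batch_scenario("LL")
  tr <- simulate_culture(toy, PSET1, sc$initial, sc$light,
                         horizon = sc$horizon, step = 0.1,
                         conservative_quota = TRUE)
  total_n <- tr$x * tr$w_n + PSET1$m_n / PSET1$m_no3 * tr$c_no3
  expect_true(all(diff(total_n) <= 1e-9))
  # the decrease is accounted for by the integrated metabolization flux
  met <- tr$x * PSET1$m_n * tr$v_no3_met
  absorbed <- cumsum(c(0, diff(tr$time_h) * (head(met, -1) + met[-1]) / 2))
  expect_lt(max(abs((total_n - total_n[1]) - absorbed)) / total_n[1], 0.01)
  # nitrate is monotone non-increasing in batch mode
  expect_true(all(diff(tr$c_no3) <= 1e-9))
  # quota bounds hold along the trajectory
  expect_true(all(tr$w_n <= PSET1$w_n_max + 1e-6))
  expect_true(all(tr$w_n >= PSET1$w_n_min - 1e-6))
})

test_that("halving the integration step changes the final state by < 0.1 %", {
  sc <- batch_scenario("LL")
  a <- simulate_culture(toy, PSET1, sc$initial, sc$light,
                        horizon = sc$horizon, step = 0.2)
  b <- simulate_culture(toy, PSET1, sc$initial, sc$light,
                        horizon = sc$horizon, step = 0.1)
  fa <- unlist(a[nrow(a), c("x", "c_no3", "w_chl", "w_car", "w_n")])
  fb <- unlist(b[nrow(b), c("x", "c_no3", "w_chl", "w_car", "w_n")])
  expect_lt(max(abs(fa - fb) / pmax(abs(fb), 1e-6)), 1e-3)
})

test_that("a lag phase much longer than the horizon freezes the culture", {
  p_frozen <- algal_parameters("set_I", lambda = 100)
  sc <- batch_scenario("LL")
  tr <- simulate_culture(toy, p_frozen, sc$initial, sc$light,
                         horizon = 72, step = 0.25)
  expect_lt(max(abs(tr$x - tr$x[1])) / tr$x[1], 0.01)
})

test_that("default initial pigment fractions come from the biomass composition", {
  comp <- biomass_composition(toy, PSET1)
  st <- reactor_state(x = 0.1, c_no3 = 0.5, w_n = 0.08)
  tr <- simulate_culture(toy, PSET1, st, 178, horizon = 1, step = 0.5)
  expect_equal(tr$w_chl[1], comp[["w_chl"]])
  expect_equal(tr$w_car[1], comp[["w_car"]])
  # explicit values override the default
  st2 <- reactor_state(x = 0.1, c_no3 = 0.5, w_n = 0.08, w_chl = 0.03,
                       w_car = 0.002)
  tr2 <- simulate_culture(toy, PSET1, st2, 178, horizon = 1, step = 0.5)
  expect_equal(tr2$w_chl[1], 0.03)
})

test_that("simulation summaries and penalties are exposed tidily", {
  st <- reactor_state(x = 0.1, c_no3 = 0.5, w_n = 0.08)
  tr <- simulate_culture(toy, PSET1, st, 178, horizon = 24, step = 0.5)
  g <- glance(tr)
  expect_named(g, c("horizon_h", "final_x", "max_x", "max_w_car",
                    "max_beta", "theta"))
  expect_equal(g$horizon_h, 24)
  expect_equal(g$theta, culture_penalty(tr))
  expect_s3_class(autoplot(tr), "ggplot")
})
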