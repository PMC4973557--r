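# The bounded-variable simplex against independent references.

test_that("random bounded LPs match boot::simplex where it returns a valid optimum", {
  skip_if_not_installed("boot")
  set.seed(42)
  checked <- 0L
  for (rep in 1:120) {
    m <- sample(2:5, 1); n <- m + sample(1:7, 1)
    A <- matrix(round(rnorm(m * n), 2), m)
    lb <- round(runif(n, -3, 0), 2); ub <- lb + round(runif(n, 0.5, 4), 2)
    x0 <- lb + runif(n) * (ub - lb)
    b <- as.numeric(A %*% x0)          # feasible by construction
    obj <- round(rnorm(n), 2)
    r <- phycoflux:::lp_solve(obj, A, b, lb, ub, sense = "max")
    expect_identical(r$status, "optimal")
    expect_lt(max(abs(A %*% r$x - b)), 1e-6)
    expect_true(all(r$x >= lb - 1e-7) && all(r$x <= ub + 1e-7))
    bs <- try(boot::simplex(a = obj, A1 = diag(n), b1 = ub - lb,
                            A3 = A, b3 = as.numeric(b - A %*% lb),
                            maxi = TRUE), silent = TRUE)
    if (inherits(bs, "try-error") || bs$solved != 1) next
    y <- as.numeric(bs$soln)
    ok <- max(abs(A %*% (y + lb) - b)) < 1e-6 &&
      all(y >= -1e-7) && all(y <= ub - lb + 1e-7)
    if (!ok) next                       # boot itself returned an invalid point
    v_ref <- bs$value + sum(obj * lb)
    expect_lt(abs(v_ref - r$objective), 1e-6 * max(1, abs(v_ref)))
    checked <- checked + 1L
  }
  expect_gt(checked, 50L)
})

test_that("infeasible and unbounded problems are reported as such", {
  r <- phycoflux:::lp_solve(c(1, 0), matrix(c(1, 1), 1), 10, c(0, 0), c(1, 1))
  expect_identical(r$status, "infeasible")
  r2 <- phycoflux:::lp_solve(1, matrix(0, 1, 1), 0, -Inf, Inf)
  expect_identical(r2$status, "unbounded")
  expect_error(solve_fba(toy, objective = "NGAM", sense = "max",
                         bounds = list(EX_photon = c(-Inf, 0))),
               "unbounded")
})

test_that("lexicographic objective values match vertex enumeration on toy instances", {
  pri <- default_priorities(toy)
  cases <- list(
    finite_toy_bounds(photon = 50),
    finite_toy_bounds(photon = 100, chl = c(-0.02, 5)),
    finite_toy_bounds(photon = 20, car = c(0.001, 5)),
    finite_toy_bounds(photon = 80, ngam = c(0.183, 5))
  )
  # plus seeded random perturbations of the bound set
  set.seed(7)
  for (i in 1:6) {
    b <- finite_toy_bounds(photon = runif(1, 10, 120),
                           chl = c(-runif(1, 0, 0.1), 5),
                           car = c(runif(1, 0, 0.002), 5))
    cases[[length(cases) + 1]] <- b
  }
  for (bounds in cases) {
    bb <- toy_bounds_vectors(bounds)
    ref <- oracle_lexicographic(toy, bb$lb, bb$ub, pri)
    sol <- solve_lexicographic(toy, bounds, pri)
    expect_equal(sol$objective_values, ref$objective_values,
                 tolerance = 1e-6)
    expect_equal(sol$penalty, 0, tolerance = 1e-8)
  }
})

test_that("level-ordered minimization resolves degenerate alternative optima", {
  # nitrogen-limited with abundant light: the growth-optimal face leaves
  # carotene flux free; level 3 must select its smallest value
  bounds <- finite_toy_bounds(photon = 100, car = c(0, 5))
  sol <- solve_lexicographic(toy, bounds)
  expect_equal(sol$flux$flux[sol$flux$reaction == "ACC_car"], 0,
               tolerance = 1e-7)
  # chlorophyll slack at optimum pins v_chl to its lower bound
  bounds2 <- finite_toy_bounds(photon = 100, chl = c(-0.02, 5))
  sol2 <- solve_lexicographic(toy, bounds2)
  expect_equal(sol2$flux$flux[sol2$flux$reaction == "ACC_chl"], -0.02,
               tolerance = 1e-7)
})

test_that("a single-priority list reduces to plain FBA", {
  b <- list(EX_photon = c(-30, -30))
  lex <- solve_lexicographic(toy, b, priority_list(list("BIO", "max")))
  fba <- solve_fba(toy, b)
  expect_equal(lex$objective_values, fba$objective_values, tolerance = 1e-9)
  expect_equal(lex$flux$flux[9], fba$flux$flux[9], tolerance = 1e-9)
})

test_that("lexicographic resolution is idempotent on its own optimum", {
  b <- list(EX_photon = c(-60, -60))
  s1 <- solve_lexicographic(toy, b)
  s2 <- solve_lexicographic(toy, b)
  expect_equal(s1$objective_values, s2$objective_values, tolerance = 1e-9)
  # feasible solutions satisfy mass balance on the balanced rows
  Sb <- toy$S[toy$metabolites$balanced, ]
  expect_lt(max(abs(Sb %*% s1$flux$flux)),
            1e-8 * max(1, max(abs(s1$flux$flux))))
})

test_that("phase-I penalty is zero iff the instance is feasible", {
  # feasible case
  ph0 <- phase1_relax(toy, list(EX_photon = c(-10, -10)))
  expect_equal(ph0$penalty, 0, tolerance = 1e-9)
  # carotene demanded with all inputs closed
  ph1 <- phase1_relax(toy, list(EX_photon = c(0, 0), NGAM = c(0, 0),
                                ACC_car = c(0.01, Inf)))
  expect_gt(ph1$penalty, 1e-6)
  # the relaxed bounds admit a lexicographic solve
  sol <- solve_lexicographic(toy, list(EX_photon = c(0, 0), NGAM = c(0, 0),
                                       ACC_car = c(0.01, Inf)))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$penalty, ph1$penalty, tolerance = 1e-8)
  expect_false(sol$feasible)
  # penalty shrinks monotonically as the conflicting bound is relaxed
  lbs <- seq(0.01, 0, length.out = 6)
  thetas <- vapply(lbs, function(l)
    phase1_relax(toy, list(EX_photon = c(0, 0), NGAM = c(0, 0),
                           ACC_car = c(l, Inf)))$penalty, numeric(1))
  expect_true(all(diff(thetas) <= 1e-12))
  expect_equal(thetas[6], 0, tolerance = 1e-10)
  # agreement with a direct feasibility check by the simplex itself
  bb <- phycoflux:::resolve_bounds(toy, list(EX_photon = c(0, 0), NGAM = c(0, 0),
                                             ACC_car = c(0.01, Inf)))
  Sb <- toy$S[toy$metabolites$balanced, ]
  direct <- phycoflux:::lp_solve(rep(0, 9), Sb, rep(0, nrow(Sb)), bb$lb, bb$ub)
  expect_identical(direct$status, "infeasible")
})

test_that("hand-solved toy growth optima are reproduced", {
  # photon-limited: 870 photons per unit biomass when maintenance is off
  s <- solve_fba(toy, list(EX_photon = c(-10, -10), NGAM = c(0, Inf)))
  expect_equal(s$objective_values, 10 / 870, tolerance = 1e-6)
  # with the maintenance demand active the balance gives 770 mu = 10 - 1.83
  s2 <- solve_fba(toy, list(EX_photon = c(-10, -10)))
  expect_equal(s2$objective_values, 8.17 / 770, tolerance = 1e-6)
  # nitrogen-limited: mu = v_no3_met_max / 3.5
  s3 <- solve_fba(toy, list(EX_photon = c(-100, -100)))
  expect_equal(s3$objective_values, 0.19 / 3.5, tolerance = 1e-6)
  # all inputs closed: no growth
  s4 <- solve_fba(toy, list(EX_photon = c(0, 0), EX_no3 = c(0, 0),
                            NGAM = c(0, 0)))
  expect_equal(s4$objective_values, 0, tolerance = 1e-8)
})
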