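test_that("transport-only steps conserve mass exactly before outflow", {
  m <- const_model(mu1 = 0, mu2 = 0, rho1 = 0, rho2 = 0, beta = beta_zero)
  init <- make_initial_history("bump", m, center = 0.3, width = 0.3)
  sim <- simulate_population(m, init, t_end = 0.2, n_out = 5)
  mass <- c(sim$mass0, sim$ledger$mass_p + sim$ledger$mass_n)
  expect_lt(max(abs(mass - mass[1L])) / mass[1L], 1e-13)
  expect_equal(sum(sim$ledger$outflow), 0)
})

test_that("stage transfer moves mass between phases without changing the total", {
  m <- const_model(mu1 = 0, mu2 = 0, rho1 = 0.8, rho2 = 0.3, beta = beta_zero)
  init <- make_initial_history("bump", m, center = 0.3, width = 0.3)
  sim <- simulate_population(m, init, t_end = 0.2, n_out = 3)
  mass <- c(sim$mass0, sim$ledger$mass_p + sim$ledger$mass_n)
  expect_lt(max(abs(mass - mass[1L])) / mass[1L], 1e-13)
  ## mass does move: p-share changes
  expect_gt(abs(sim$ledger$mass_p[nrow(sim$ledger)] - sim$mass0_p), 1e-3)
})

test_that("uniform death matches the scalar ODE oracle", {
  mu <- 0.3
  m <- const_model(mu1 = mu, mu2 = mu, rho1 = 0, rho2 = 0, beta = beta_zero)
  init <- make_initial_history("bump", m, center = 0.3, width = 0.3)
  sim <- simulate_population(m, init, t_end = 0.3, n_out = 4)
  k <- nrow(sim$ledger)
  expect_equal((sim$ledger$mass_p[k] + sim$ledger$mass_n[k]) / sim$mass0,
               exp(-mu * sim$t_end), tolerance = 5 * sim$dt * mu)
})

test_that("t_end = 0 returns exactly the initial state", {
  m <- tiny_model()
  init <- make_initial_history("bump", m)
  sim <- simulate_population(m, init, t_end = 0)
  expect_equal(sim$times, 0)
  expect_equal(sim$p[, 1L], init$p_history(0, m$size$centers))
  expect_equal(sim$n[, 1L], init$n0(m$size$centers))
  expect_error(mass_balance_residual(sim), "empty")
})

test_that("nonnegative data stay exactly nonnegative under the CFL bound", {
  m <- tiny_model()
  for (kind in c("bump", "n-only")) {
    sim <- simulate_population(m, make_initial_history(kind, m), t_end = 2,
                               n_out = 6)
    expect_true(all(sim$p >= 0) && all(sim$n >= 0), label = kind)
  }
  bad <- make_initial_history("bump", m, amplitude = -1)
  expect_error(simulate_population(m, bad, 1), "negative")
})

test_that("the mass ledger closes to round-off and is dt-refinement invariant", {
  m <- tiny_model()
  init <- make_initial_history("bump", m)
  r1 <- max(abs(mass_balance_residual(
    simulate_population(m, init, 1))$residual_rel))
  r2 <- max(abs(mass_balance_residual(
    simulate_population(m, init, 1, dt = m$delay$dsig / 4))$residual_rel))
  expect_lt(r1, 1e-13)
  expect_lt(r2, 1e-13)                 # stays at round-off, not O(dt)
})

test_that("with all rates off, cumulative outflow returns the whole mass", {
  m <- const_model(mu1 = 0, mu2 = 0, rho1 = 0, rho2 = 0, beta = beta_zero,
                   tau = 0, n_cells = 50L)
  init <- make_initial_history("bump", m, center = 0.3, width = 0.3)
  sim <- simulate_population(m, init, t_end = 1.5, n_out = 3)
  k <- nrow(sim$ledger)
  final_mass <- sim$ledger$mass_p[k] + sim$ledger$mass_n[k]
  expect_lt(final_mass / sim$mass0, 1e-12)   # everything exited
  expect_equal(sum(sim$ledger$outflow), sim$mass0,
               tolerance = 1e-12)
})

test_that("time step validation refuses CFL violations and non-divisors", {
  m <- tiny_model()
  expect_error(simulate_population(m, make_initial_history("bump", m), 1,
                                   dt = m$delay$dsig),   # divides, but > bound
               "bound")
  expect_error(simulate_population(m, make_initial_history("bump", m), 1,
                                   dt = m$delay$dsig / 2.5),
               "integer q")
  ## the auto-selected step respects both constraints
  st <- population_state(m, make_initial_history("bump", m))
  expect_lte(st$dt, cfl_bound(m))
  expect_equal(st$q * st$dt, m$delay$dsig, tolerance = 1e-14)
})

test_that("the newest history slice always equals the current profile", {
  m <- tiny_model()
  st <- population_state(m, make_initial_history("bump", m))
  expect_identical(st$hist[, ncol(st$hist)], st$p)
  for (i in 1:3) st <- step_population(st, m)
  expect_identical(st$hist[, ncol(st$hist)], st$p)
})

test_that("the solution map is linear and continuous in the data", {
  m <- tiny_model()
  i1 <- make_initial_history("bump", m)
  i2 <- make_initial_history("bump", m, amplitude = 2)
  s1 <- simulate_population(m, i1, 1, n_out = 3)
  s2 <- simulate_population(m, i2, 1, n_out = 3)
  expect_equal(s2$p, 2 * s1$p, tolerance = 1e-14)
  expect_equal(s2$n, 2 * s1$n, tolerance = 1e-14)

  ## small L1 perturbation of the data -> proportionally small output change
  delta <- 1e-3
  i3 <- make_initial_history("bump", m, center = 0.6, width = 0.3,
                             amplitude = delta)
  i13 <- structure(list(
    p_history = function(sigma, x) i1$p_history(sigma, x) + i3$p_history(sigma, x),
    n0 = function(x) i1$n0(x) + i3$n0(x), kind = "sum"), class = "initial_data")
  s13 <- simulate_population(m, i13, 1, n_out = 3)
  K <- ncol(s1$p)
  out_diff <- l1(s13$p[, K] - s1$p[, K], m$size$dx) +
    l1(s13$n[, K] - s1$n[, K], m$size$dx)
  in_diff <- l1(i3$p_history(0, m$size$centers), m$size$dx) * (1 + m$delay$tau) +
    l1(i3$n0(m$size$centers), m$size$dx)
  expect_lt(out_diff, 10 * in_diff)
})

test_that("growth_rate_estimate recovers exact exponents from synthetic ledgers", {
  tm <- seq(0, 10, by = 0.1)
  expect_equal(growth_rate_estimate(data.frame(time = tm, mass = 5 * exp(0.3 * tm))),
               0.3, tolerance = 1e-12)
  expect_equal(growth_rate_estimate(data.frame(time = tm, mass = rep(7, length(tm)))),
               0, tolerance = 1e-12)
  expect_error(growth_rate_estimate(data.frame(time = tm, mass = 0 * tm)),
               "nonpositive")
})
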