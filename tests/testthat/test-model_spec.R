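test_that("hypothesis checks flag the documented pass/fail cases", {
  ## constant rates, indicator kernel: every hypothesis holds by construction
  m <- const_model()
  rep <- validate_hypotheses(m)
  expect_true(rep$pass)
  expect_true(all(unlist(rep$flags)))

  ## rho2 == 0 with nu < 1 violates the first branch of (H.4)
  m2 <- const_model(rho2 = 0, nu = 0.5)
  rep2 <- validate_hypotheses(m2)
  expect_false(rep2$flags$H4)
  expect_true(rep2$flags$H1)  # rho2 = 0 is still nonnegative
  expect_false(rep2$pass)

  ## nu = 1 requires both transfer rates strictly positive
  m3 <- const_model(rho1 = 0, nu = 1)
  expect_false(validate_hypotheses(m3)$flags$H4)

  ## gamma(0) = 0 violates (H.2) at the x = 0 edge (cell centers alone
  ## would miss it)
  m4 <- const_model(gamma1 = function(x) x + 0 * x)
  rep4 <- validate_hypotheses(m4)
  expect_false(rep4$flags$H2)
  expect_match(rep4$witness$H2, "gamma")

  ## beta vanishing above the diagonal violates (H.5)
  m5 <- const_model(beta = function(s, x, y) 1 * (y > x + 0.5))
  expect_false(validate_hypotheses(m5)$flags$H5)
})

test_that("non-finite rate evaluation fails with the offender named", {
  expect_error(
    const_model(mu1 = function(x) ifelse(x < 0.5, NaN, 1)),
    "mu1"
  )
  expect_error(
    const_model(beta = function(s, x, y) ifelse(y > 0.9, Inf, 1)),
    "beta"
  )
})

test_that("validate_hypotheses is pure", {
  m <- tiny_model()
  r1 <- validate_hypotheses(m)
  r2 <- validate_hypotheses(m)
  expect_identical(r1, r2)
})

test_that("discounted kernel reduces to the plain time integral at lambda = 0", {
  tau <- 0.5
  m <- const_model(beta = function(s, x, y) 1 * (y > x), tau = tau)
  B0 <- discounted_birth_kernel(m, 0)
  x <- m$size$centers
  expected <- outer(x, x, function(xx, yy) 1 * (yy > xx)) * tau * m$size$dx
  expect_equal(B0, expected, tolerance = 1e-12)
})

test_that("discounted kernel matches the closed form for a sigma-constant kernel", {
  ## beta = k(x) h(y), tau = 1, lambda = 1: the sigma integral is 1 - e^{-1}
  kf <- function(x) 1 + x
  hf <- function(y) 2 - y
  m <- const_model(beta = function(s, x, y) kf(x) * hf(y),
                   tau = 1, n_nodes = 201L)
  B <- discounted_birth_kernel(m, 1)
  x <- m$size$centers
  exact <- outer(kf(x), hf(x)) * (1 - exp(-1)) * m$size$dx
  ## composite trapezoid in sigma: O(dsig^2) error
  expect_equal(B, exact, tolerance = 1e-5)
})

test_that("discounted kernel agrees with a brute-force fine-quadrature oracle", {
  m <- tiny_model(n_cells = 16L, n_nodes = 21L)
  lam <- 0.7
  B <- discounted_birth_kernel(m, lam)
  ## oracle: composite trapezoid with 1e4 nodes applied to the same
  ## separable integrand, independent of the package's delay grid
  tau <- m$delay$tau
  sig <- seq(-tau, 0, length.out = 10001L)
  w <- rep(tau / 10000, 10001L); w[c(1L, 10001L)] <- w[1L] / 2
  bvals <- (1 + 0.8 * cos(pi * sig / tau)) * exp(lam * sig)
  fac_oracle <- sum(w * bvals)
  x <- m$size$centers
  kx <- exp(-((x - 0.1) / 0.15)^2) + 0.01
  hy <- 83 * (x^2 + 0.02)
  oracle <- outer(kx, hy) * outer(x, x, function(xx, yy) 1 * (yy > xx)) *
    fac_oracle * m$size$dx
  expect_lt(max(abs(B - oracle)) / max(oracle), 5e-4)
})

test_that("discounted kernel is nonnegative and entrywise nonincreasing in lambda", {
  for (seed in 1:3) {
    m <- tiny_model(perturb = 0.2, seed = seed)
    lams <- c(-0.5, 0, 0.4, 1.5)
    Bs <- lapply(lams, function(l) discounted_birth_kernel(m, l))
    for (B in Bs) expect_true(all(B >= 0))
    for (j in seq_len(length(lams) - 1L)) {
      expect_true(all(Bs[[j]] >= Bs[[j + 1L]] - 1e-14))
    }
  }
})

test_that("tau = 0 degrades the delay integral to a unit-weight point evaluation", {
  m <- const_model(beta = function(s, x, y) (1 + s) * (y > x), tau = 0)
  expect_identical(m$delay$n_nodes, 1L)
  B <- discounted_birth_kernel(m, 3)   # discount e^{lam*0} = 1 regardless of lam
  x <- m$size$centers
  expect_equal(B, outer(x, x, function(xx, yy) 1 * (yy > xx)) * m$size$dx)
})

test_that("grid constructors enforce their invariants", {
  g <- size_grid(2, 8)
  expect_equal(g$edges[1L], 0)
  expect_equal(g$edges[length(g$edges)], 2)
  expect_equal(diff(g$edges), rep(g$dx, 8), tolerance = 1e-15)
  d <- delay_grid(0.5, 6)
  expect_equal(range(d$nodes), c(-0.5, 0))
  expect_equal(sum(d$weights), 0.5, tolerance = 1e-15)
  expect_error(size_grid(-1, 10))
  expect_error(delay_grid(-0.1))
})
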