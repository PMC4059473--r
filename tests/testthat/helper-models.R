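## Shared fixture builders. Everything is generated in code; unit tests run
## on deliberately small grids so the whole suite stays fast.

tiny_model <- function(preset = "generic", n_cells = 40L, n_nodes = 11L, ...) {
  example_model(preset, n_cells = n_cells, n_nodes = n_nodes, ...)
}

## Fully hand-specified model (useful for beta = 0, constant coefficients,
## manufactured solutions, ...).
const_model <- function(mu1 = 0.1, mu2 = 0.1, rho1 = 0.2, rho2 = 0.2,
                        gamma1 = 1, gamma2 = 1,
                        beta = function(s, x, y) 1 * (y > x), nu = 0.5,
                        n_cells = 40L, n_nodes = 11L, a_max = 1, tau = 0.5) {
  two_phase_model(vital_rates(mu1, mu2, rho1, rho2, gamma1, gamma2),
                  birth_kernel(beta, nu),
                  size_grid(a_max, n_cells), delay_grid(tau, n_nodes))
}

beta_zero <- function(s, x, y) 0 * (x + y)

## Smooth compactly supported profile and matching initial data with the
## reproductive history identically zero in the strict past.
cos_bump <- function(center, width) {
  function(x) {
    z <- (x - center) / (width / 2)
    ifelse(abs(z) < 1, cos(pi * z / 2)^2, 0)
  }
}

present_only_init <- function(center = 0.4, width = 0.5) {
  f <- cos_bump(center, width)
  structure(list(
    p_history = function(sigma, x) if (sigma >= 0) f(x) else 0 * x,
    n0 = function(x) 0 * x,
    kind = "present-only"
  ), class = "initial_data")
}

## L1 norm on the size grid
l1 <- function(v, dx) sum(abs(v)) * dx
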