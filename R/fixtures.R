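## Built-in model presets and initial data. Everything is closed-form so the
## discounted kernels are analytically checkable, and every preset satisfies
## the structural hypotheses (H.1)-(H.5) by construction. Nondimensional
## units: a_max = 1, tau = 0.5 by default. The birth-kernel amplitudes are
## frozen constants chosen once so that the Malthusian parameter is O(0.3),
## giving a well-separated dominant eigenvalue and a mild CFL constraint
## (see the methods vignette).

preset_catalog <- function() c("symmetric", "generic", "equal-growth")

#' Built-in example models
#'
#' Three closed-form parameter regimes satisfying all structural hypotheses:
#' `"symmetric"` (`mu1 = mu2`, `rho1 = rho2`, `gamma1 = gamma2`, `nu = 1/2`;
#' the phase-swap symmetry forces `p* = n*`), `"equal-growth"` (equal growth
#' rates but asymmetric death/transfer, the regime of the one-phase
#' comparison) and `"generic"` (all rates distinct). The birth kernel is
#' separable, `beta = b(sigma) k(x) h(y) 1{y > x}` with `b, k, h > 0`:
#' newborn sizes concentrate near small `x`, fertility near large `y`.
#'
#' @param preset one of `"symmetric"`, `"generic"`, `"equal-growth"`.
#' @param n_cells,n_nodes grid resolutions (defaults 100 cells, 21 delay
#'   nodes).
#' @param a_max,tau domain size and maximal delay (nondimensional defaults
#'   1 and 0.5).
#' @param nu optional override of the newborn split.
#' @param birth_scale optional override of the frozen kernel amplitude.
#' @param perturb amplitude of a smooth seeded multiplicative perturbation
#'   of the death rates (property-testing aid; kept `< 1` so (H.1) still
#'   holds).
#' @param seed seed for the perturbation draw.
#' @return A [two_phase_model()].
#' @export
example_model <- function(preset = "generic", n_cells = 100L, n_nodes = 21L,
                          a_max = 1, tau = 0.5, nu = NULL, birth_scale = NULL,
                          perturb = 0, seed = 1L) {
  if (!preset %in% preset_catalog()) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(preset_catalog(), collapse = ", "))
  }
  grid <- size_grid(a_max, n_cells)
  dg <- delay_grid(tau, n_nodes)
  ab <- a_max

  bsig <- if (tau > 0) {
    function(sigma) 1 + 0.8 * cos(pi * sigma / tau)
  } else {
    function(sigma) rep(1, length(sigma))
  }
  kx <- function(x) exp(-((x - 0.1 * ab) / (0.15 * ab))^2) + 0.01
  hy <- function(y) (y / ab)^2 + 0.02

  if (preset == "symmetric") {
    mu <- function(x) 0.2 + 0.1 * x / ab
    rates <- vital_rates(mu1 = mu, mu2 = mu, rho1 = 0.5, rho2 = 0.5,
                         gamma1 = 1, gamma2 = 1)
    nu0 <- 0.5; scale0 <- 75
  } else if (preset == "equal-growth") {
    rates <- vital_rates(
      mu1 = function(x) 0.15 + 0.10 * x / ab,
      mu2 = function(x) 0.25 - 0.10 * x / ab,
      rho1 = function(x) 0.5 + 0.2 * x / ab,
      rho2 = function(x) 0.7 - 0.2 * x / ab,
      gamma1 = 1, gamma2 = 1)
    nu0 <- 0.4; scale0 <- 81
  } else {
    rates <- vital_rates(
      mu1 = function(x) 0.20 + 0.10 * x / ab,
      mu2 = function(x) 0.10 + 0.20 * (x / ab)^2,
      rho1 = function(x) 0.4 + 0.2 * x / ab,
      rho2 = function(x) 0.6 - 0.2 * x / ab,
      gamma1 = function(x) 1 + 0.1 * x / ab,
      gamma2 = function(x) 0.9 - 0.2 * x / ab)
    nu0 <- 0.4; scale0 <- 83
  }
  if (perturb > 0) {
    stopifnot(perturb < 1)
    set.seed(seed)
    a1 <- stats::runif(1, 0.5, 2); ph1 <- stats::runif(1, 0, 2 * pi)
    a2 <- stats::runif(1, 0.5, 2); ph2 <- stats::runif(1, 0, 2 * pi)
    m1 <- rates$mu1; m2 <- rates$mu2
    rates$mu1 <- function(x) m1(x) * (1 + perturb * sin(2 * pi * a1 * x / ab + ph1))
    rates$mu2 <- function(x) m2(x) * (1 + perturb * sin(2 * pi * a2 * x / ab + ph2))
  }
  if (is.null(nu)) nu <- nu0
  if (is.null(birth_scale)) birth_scale <- scale0
  beta <- separable_kernel(bsig, kx, function(y) birth_scale * hy(y))
  two_phase_model(rates, birth_kernel(beta, nu), grid, dg)
}

#' Initial data (history segment plus current profiles)
#'
#' @param kind `"bump"` (smooth compactly supported profiles interior to
#'   `(0, a_max)`, constant in `sigma`), `"eigen"` (the exact exponential
#'   eigen-history `p(sigma, x) = e^{lam0 sigma} p*(x)`, `n0 = n*`; requires
#'   `eigen`), or `"n-only"` (zero reproductive history, bump `n0`).
#' @param model the [two_phase_model()] the data are for.
#' @param eigen an `eigen_solution`, required for `kind = "eigen"`.
#' @param center,width center and support width of the bump (size units).
#' @param amplitude bump amplitude.
#' @return An object of class `"initial_data"` with vectorized component
#'   functions `p_history(sigma, x)` and `n0(x)`.
#' @export
make_initial_history <- function(kind = "bump", model, eigen = NULL,
                                 center = 0.4 * model$size$a_max,
                                 width = 0.5 * model$size$a_max,
                                 amplitude = 1) {
  stopifnot(inherits(model, "two_phase_model"))
  bump <- function(x) {
    z <- (x - center) / (width / 2)
    ifelse(abs(z) < 1, amplitude * cos(pi * z / 2)^2, 0)
  }
  if (kind == "bump") {
    dat <- list(p_history = function(sigma, x) bump(x),
                n0 = function(x) 0.8 * bump(x))
  } else if (kind == "n-only") {
    dat <- list(p_history = function(sigma, x) rep(0, length(x)),
                n0 = function(x) bump(x))
  } else if (kind == "eigen") {
    if (is.null(eigen)) stop("kind = 'eigen' requires an eigen solution")
    stopifnot(inherits(eigen, "eigen_solution"))
    xs <- model$size$centers
    pf <- stats::approxfun(xs, eigen$p_star, rule = 2)
    nf <- stats::approxfun(xs, eigen$n_star, rule = 2)
    lam0 <- eigen$lam0
    dat <- list(p_history = function(sigma, x) exp(lam0 * sigma) * pf(x),
                n0 = function(x) nf(x))
  } else {
    stop("unknown initial-data kind '", kind,
         "'; valid kinds: bump, eigen, n-only")
  }
  structure(c(dat, list(kind = kind)), class = "initial_data")
}

#' @export
print.initial_data <- function(x, ...) {
  cat(sprintf("initial data, kind '%s'\n", x$kind))
  invisible(x)
}
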