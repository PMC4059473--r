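## Model parameterization: vital rates, birth kernel, assembled model object,
## structural hypothesis checks, and the lambda-discounted birth kernel that
## the whole spectral machinery is built on.

as_rate_fun <- function(f, name) {
  if (is.function(f)) return(f)
  if (is.numeric(f) && length(f) == 1L && is.finite(f)) {
    force(f)
    return(function(x) rep(f, length(x)))
  }
  stop(sprintf("rate '%s' must be a function of size or a single number", name))
}

#' Vital rates of the two-phase model
#'
#' Death rates `mu1`, `mu2` (per time), stage-transfer rates `rho1` (out of
#' the reproductive stage) and `rho2` (into it), and growth rates `gamma1`,
#' `gamma2` (size per time), each a function of size on `[0, a_max]` or a
#' single constant.
#'
#' @param mu1,mu2,rho1,rho2,gamma1,gamma2 functions of size (vectorized) or
#'   single nonnegative numbers; `gamma1`, `gamma2` must be strictly positive.
#' @return An object of class `"vital_rates"`.
#' @export
vital_rates <- function(mu1, mu2, rho1, rho2, gamma1, gamma2) {
  structure(list(
    mu1 = as_rate_fun(mu1, "mu1"),   mu2 = as_rate_fun(mu2, "mu2"),
    rho1 = as_rate_fun(rho1, "rho1"), rho2 = as_rate_fun(rho2, "rho2"),
    gamma1 = as_rate_fun(gamma1, "gamma1"),
    gamma2 = as_rate_fun(gamma2, "gamma2")
  ), class = "vital_rates")
}

#' Birth kernel with newborn-stage split
#'
#' `beta(sigma, x, y)` is the rate density at which reproductive individuals
#' of size `y` produce, after a gestation lag `-sigma` (`sigma` in
#' `[-tau, 0]`), newborns of size `x`. A fixed fraction `nu` of newborns
#' enters the reproductive stage, the rest the nonreproductive stage.
#'
#' @param beta function `beta(sigma, x, y)`; must accept a scalar `sigma`
#'   and equal-length vectors / conformable arrays `x`, `y`, evaluating
#'   elementwise (any arithmetic closed form qualifies).
#' @param nu fraction of newborns entering the reproductive stage, in
#'   `[0, 1]`.
#' @return An object of class `"birth_kernel"`.
#' @seealso [separable_kernel()] for the product-form kernels the presets use.
#' @export
birth_kernel <- function(beta, nu) {
  stopifnot(is.function(beta), is.numeric(nu), length(nu) == 1L,
            is.finite(nu), nu >= 0, nu <= 1)
  structure(list(beta = beta, nu = nu), class = "birth_kernel")
}

#' Separable birth kernel b(sigma) k(x) h(y) 1{y > x}
#'
#' Product-form kernel: `b` the gestation-lag profile on `[-tau, 0]`, `k` the
#' newborn-size profile, `h` the size-specific fertility, optionally
#' restricted to `y > x` (parents only produce offspring smaller than
#' themselves).
#'
#' @param b,k,h vectorized positive functions (or constants).
#' @param upper_only if `TRUE` (default) multiply by the indicator `y > x`.
#' @return A kernel function suitable for [birth_kernel()].
#' @export
separable_kernel <- function(b, k, h, upper_only = TRUE) {
  b <- as_rate_fun(b, "b"); k <- as_rate_fun(k, "k"); h <- as_rate_fun(h, "h")
  force(upper_only)
  function(sigma, x, y) {
    out <- b(sigma) * k(x) * h(y)
    if (upper_only) out <- out * (y > x)
    out
  }
}

#' Assemble and discretize a two-phase model
#'
#' Evaluates all rates on the size grid, tabulates the birth kernel on the
#' (delay node) x (size) x (size) lattice and stores the per-node birth
#' matrices `B_k[i, j] = beta(sigma_k, x_i, y_j) * dx` whose action on a
#' reproductive profile approximates the inner size integral of the birth
#' term.
#'
#' @param rates a [vital_rates()] object.
#' @param kernel a [birth_kernel()] object.
#' @param size a [size_grid()].
#' @param delay a [delay_grid()].
#' @return An object of class `"two_phase_model"` carrying the rate functions,
#'   their grid tabulations (`mu1v`, ..., `gamma2v`), the kernel tabulation
#'   `Bk` (list over delay nodes) and the grids.
#' @export
two_phase_model <- function(rates, kernel, size, delay) {
  stopifnot(inherits(rates, "vital_rates"), inherits(kernel, "birth_kernel"),
            inherits(size, "size_grid"), inherits(delay, "delay_grid"))
  x <- size$centers
  tab <- lapply(rates[c("mu1", "mu2", "rho1", "rho2", "gamma1", "gamma2")],
                function(f) {
                  v <- as.numeric(f(x))
                  stopifnot(length(v) == length(x))
                  v
                })
  for (nm in names(tab)) {
    if (any(!is.finite(tab[[nm]]))) {
      stop(sprintf("rate '%s' evaluates non-finite at x = %g",
                   nm, x[which(!is.finite(tab[[nm]]))[1L]]))
    }
  }
  n <- size$n_cells
  Bk <- lapply(delay$nodes, function(sg) {
    B <- outer(x, x, function(xx, yy) kernel$beta(sg, xx, yy)) * size$dx
    if (any(!is.finite(B))) {
      bad <- which(!is.finite(B), arr.ind = TRUE)[1L, ]
      stop(sprintf("beta evaluates non-finite at (sigma, x, y) = (%g, %g, %g)",
                   sg, x[bad[1L]], x[bad[2L]]))
    }
    dim(B) <- c(n, n)
    B
  })
  structure(list(
    rates = rates, kernel = kernel, size = size, delay = delay,
    nu = kernel$nu,
    mu1v = tab$mu1, mu2v = tab$mu2, rho1v = tab$rho1, rho2v = tab$rho2,
    gamma1v = tab$gamma1, gamma2v = tab$gamma2,
    Bk = Bk
  ), class = "two_phase_model")
}

#' @export
print.two_phase_model <- function(x, ...) {
  cat("two-phase size-structured model\n")
  print(x$size); print(x$delay)
  cat(sprintf("  nu = %g; rate ranges: mu1 [%g, %g], mu2 [%g, %g],\n",
              x$nu, min(x$mu1v), max(x$mu1v), min(x$mu2v), max(x$mu2v)))
  cat(sprintf("  rho1 [%g, %g], rho2 [%g, %g], gamma1 [%g, %g], gamma2 [%g, %g]\n",
              min(x$rho1v), max(x$rho1v), min(x$rho2v), max(x$rho2v),
              min(x$gamma1v), max(x$gamma1v), min(x$gamma2v), max(x$gamma2v)))
  invisible(x)
}

#' Structural hypothesis checks for the asynchronous-growth theory
#'
#' Samples the model on its grids and checks, as necessary conditions only:
#' nonnegativity of `mu1`, `mu2`, `rho1`, `rho2` (H.1); strict positivity of
#' `gamma1`, `gamma2` (H.2; continuous differentiability is assumed
#' structurally, not verified numerically); nonnegativity of `beta` (H.3);
#' strict positivity of the transfer rates in the branch selected by `nu`
#' (H.4: `rho2 > 0` everywhere when `nu < 1`, both `rho1 > 0` and
#' `rho2 > 0` when `nu = 1`); and strict positivity of `beta(., x, y)` for
#' `y > x` (H.5). (H.1)-(H.3) are needed for well-posedness, (H.4)-(H.5)
#' additionally for the asynchronous-exponential-growth guarantee. Rates are
#' sampled on cell centers *and* edges (so endpoint failures such as
#' `gamma(0) = 0` are caught); the kernel on the stored lattice.
#'
#' @param model a [two_phase_model()].
#' @return An object of class `"hypothesis_report"`: per-hypothesis logical
#'   flags, a witness (failing point) per failed flag, and `pass`, the
#'   conjunction of all flags.
#' @export
validate_hypotheses <- function(model) {
  stopifnot(inherits(model, "two_phase_model"))
  xs <- sort(unique(c(model$size$edges, model$size$centers)))
  flags <- list(); witness <- list()
  chk <- function(id, vals, pts, ok_fun, what) {
    bad <- which(!ok_fun(vals))
    flags[[id]] <<- length(bad) == 0L
    if (length(bad) > 0L) {
      witness[[id]] <<- sprintf("%s violated at x = %g (value %g)",
                                what, pts[bad[1L]], vals[bad[1L]])
    }
  }
  nonneg <- function(v) is.finite(v) & v >= 0
  pos <- function(v) is.finite(v) & v > 0
  r <- model$rates
  vH1 <- c(r$mu1(xs), r$mu2(xs), r$rho1(xs), r$rho2(xs))
  chk("H1", vH1, rep(xs, 4L), nonneg, "mu/rho >= 0")
  vH2 <- c(r$gamma1(xs), r$gamma2(xs))
  chk("H2", vH2, rep(xs, 2L), pos, "gamma > 0")

  Ball <- unlist(model$Bk)
  flags$H3 <- all(is.finite(Ball) & Ball >= -0)
  if (!flags$H3) witness$H3 <- "beta < 0 or non-finite on the sampled lattice"

  if (model$nu < 1) {
    v <- r$rho2(xs)
    chk("H4", v, xs, pos, sprintf("nu = %g < 1 requires rho2 > 0", model$nu))
  } else {
    v <- c(r$rho1(xs), r$rho2(xs))
    chk("H4", v, rep(xs, 2L), pos, "nu = 1 requires rho1, rho2 > 0")
  }

  ## H.5 on the stored lattice: strict positivity strictly above the diagonal
  x <- model$size$centers
  upper <- outer(x, x, function(xx, yy) yy > xx)
  ok5 <- TRUE; wit5 <- NULL
  for (k in seq_along(model$Bk)) {
    B <- model$Bk[[k]]
    bad <- upper & !(B > 0)
    if (any(bad)) {
      ok5 <- FALSE
      ij <- which(bad, arr.ind = TRUE)[1L, ]
      wit5 <- sprintf("beta(%g, %g, %g) = %g not > 0 although y > x",
                      model$delay$nodes[k], x[ij[1L]], x[ij[2L]],
                      B[ij[1L], ij[2L]] / model$size$dx)
      break
    }
  }
  flags$H5 <- ok5
  if (!ok5) witness$H5 <- wit5

  structure(list(flags = flags, witness = witness,
                 pass = all(unlist(flags))),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("hypothesis report (necessary-condition grid checks):\n")
  for (id in names(x$flags)) {
    cat(sprintf("  (%s.%s): %s\n", substr(id, 1, 1), substr(id, 2, 2),
                if (x$flags[[id]]) "pass" else paste("FAIL --", x$witness[[id]])))
  }
  cat(if (x$pass) "  all hypotheses pass\n" else "  overall: FAIL\n")
  invisible(x)
}

#' Discounted birth kernel matrix B_lambda
#'
#' Tabulates the exponentially discounted delay integral
#' `B_lambda(x, y) = int_{-tau}^{0} e^{lambda sigma} beta(sigma, x, y) dsigma`
#' on the size grid, including the size-quadrature weight `dx`, so that
#' `B %*% P` approximates the operator `P -> int B_lambda(., y) P(y) dy`.
#' The delay integral uses the composite trapezoid rule on the delay grid;
#' `tau = 0` degenerates to a point evaluation with unit weight.
#'
#' Entries are nonnegative and entrywise nonincreasing in `lambda` (the
#' integrand carries `e^{lambda sigma}` with `sigma <= 0`).
#'
#' @param model a [two_phase_model()].
#' @param lam real growth exponent `lambda`.
#' @return An `n_cells x n_cells` nonnegative matrix.
#' @export
discounted_birth_kernel <- function(model, lam) {
  stopifnot(inherits(model, "two_phase_model"),
            is.numeric(lam), length(lam) == 1L, is.finite(lam))
  w <- model$delay$weights * exp(lam * model$delay$nodes)
  B <- model$Bk[[1L]] * w[1L]
  if (length(model$Bk) > 1L) {
    for (k in 2L:length(model$Bk)) B <- B + model$Bk[[k]] * w[k]
  }
  B
}
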