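## Spectral machinery: the characteristic (next-generation-type) operator
## K_lambda, bisection for the Malthusian parameter, the dense discretized
## generator used as an independent oracle, and the adjoint (reproductive
## value) eigenfunctions with their biorthogonal normalization.

## Local (birth-free) part of the discretized generator on the (p, n) block:
## conservative upwind transport, death and stage transfer. Returned as a
## dense 2n x 2n matrix, ordering (p_1..p_n, n_1..n_n).
local_generator <- function(model) {
  n <- model$size$n_cells
  dx <- model$size$dx
  sub_trans <- function(g) {
    M <- diag(-g / dx, n)
    if (n > 1L) M[cbind(2:n, 1:(n - 1L))] <- g[1:(n - 1L)] / dx
    M
  }
  L <- matrix(0, 2L * n, 2L * n)
  ip <- 1:n; inn <- (n + 1L):(2L * n)
  L[ip, ip] <- sub_trans(model$gamma1v) - diag(model$mu1v + model$rho1v, n)
  L[inn, inn] <- sub_trans(model$gamma2v) - diag(model$mu2v + model$rho2v, n)
  L[ip, inn] <- diag(model$rho2v, n)
  L[inn, ip] <- diag(model$rho1v, n)
  L
}

## 2n x 2n matrix J(lambda) = Local + [nu; 1-nu] * B_lambda acting on p.
## Its eigenvalue condition J(lam0) v = lam0 v is the discrete eigenproblem;
## the adjoint eigenfunctions are left eigenvectors of J(lam0).
generator_2n <- function(model, lam) {
  n <- model$size$n_cells
  J <- local_generator(model)
  B <- discounted_birth_kernel(model, lam)
  J[1:n, 1:n] <- J[1:n, 1:n] + model$nu * B
  J[(n + 1L):(2L * n), 1:n] <- J[(n + 1L):(2L * n), 1:n] + (1 - model$nu) * B
  J
}

#' Resolve a distributed birth source through the transfer/transport system
#'
#' Solves the stationary coupled system (first-order in size, marching from
#' `x = 0` with zero traces)
#' \deqn{(\gamma_1 P)' = -(\lambda+\mu_1+\rho_1)P + \rho_2 N + \nu s(x),}
#' \deqn{(\gamma_2 N)' = -(\lambda+\mu_2+\rho_2)N + \rho_1 P + (1-\nu) s(x),}
#' by first-order implicit upwind marching (backward differences), the exact
#' stationary counterpart of the simulator's transport discretization. The
#' per-cell 2x2 system is an M-matrix whenever the implicit diagonals stay
#' positive, so nonnegative sources yield nonnegative profiles with no step
#' restriction.
#'
#' @param model a [two_phase_model()].
#' @param lam real exponent `lambda`.
#' @param source a numeric vector (length `n_cells`) or matrix
#'   (`n_cells` rows, one column per independent source).
#' @param nu newborn split; defaults to the model's `nu`.
#' @return list with matrices/vectors `P` and `N` shaped like `source`.
#' @export
transfer_resolve <- function(model, lam, source, nu = model$nu) {
  stopifnot(inherits(model, "two_phase_model"), is.finite(lam))
  s <- as.matrix(source)
  n <- model$size$n_cells
  stopifnot(nrow(s) == n)
  dx <- model$size$dx
  d1 <- model$gamma1v / dx + lam + model$mu1v + model$rho1v
  d2 <- model$gamma2v / dx + lam + model$mu2v + model$rho2v
  dets <- d1 * d2 - model$rho1v * model$rho2v
  if (any(d1 <= 0) || any(d2 <= 0) || any(dets <= 0)) {
    stop(sprintf(paste0("transfer_resolve: implicit upwind loses positivity at",
                        " lambda = %g; admissible lambda must exceed %g"),
                 lam, max(-model$gamma1v / dx - model$mu1v - model$rho1v,
                          -model$gamma2v / dx - model$mu2v - model$rho2v)))
  }
  P <- matrix(0, n, ncol(s)); N <- matrix(0, n, ncol(s))
  g1 <- model$gamma1v / dx; g2 <- model$gamma2v / dx
  pprev <- rep(0, ncol(s)); nprev <- rep(0, ncol(s))
  for (i in seq_len(n)) {
    r1 <- if (i == 1L) nu * s[i, ] else g1[i - 1L] * pprev + nu * s[i, ]
    r2 <- if (i == 1L) (1 - nu) * s[i, ] else g2[i - 1L] * nprev + (1 - nu) * s[i, ]
    pprev <- (d2[i] * r1 + model$rho2v[i] * r2) / dets[i]
    nprev <- (model$rho1v[i] * r1 + d1[i] * r2) / dets[i]
    P[i, ] <- pprev; N[i, ] <- nprev
  }
  if (is.vector(source)) list(P = drop(P), N = drop(N)) else list(P = P, N = N)
}

#' Characteristic operator K_lambda
#'
#' The nonnegative `n x n` matrix acting on reproductive profiles as
#' `P -> ` (reproductive component of [transfer_resolve()] applied to
#' `B_lambda P`). Its spectral radius is continuous and strictly decreasing
#' in `lambda`, and equals 1 exactly at the Malthusian parameter.
#'
#' @inheritParams transfer_resolve
#' @return `n_cells x n_cells` nonnegative matrix.
#' @export
characteristic_operator <- function(model, lam) {
  B <- discounted_birth_kernel(model, lam)
  transfer_resolve(model, lam, B)$P
}

#' Spectral radius and Perron vector of a nonnegative matrix
#'
#' Dense eigendecomposition below dimension 400; deterministic power
#' iteration (all-ones start, tolerance 1e-12, at most 1e4 iterations)
#' above.
#'
#' @param M square nonnegative matrix.
#' @return list with `radius` and `vector` (nonnegative, unit L1 norm).
#' @export
spectral_radius <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(is.finite(M)))
  if (any(M < 0)) stop("spectral_radius expects a nonnegative matrix")
  n <- nrow(M)
  if (n < 400L) {
    ev <- eigen(M)
    i <- which.max(Mod(ev$values))
    v <- Re(ev$vectors[, i])
    if (sum(v) < 0) v <- -v
    v[v < 0 & v > -1e-12 * max(abs(v))] <- 0
    return(list(radius = Re(ev$values[i]), vector = v / sum(v)))
  }
  v <- rep(1 / n, n); r <- NA_real_
  for (it in seq_len(10000L)) {
    w <- as.numeric(M %*% v)
    rn <- sum(w)
    if (rn == 0) return(list(radius = 0, vector = v))
    w <- w / rn
    if (max(abs(w - v)) < 1e-12) {
      v <- w; r <- rn; break
    }
    v <- w; r <- rn
  }
  list(radius = r, vector = v)
}

#' Malthusian parameter and stable size distribution
#'
#' Finds the dominant eigenvalue `lambda_0` of the discretized model as the
#' unique root of `r(K_lambda) = 1`, where `r` is the spectral radius of the
#' [characteristic_operator()]. The bracket is auto-expanded: the upper end
#' geometrically until `r < 1` (such a ceiling always exists because the
#' discounted kernel vanishes as `lambda -> Inf`), the lower end
#' geometrically toward the positivity bound of the implicit marching. Root
#' refinement uses [stats::uniroot()] (Brent) to near machine precision.
#'
#' @param model a [two_phase_model()].
#' @param bracket optional numeric `c(lo, hi)` with
#'   `r(K_lo) > 1 > r(K_hi)`; auto-expanded when `NULL` or unsuitable.
#' @param tol tolerance on `|r(K_lambda) - 1|` at the returned root.
#' @return An object of class `"eigen_solution"`: `lam0`, mass-normalized
#'   strictly positive profiles `p_star`, `n_star`, the eigen-equation
#'   `residual`, the spectral radius `r_root` at the root, the bracket and
#'   the `r(lambda)` trace explored.
#' @export
malthusian_parameter <- function(model, bracket = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "two_phase_model"))
  trace_l <- numeric(0); trace_r <- numeric(0)
  rfun <- function(lam) {
    r <- spectral_radius(characteristic_operator(model, lam))$radius
    trace_l <<- c(trace_l, lam); trace_r <<- c(trace_r, r)
    r
  }
  lam_floor <- max(-model$gamma1v / model$size$dx - model$mu1v - model$rho1v,
                   -model$gamma2v / model$size$dx - model$mu2v - model$rho2v)
  if (is.null(bracket)) {
    lo <- 0; rlo <- rfun(lo)
    if (rlo > 1) {
      hi <- 0.5
      while (rfun(hi) > 1 && hi < 1e4) { lo <- hi; hi <- hi * 2 }
      if (hi >= 1e4) stop("bracket expansion failed upward; r(lambda) trace: ",
                          paste(sprintf("r(%g)=%g", trace_l, trace_r),
                                collapse = ", "))
    } else {
      hi <- 0; step <- 0.25
      repeat {
        lo <- hi - step
        if (lo <= 0.95 * lam_floor) {
          stop("bracket expansion failed: r(K_lambda) < 1 down to the ",
               "positivity bound (birth kernel too weak?); r(lambda) trace: ",
               paste(sprintf("r(%g)=%g", trace_l, trace_r), collapse = ", "))
        }
        if (rfun(lo) > 1) break
        hi <- lo; step <- step * 2
      }
    }
    bracket <- c(lo, hi)
  } else {
    stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L])
    if (!(rfun(bracket[1L]) > 1 && rfun(bracket[2L]) < 1)) {
      return(malthusian_parameter(model, bracket = NULL, tol = tol))
    }
  }
  root <- stats::uniroot(function(l) rfun(l) - 1, interval = bracket,
                         tol = .Machine$double.eps^0.75)
  lam0 <- root$root
  K <- characteristic_operator(model, lam0)
  pr <- spectral_radius(K)
  if (abs(pr$radius - 1) > tol) {
    stop(sprintf("characteristic root not converged: |r - 1| = %.3e > %g",
                 abs(pr$radius - 1), tol))
  }
  sol <- transfer_resolve(model, lam0,
                          discounted_birth_kernel(model, lam0) %*% pr$vector)
  p_star <- drop(sol$P); n_star <- drop(sol$N)
  mass <- sum(p_star + n_star) * model$size$dx
  p_star <- p_star / mass; n_star <- n_star / mass
  v <- c(p_star, n_star)
  resid <- max(abs(generator_2n(model, lam0) %*% v - lam0 * v))
  structure(list(lam0 = lam0, p_star = p_star, n_star = n_star,
                 residual = resid, r_root = pr$radius, bracket = bracket,
                 iterations = length(trace_l),
                 r_trace = data.frame(lambda = trace_l, r = trace_r),
                 size = model$size, delay = model$delay),
            class = "eigen_solution")
}

#' @export
print.eigen_solution <- function(x, ...) {
  cat(sprintf("Malthusian parameter lam0 = %.10g\n", x$lam0))
  cat(sprintf("  eigen residual %.3e, r(K) at root %.12f, %d radius evaluations\n",
              x$residual, x$r_root, x$iterations))
  invisible(x)
}

#' Dense generator matrix on the history x profile state space
#'
#' Discretizes the abstract first-order system whose state is the history
#' segment of the reproductive density (one block per delay node) together
#' with the current profiles `(p, n)`. Layout:
#' `(h_1, ..., h_m, p, n)` with `h_k` the slice at delay node `sigma_k`
#' (`sigma_m = 0`), each block of length `n_cells`; the matrix dimension is
#' exactly `n_nodes * n_cells + 2 * n_cells`.
#'
#' The shift-in-sigma coupling uses a Crank-Nicolson (trapezoid) relation
#' between adjacent history nodes, and the `sigma = 0` node is pinned to `p`
#' through a stiff relaxation row (rate `1/dsig`); under eigen-elimination
#' the history nodes then reproduce the exponential `e^{lambda sigma_k}`
#' with third-order per-step accuracy, which is what lets the rightmost
#' eigenvalue of this matrix agree with the characteristic-root method to
#' ~1e-6 and better on one and the same grid. The `(p, n)` rows are the
#' identical transport/transfer discretization used everywhere else, with
#' the delayed birth term reading the history block through the trapezoid
#' weights.
#'
#' This matrix is the *oracle* route to the Malthusian parameter; the
#' characteristic-root method is the primary one.
#'
#' @param model a [two_phase_model()].
#' @param max_dim guard on the dense dimension.
#' @return square matrix of dimension `n_nodes*n_cells + 2*n_cells`.
#' @export
full_generator_matrix <- function(model, max_dim = 8000L) {
  stopifnot(inherits(model, "two_phase_model"))
  n <- model$size$n_cells
  m <- model$delay$n_nodes
  dim_tot <- m * n + 2L * n
  if (dim_tot > max_dim) {
    stop(sprintf("generator dimension %d exceeds guard %d", dim_tot, max_dim))
  }
  idx <- function(k) ((k - 1L) * n + 1L):(k * n)   # history block k
  ip <- (m * n + 1L):(m * n + n)
  inn <- (m * n + n + 1L):(m * n + 2L * n)
  S <- matrix(0, dim_tot, dim_tot)
  Mm <- diag(dim_tot)
  In <- diag(n)
  kap <- if (model$delay$tau > 0) 1 / model$delay$dsig else 1

  ## (p, n) rows: local dynamics + delayed birth from the history block
  L <- local_generator(model)
  S[c(ip, inn), c(ip, inn)] <- L
  w <- model$delay$weights
  for (k in seq_len(m)) {
    S[ip, idx(k)] <- S[ip, idx(k)] + model$nu * w[k] * model$Bk[[k]]
    S[inn, idx(k)] <- S[inn, idx(k)] + (1 - model$nu) * w[k] * model$Bk[[k]]
  }

  ## history rows k = 1..m-1: Crank-Nicolson shift  d/dt (h_k+h_{k+1})/2 =
  ## (h_{k+1} - h_k)/dsig
  if (m > 1L) {
    ds <- model$delay$dsig
    for (k in seq_len(m - 1L)) {
      S[idx(k), idx(k)] <- -In / ds
      S[idx(k), idx(k + 1L)] <- In / ds
      Mm[idx(k), idx(k)] <- In / 2
      Mm[idx(k), idx(k + 1L)] <- In / 2
    }
  }

  ## sigma = 0 node: follow p through relaxation plus a copy of the p-row,
  ## so that in any eigenpair with lambda != -kappa the node equals p exactly
  S[idx(m), ] <- S[ip, , drop = FALSE]
  S[idx(m), idx(m)] <- S[idx(m), idx(m)] - kap * In
  S[idx(m), ip] <- S[idx(m), ip] + kap * In

  solve(Mm, S)
}

#' Rightmost eigenvalue of a dense generator matrix
#'
#' Helper for the oracle route: returns the eigenvalue of maximal real part
#' and its eigenvector, rejecting ties with genuinely complex rightmost
#' pairs (which signal a model violating the strict-positivity hypotheses or
#' an inadequate grid).
#'
#' @param G square matrix, e.g. from [full_generator_matrix()].
#' @param imag_tol tolerance on the imaginary part of the rightmost
#'   eigenvalue, relative to its magnitude.
#' @return list with `value` (real) and `vector` (real part, sign-fixed).
#' @export
rightmost_eigenvalue <- function(G, imag_tol = 1e-8) {
  ev <- eigen(G)
  i <- which.max(Re(ev$values))
  lam <- ev$values[i]
  if (abs(Im(lam)) > imag_tol * max(1, abs(lam))) {
    stop(sprintf("rightmost eigenvalue is complex (%g + %gi): dominant-",
                 Re(lam), Im(lam)),
         "eigenvalue simplicity fails on this model/grid")
  }
  v <- Re(ev$vectors[, i])
  if (sum(v) < 0) v <- -v
  list(value = Re(lam), vector = v)
}

#' Adjoint (reproductive value) eigenfunctions
#'
#' Computes the positive left eigenpair of the discrete eigenproblem at
#' `lambda_0`: `(phi, psi)` solve the transposed profile problem
#' `t(J(lam0)) l = lam0 l`, and the history pairing weight is the
#' exponentially discounted factor of the Hale-type bilinear form,
#' `W(sigma_j, y) = sum_{k <= j} w_k e^{lam0 (sigma_k - sigma_j)} (c^T B_k)_y`
#' with `c = nu phi + (1 - nu) psi`. Normalization makes the bilinear
#' pairing with the right eigenvector equal to 1:
#' `<l, v> = phi.p* + psi.n* + sum_k w_k (-sigma_k) e^{lam0 sigma_k} c^T B_k p*`,
#' (the `u`-integral of the form evaluated exactly on the exponential
#' eigenhistory). With this normalization the paired functional of any
#' solution, discounted by `e^{-lam0 t}`, is a conserved quantity of the
#' semi-discrete dynamics.
#'
#' @param model a [two_phase_model()].
#' @param eigen an [malthusian_parameter()] solution on the same grids.
#' @param tol acceptance tolerance on `|lambda_adj - lambda_0|`.
#' @return An object of class `"adjoint_solution"`: `phi`, `psi`,
#'   `lam0` (the adjoint eigenvalue), `history_weight` (an
#'   `n_nodes x n_cells` matrix at the delay nodes), `cB` (the
#'   `n_nodes x n_cells` matrix of rows `c^T B_k`, the reusable ingredient
#'   of all pairings) and the normalization constant applied.
#' @export
adjoint_eigenfunctions <- function(model, eigen, tol = 1e-7) {
  stopifnot(inherits(model, "two_phase_model"),
            inherits(eigen, "eigen_solution"))
  if (!isTRUE(all.equal(model$size$centers, eigen$size$centers))) {
    stop("eigen solution was computed on a different size grid")
  }
  n <- model$size$n_cells
  lam0 <- eigen$lam0
  J <- generator_2n(model, lam0)
  ev <- base::eigen(t(J))
  i <- which.min(abs(ev$values - lam0))
  if (abs(ev$values[i] - lam0) > tol * max(1, abs(lam0))) {
    stop(sprintf("left eigenpair extraction failed: nearest eigenvalue %g%+gi vs lam0 = %g",
                 Re(ev$values[i]), Im(ev$values[i]), lam0))
  }
  l <- Re(ev$vectors[, i])
  if (sum(l) < 0) l <- -l
  phi <- l[1:n]; psi <- l[(n + 1L):(2L * n)]

  cw <- model$nu * phi + (1 - model$nu) * psi
  m <- model$delay$n_nodes
  cB <- matrix(0, m, n)
  for (k in seq_len(m)) cB[k, ] <- as.numeric(crossprod(cw, model$Bk[[k]]))

  w <- model$delay$weights; sg <- model$delay$nodes
  pairing <- sum(phi * eigen$p_star) + sum(psi * eigen$n_star) +
    sum(vapply(seq_len(m), function(k) {
      w[k] * (-sg[k]) * exp(lam0 * sg[k]) * sum(cB[k, ] * eigen$p_star)
    }, numeric(1)))
  if (!is.finite(pairing) || pairing <= 0) {
    stop("degenerate adjoint pairing; cannot normalize")
  }
  phi <- phi / pairing; psi <- psi / pairing; cB <- cB / pairing

  W <- matrix(0, m, n)
  for (j in seq_len(m)) {
    for (k in seq_len(j)) {
      W[j, ] <- W[j, ] + w[k] * exp(lam0 * (sg[k] - sg[j])) * cB[k, ]
    }
  }
  structure(list(phi = phi, psi = psi, lam0 = Re(ev$values[i]),
                 history_weight = W, cB = cB, normalization = pairing,
                 size = model$size, delay = model$delay, nu = model$nu),
            class = "adjoint_solution")
}

#' @export
print.adjoint_solution <- function(x, ...) {
  cat(sprintf("adjoint eigenfunctions at lam0 = %.10g (normalized pairing = 1)\n",
              x$lam0))
  cat(sprintf("  phi range [%g, %g], psi range [%g, %g]\n",
              min(x$phi), max(x$phi), min(x$psi), max(x$psi)))
  invisible(x)
}

## Discrete bilinear pairing of an arbitrary (history, p, n) state with the
## adjoint: phi.p + psi.n + sum_{k<m} w_k int_{sigma_k}^0
## e^{lam0(sigma_k-u)} cB_k . p(t+u) du.  `hist_fun(u)` must return the
## reproductive profile at offset u in [-tau, 0]; the u-integral uses
## composite Simpson with `refine` panels per delay node interval.
adjoint_pairing <- function(adjoint, lam0, p, n, hist_fun, refine = 8L) {
  val <- sum(adjoint$phi * p) + sum(adjoint$psi * n)
  m <- adjoint$delay$n_nodes
  if (m == 1L) return(val)
  w <- adjoint$delay$weights; sg <- adjoint$delay$nodes
  for (k in seq_len(m - 1L)) {
    nseg <- 2L * refine * (m - k)           # even panel count on [sigma_k, 0]
    u <- seq(sg[k], 0, length.out = nseg + 1L)
    du <- u[2L] - u[1L]
    sw <- c(1, rep(c(4, 2), length.out = nseg - 1L), 1)
    sw[length(sw)] <- 1
    vals <- vapply(seq_along(u), function(j) {
      exp(lam0 * (sg[k] - u[j])) * sum(adjoint$cB[k, ] * hist_fun(u[j]))
    }, numeric(1))
    val <- val + w[k] * du / 3 * sum(sw * vals)
  }
  val
}
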