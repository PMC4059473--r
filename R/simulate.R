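## Time integration of the two-phase model: conservative upwind transport,
## pointwise death/transfer, and the distributed-delay birth source read from
## a history buffer of the reproductive density. A single unsplit explicit
## Euler update keeps the scheme positivity-preserving under the combined
## CFL/decay bound and makes the discrete mass ledger close to round-off,
## because the ledger is built from exactly the fluxes the update applies.

#' Positivity/CFL time-step bound of the explicit scheme
#'
#' The unsplit Euler update keeps nonnegative data nonnegative iff
#' `dt * (gamma_i/dx + mu_i + rho_i) <= 1` in every cell and both phases.
#'
#' @param model a [two_phase_model()].
#' @return the largest admissible `dt`.
#' @export
cfl_bound <- function(model) {
  dx <- model$size$dx
  1 / max(model$gamma1v / dx + model$mu1v + model$rho1v,
          model$gamma2v / dx + model$mu2v + model$rho2v)
}

resolve_dt <- function(model, dt) {
  bound <- cfl_bound(model)
  tau <- model$delay$tau
  if (tau == 0) {
    if (is.null(dt)) dt <- 0.95 * bound
    if (dt > bound) {
      stop(sprintf("dt = %g violates the positivity/CFL bound; need dt <= %g",
                   dt, bound))
    }
    return(list(dt = dt, q = 1L))
  }
  ds <- model$delay$dsig
  if (is.null(dt)) {
    q <- max(1L, as.integer(ceiling(ds / (0.95 * bound) - 1e-12)))
    dt <- ds / q
  } else {
    q <- round(ds / dt)
    if (q < 1 || abs(ds / dt - q) > 1e-8) {
      stop(sprintf(paste0("dt = %g does not divide the delay node spacing ",
                          "%g; use dt = dsig/q for integer q"), dt, ds))
    }
    q <- as.integer(q)
    dt <- ds / q
    if (dt > bound * (1 + 1e-12)) {
      stop(sprintf("dt = %g violates the positivity/CFL bound; need dt <= %g",
                   dt, bound))
    }
  }
  list(dt = dt, q = q)
}

#' Construct the time-stepping state from initial data
#'
#' Evaluates the initial history on the stored time levels
#' `t = -tau, ..., -dt, 0` (spacing `dt`; the delay nodes land on every
#' `q`-th level) and the profiles on cell centers.
#'
#' @param model a [two_phase_model()].
#' @param init an [make_initial_history()] object.
#' @param dt time step; `NULL` selects the largest step of the form
#'   `dsig / q` within the positivity/CFL bound.
#' @param check_positivity error on negative initial values (population
#'   runs demand nonnegative data).
#' @return An object of class `"population_state"` with fields `t`, `p`,
#'   `n`, `hist` (chronological `n_cells x n_store` matrix whose last
#'   column is `p`; `NULL` when `tau = 0`), `dt`, `q`.
#' @export
population_state <- function(model, init, dt = NULL, check_positivity = TRUE) {
  stopifnot(inherits(model, "two_phase_model"), inherits(init, "initial_data"))
  r <- resolve_dt(model, dt)
  x <- model$size$centers
  m <- model$delay$n_nodes
  if (model$delay$tau > 0) {
    n_store <- (m - 1L) * r$q + 1L
    offs <- (-(n_store - 1L):0) * r$dt
    hist <- vapply(offs, function(u) as.numeric(init$p_history(u, x)),
                   numeric(length(x)))
    p <- hist[, n_store]
  } else {
    hist <- NULL
    p <- as.numeric(init$p_history(0, x))
  }
  n <- as.numeric(init$n0(x))
  if (check_positivity &&
      (any(p < 0) || any(n < 0) || (!is.null(hist) && any(hist < 0)))) {
    stop("negative initial data in a positivity-checked run")
  }
  w <- model$delay$weights
  BW <- do.call(cbind, lapply(seq_len(m), function(k) w[k] * model$Bk[[k]]))
  structure(list(t = 0, p = p, n = n, hist = hist, dt = r$dt, q = r$q,
                 BW = BW), class = "population_state")
}

#' Advance the population state by one time step
#'
#' One unsplit explicit Euler step: upwind transport of `p` at speed
#' `gamma1` and of `n` at speed `gamma2` (zero inflow at `x = 0`, free
#' outflow at `x = a_max`), death and stage transfer, and the delayed birth
#' source `b(t, x)` (trapezoid over the delay nodes, each node reading the
#' matching stored history level), split `nu` to `p` and `1 - nu` to `n`.
#' The returned state carries a `"flows"` attribute with the step's birth,
#' death, outflow and transfer totals and the mass-balance residual, all
#' computed from the very fluxes applied.
#'
#' @param state a [population_state()].
#' @param model the matching [two_phase_model()].
#' @return the advanced `"population_state"`.
#' @export
step_population <- function(state, model) {
  p <- state$p; n <- state$n; dt <- state$dt
  dx <- model$size$dx
  m <- model$delay$n_nodes
  if (!is.null(state$hist)) {
    n_store <- ncol(state$hist)
    cols <- n_store - (m - seq_len(m)) * state$q
    b <- as.numeric(state$BW %*% as.vector(state$hist[, cols]))
  } else {
    b <- as.numeric(state$BW %*% p)
  }
  f1 <- model$gamma1v * p
  f2 <- model$gamma2v * n
  nc <- length(p)
  div1 <- (f1 - c(0, f1[-nc])) / dx
  div2 <- (f2 - c(0, f2[-nc])) / dx
  t12 <- model$rho1v * p          # reproductive -> nonreproductive
  t21 <- model$rho2v * n          # nonreproductive -> reproductive
  pnew <- p + dt * (-div1 - model$mu1v * p - t12 + t21 + model$nu * b)
  nnew <- n + dt * (-div2 - model$mu2v * n - t21 + t12 + (1 - model$nu) * b)

  mass_old <- sum(p + n) * dx
  mass_new <- sum(pnew + nnew) * dx
  births <- dt * sum(b) * dx
  deaths <- dt * sum(model$mu1v * p + model$mu2v * n) * dx
  outflow <- dt * (f1[nc] + f2[nc])
  resid <- (mass_new - mass_old) - (births - deaths - outflow)
  hist <- state$hist
  if (!is.null(hist)) hist <- cbind(hist[, -1L, drop = FALSE], pnew)
  out <- state
  out$t <- state$t + dt; out$p <- pnew; out$n <- nnew; out$hist <- hist
  attr(out, "flows") <- c(
    births = births, deaths = deaths, outflow = outflow,
    transfer12 = dt * sum(t12) * dx, transfer21 = dt * sum(t21) * dx,
    mass_p = sum(pnew) * dx, mass_n = sum(nnew) * dx,
    residual = resid, residual_rel = resid / max(mass_old, .Machine$double.xmin))
  out
}

#' Simulate the two-phase model
#'
#' Repeated [step_population()] with snapshot recording and a per-step mass
#' ledger. The horizon is rounded up to a whole number of steps.
#'
#' @inheritParams population_state
#' @param t_end simulation horizon (>= 0; `t_end = 0` returns only the
#'   initial state).
#' @param n_out number of snapshots (evenly spread over the run, always
#'   including `t = 0` and the final time).
#' @param store_history keep the full history buffer at every snapshot
#'   (needed by the adjoint-pairing diagnostics).
#' @return An object of class `"simulation_result"`: snapshot `times`,
#'   profile matrices `p`, `n` (`n_cells` x snapshots), the per-step
#'   `ledger` data frame (time, masses, births, deaths, outflow, transfers,
#'   mass-balance residual), initial masses, `dt`, and (optionally) the
#'   stored snapshot histories.
#' @export
simulate_population <- function(model, init, t_end, dt = NULL, n_out = 11L,
                                store_history = FALSE,
                                check_positivity = TRUE) {
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end >= 0)
  state <- population_state(model, init, dt, check_positivity)
  mass0_p <- sum(state$p) * model$size$dx
  mass0_n <- sum(state$n) * model$size$dx
  n_steps <- if (t_end == 0) 0L else as.integer(ceiling(t_end / state$dt - 1e-9))
  out_steps <- unique(as.integer(round(seq(0L, n_steps, length.out =
                                             min(n_out, n_steps + 1L)))))
  K <- length(out_steps)
  nc <- model$size$n_cells
  P <- matrix(0, nc, K); N <- matrix(0, nc, K)
  histories <- if (store_history && !is.null(state$hist)) vector("list", K)
  led <- matrix(NA_real_, n_steps, 9L,
                dimnames = list(NULL, c("births", "deaths", "outflow",
                                        "transfer12", "transfer21", "mass_p",
                                        "mass_n", "residual", "residual_rel")))
  rec <- 1L
  record <- function(k) {
    P[, rec] <<- state$p; N[, rec] <<- state$n
    if (!is.null(histories)) histories[[rec]] <<- state$hist
    rec <<- rec + 1L
  }
  if (out_steps[1L] == 0L) record(0L)
  if (n_steps > 0L) {
    for (k in seq_len(n_steps)) {
      state <- step_population(state, model)
      led[k, ] <- attr(state, "flows")
      if (k %in% out_steps) record(k)
    }
  }
  ledger <- data.frame(time = seq_len(max(n_steps, 0L)) * state$dt, led)
  structure(list(
    times = out_steps * state$dt, p = P, n = N, ledger = ledger,
    mass0_p = mass0_p, mass0_n = mass0_n, mass0 = mass0_p + mass0_n,
    dt = state$dt, q = state$q, n_steps = n_steps,
    t_end = n_steps * state$dt, init = init,
    histories = histories, centers = model$size$centers,
    dx = model$size$dx
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation: %d steps of dt = %g to t = %g, %d snapshots\n",
              x$n_steps, x$dt, x$t_end, length(x$times)))
  if (x$n_steps > 0L) {
    cat(sprintf("  final mass %.6g, max |mass-balance residual| %.3e (relative)\n",
                x$ledger$mass_p[x$n_steps] + x$ledger$mass_n[x$n_steps],
                max(abs(x$ledger$residual_rel))))
  }
  invisible(x)
}

#' Per-step mass-balance residual series
#'
#' `residual_k = (mass change) - (births - deaths - outflow)` at step `k`,
#' reported relative to the pre-step mass. Built from the same fluxes the
#' update applies, so it sits at round-off for every run.
#'
#' @param result a [simulate_population()] result.
#' @return data frame with `time` and `residual_rel`.
#' @export
mass_balance_residual <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  if (nrow(result$ledger) == 0L) stop("ledger is empty (t_end = 0 run)")
  result$ledger[, c("time", "residual_rel")]
}

#' Growth-rate estimate from the mass ledger
#'
#' Least-squares slope of `log(total mass)` against time over the trailing
#' `window` fraction of the run; targets the Malthusian parameter.
#'
#' @param result a [simulate_population()] result, or a data frame with
#'   columns `time` and `mass`.
#' @param window trailing fraction of the time range used for the fit.
#' @return the estimated exponent.
#' @export
growth_rate_estimate <- function(result, window = 0.4) {
  if (inherits(result, "simulation_result")) {
    tm <- c(0, result$ledger$time)
    mass <- c(result$mass0, result$ledger$mass_p + result$ledger$mass_n)
  } else {
    stopifnot(is.data.frame(result), all(c("time", "mass") %in% names(result)))
    tm <- result$time; mass <- result$mass
  }
  keep <- tm >= (1 - window) * max(tm)
  tm <- tm[keep]; mass <- mass[keep]
  if (any(mass <= 0)) stop("nonpositive mass in the fit window; ",
                           "growth-rate estimate undefined")
  if (length(tm) < 2L) stop("need at least two ledger points in the window")
  unname(stats::coef(stats::lm(log(mass) ~ tm))[2L])
}
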