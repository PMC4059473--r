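#' Uniform cell-centered size grid on [0, a_max]
#'
#' The size domain is partitioned into `n_cells` uniform finite-volume cells;
#' all densities live on cell centers and transport fluxes on cell edges.
#'
#' @param a_max maximal individual size (size units, > 0).
#' @param n_cells number of uniform cells (>= 2).
#' @return An object of class `"size_grid"` with fields `a_max`, `n_cells`,
#'   `dx`, `centers` and `edges`.
#' @examples
#' g <- size_grid(1, 10)
#' g$dx
#' @export
size_grid <- function(a_max, n_cells) {
  stopifnot(is.numeric(a_max), length(a_max) == 1L, is.finite(a_max), a_max > 0)
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 2,
            n_cells == round(n_cells))
  n_cells <- as.integer(n_cells)
  dx <- a_max / n_cells
  edges <- seq(0, a_max, length.out = n_cells + 1L)
  structure(list(
    a_max   = a_max,
    n_cells = n_cells,
    dx      = dx,
    centers = edges[-(n_cells + 1L)] + dx / 2,
    edges   = edges
  ), class = "size_grid")
}

#' Uniform quadrature grid for the gestation delay interval [-tau, 0]
#'
#' Holds the nodes and composite-trapezoid weights used for every
#' sigma-integral (delayed birth term, discounted kernels, adjoint pairings).
#' `tau = 0` degenerates to a single node at 0 with unit weight, recovering
#' the undelayed model.
#'
#' @param tau maximal delay (time units, >= 0).
#' @param n_nodes number of nodes on `[-tau, 0]`; must be >= 2 when
#'   `tau > 0`, and is forced to 1 when `tau == 0`.
#' @return An object of class `"delay_grid"` with fields `tau`, `n_nodes`,
#'   `nodes` (increasing, last node 0), `dsig` (node spacing, 0 when tau = 0)
#'   and `weights` (trapezoid weights; unit weight when tau = 0).
#' @export
delay_grid <- function(tau, n_nodes = 21L) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau >= 0)
  if (tau == 0) {
    return(structure(list(tau = 0, n_nodes = 1L, nodes = 0,
                          dsig = 0, weights = 1),
                     class = "delay_grid"))
  }
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2,
            n_nodes == round(n_nodes))
  n_nodes <- as.integer(n_nodes)
  nodes <- seq(-tau, 0, length.out = n_nodes)
  dsig <- tau / (n_nodes - 1L)
  w <- rep(dsig, n_nodes)
  w[c(1L, n_nodes)] <- dsig / 2
  structure(list(tau = tau, n_nodes = n_nodes, nodes = nodes,
                 dsig = dsig, weights = w),
            class = "delay_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("size grid: %d cells on [0, %g], dx = %g\n",
              x$n_cells, x$a_max, x$dx))
  invisible(x)
}

#' @export
print.delay_grid <- function(x, ...) {
  if (x$tau == 0) {
    cat("delay grid: tau = 0 (undelayed, point evaluation)\n")
  } else {
    cat(sprintf("delay grid: %d nodes on [%g, 0], dsig = %g (trapezoid)\n",
                x$n_nodes, -x$tau, x$dsig))
  }
  invisible(x)
}
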