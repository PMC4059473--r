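## Configuration files, run driver, and deterministic on-disk artifacts.
## Configs are Debian-control-style key: value text (read.dcf); numeric
## tables are comma-separated with a mandatory header. All solver starts are
## fixed, so outputs are a pure function of the config.

#' Read a run configuration file
#'
#' The file is key-value text in DCF format (one `key: value` per line).
#' Recognized keys: `preset` (or the six rate-table paths `mu1_table`, ...,
#' `gamma2_table` plus the separable-kernel tables `b_table`, `k_table`,
#' `h_table`), `n_cells`, `n_nodes`, `a_max`, `tau`, `nu`, `birth_scale`,
#' `dt`, `t_end`, `n_out`, `init` (bump / eigen / n-only), `init_center`,
#' `init_width`, `tol`, `seed`. Rate tables are CSV with header `x,value`
#' (`sigma,value` for `b_table`) and are wrapped by linear interpolation
#' with constant extrapolation.
#'
#' @param path config file path.
#' @return a named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.dcf(path)
  cfg <- as.list(raw[1L, ])
  num_keys <- c("n_cells", "n_nodes", "a_max", "tau", "nu", "birth_scale",
                "dt", "t_end", "n_out", "init_center", "init_width", "tol",
                "seed")
  for (k in intersect(names(cfg), num_keys)) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (is.na(v)) stop("config key '", k, "' is not numeric: ", cfg[[k]])
    cfg[[k]] <- v
  }
  if (!is.null(cfg$tol) && cfg$tol <= 0) stop("tolerances must be > 0")
  structure(cfg, class = "run_config")
}

read_rate_table <- function(path, xname = "x") {
  tab <- utils::read.csv(path)
  if (!all(c(xname, "value") %in% names(tab))) {
    stop("rate table ", path, " must have header columns '",
         xname, "' and 'value'")
  }
  stats::approxfun(tab[[xname]], tab$value, rule = 2)
}

model_from_config <- function(cfg) {
  n_cells <- as.integer(cfg$n_cells %||% 100L)
  n_nodes <- as.integer(cfg$n_nodes %||% 21L)
  a_max <- cfg$a_max %||% 1
  tau <- cfg$tau %||% 0.5
  if (!is.null(cfg$preset)) {
    return(example_model(cfg$preset, n_cells = n_cells, n_nodes = n_nodes,
                         a_max = a_max, tau = tau, nu = cfg$nu,
                         birth_scale = cfg$birth_scale,
                         seed = as.integer(cfg$seed %||% 1L)))
  }
  need <- c("mu1_table", "mu2_table", "rho1_table", "rho2_table",
            "gamma1_table", "gamma2_table", "k_table", "h_table", "nu")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop("config must give either 'preset' or all rate tables; missing: ",
         paste(miss, collapse = ", "))
  }
  rates <- vital_rates(
    mu1 = read_rate_table(cfg$mu1_table), mu2 = read_rate_table(cfg$mu2_table),
    rho1 = read_rate_table(cfg$rho1_table),
    rho2 = read_rate_table(cfg$rho2_table),
    gamma1 = read_rate_table(cfg$gamma1_table),
    gamma2 = read_rate_table(cfg$gamma2_table))
  b <- if (!is.null(cfg$b_table)) read_rate_table(cfg$b_table, "sigma") else 1
  kern <- separable_kernel(b, read_rate_table(cfg$k_table),
                           read_rate_table(cfg$h_table))
  two_phase_model(rates, birth_kernel(kern, cfg$nu),
                  size_grid(a_max, n_cells), delay_grid(tau, n_nodes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_scalar_report <- function(values, path) {
  utils::write.csv(data.frame(name = names(values),
                              value = unname(unlist(values))),
                   path, row.names = FALSE, quote = FALSE)
}

write_manifest <- function(cfg, command, model, seed, out_dir) {
  manifest <- list(
    package = "twophasepop",
    version = as.character(utils::packageVersion("twophasepop")),
    command = command,
    config = unclass(cfg),
    grid = list(n_cells = model$size$n_cells, a_max = model$size$a_max,
                dx = model$size$dx, n_nodes = model$delay$n_nodes,
                tau = model$delay$tau),
    seed = seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")  # excluded from hashing
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Execute a pipeline command from a configuration
#'
#' Commands: `"validate"` (hypothesis report), `"simulate"` (snapshots +
#' ledger; hypothesis failures are warnings), `"eigen"` (Malthusian
#' parameter, eigenprofiles, adjoint; hypothesis failures are fatal since
#' the asynchronous-growth guarantee needs (H.4)-(H.5)), `"aeg"`
#' (simulation plus projection/functional diagnostics; fatal gate) and
#' `"compare"` (equal-growth one-phase comparison; fatal gate). Progress
#' messages go to stderr; stdout stays machine-readable.
#'
#' @param config a `"run_config"` or path to one.
#' @param command one of `validate`, `simulate`, `eigen`, `aeg`, `compare`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed echoed into the manifest and used for any
#'   seeded fixture perturbation.
#' @return invisibly, a list with `status` (0 on success), `reason` and the
#'   written `files`.
#' @export
run_from_config <- function(config, command, out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command,
                       c("validate", "simulate", "eigen", "aeg", "compare"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  model <- model_from_config(config)
  rep <- validate_hypotheses(model)
  files <- character(0)
  fail <- function(reason) {
    message("run_from_config: ", reason)
    invisible(list(status = 1L, reason = reason, files = files))
  }
  gate_fatal <- command %in% c("eigen", "aeg", "compare")
  if (!rep$pass) {
    failed <- names(rep$flags)[!unlist(rep$flags)]
    msg <- sprintf("hypothesis check failed: %s (%s)",
                   paste(failed, collapse = ", "),
                   paste(unlist(rep$witness[failed]), collapse = "; "))
    if (gate_fatal) return(fail(msg))
    if (command == "simulate") warning(msg)
  }
  write_manifest(config, command, model, seed, out_dir)
  files <- c(files, file.path(out_dir, "manifest.json"))
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  if (command == "validate") {
    emit(data.frame(hypothesis = names(rep$flags),
                    pass = unlist(rep$flags),
                    witness = vapply(names(rep$flags), function(id) {
                      rep$witness[[id]] %||% ""
                    }, character(1))), "hypotheses.csv")
    message("validate: ", if (rep$pass) "all hypotheses pass" else "FAIL")
    return(invisible(list(status = as.integer(!rep$pass),
                          reason = if (rep$pass) "" else "hypothesis failure",
                          files = files)))
  }

  init_kind <- config$init %||% "bump"
  mk_init <- function(eig = NULL) {
    args <- list(kind = init_kind, model = model, eigen = eig)
    if (!is.null(config$init_center)) args$center <- config$init_center
    if (!is.null(config$init_width)) args$width <- config$init_width
    do.call(make_initial_history, args)
  }
  t_end <- config$t_end %||% 10
  n_out <- as.integer(config$n_out %||% 11L)

  if (command == "simulate") {
    sim <- simulate_population(model, mk_init(), t_end, dt = config$dt,
                               n_out = n_out)
    snaps <- do.call(rbind, lapply(seq_along(sim$times), function(j) {
      data.frame(t = sim$times[j], x = sim$centers,
                 p = sim$p[, j], n = sim$n[, j])
    }))
    emit(snaps, "snapshots.csv")
    emit(sim$ledger, "ledger.csv")
    message(sprintf("simulate: %d steps to t = %g", sim$n_steps, sim$t_end))
    return(invisible(list(status = 0L, reason = "", files = files)))
  }

  eig <- malthusian_parameter(model, tol = config$tol %||% 1e-9)
  adj <- adjoint_eigenfunctions(model, eig)
  if (command == "eigen") {
    emit(data.frame(x = model$size$centers, p_star = eig$p_star,
                    n_star = eig$n_star, phi = adj$phi, psi = adj$psi),
         "eigen.csv")
    write_scalar_report(list(lam0 = eig$lam0, residual = eig$residual,
                             r_root = eig$r_root,
                             bracket_lo = eig$bracket[1L],
                             bracket_hi = eig$bracket[2L],
                             radius_evaluations = eig$iterations),
                        file.path(out_dir, "report.csv"))
    files <- c(files, file.path(out_dir, "report.csv"))
    message(sprintf("eigen: lam0 = %.10g", eig$lam0))
    return(invisible(list(status = 0L, reason = "", files = files)))
  }

  if (command == "aeg") {
    sim <- simulate_population(model, mk_init(eig), t_end, dt = config$dt,
                               n_out = n_out, store_history = TRUE)
    diag <- aeg_diagnostics(sim, eig, adj)
    emit(diag$table, "diagnostics.csv")
    write_scalar_report(list(lam0 = eig$lam0, c = diag$c, drift = diag$drift,
                             decay_rate = diag$decay_rate,
                             final_aeg_error =
                               diag$table$aeg_error[nrow(diag$table)]),
                        file.path(out_dir, "report.csv"))
    files <- c(files, file.path(out_dir, "report.csv"))
    message(sprintf("aeg: c = %.6g, final error %.3e", diag$c,
                    diag$table$aeg_error[nrow(diag$table)]))
    return(invisible(list(status = 0L, reason = "", files = files)))
  }

  ## compare
  if (max(abs(model$gamma1v - model$gamma2v)) > 1e-12 * max(model$gamma1v)) {
    return(fail("compare requires an equal-growth model (gamma1 = gamma2)"))
  }
  op <- reduce_to_onephase(model, eig)
  cmp <- compare_asymptotics(model, op, mk_init(eig), t_end = t_end,
                             dt = config$dt, eigen = eig, adjoint = adj)
  eig1 <- malthusian_parameter(op)
  emit(data.frame(x = model$size$centers, theta = cmp$theta,
                  p_star = eig$p_star, n_star = eig$n_star,
                  onephase_profile = eig1$p_star),
       "comparison.csv")
  write_scalar_report(list(lam0_two = cmp$lam0_two, lam0_one = cmp$lam0_one,
                           c1 = cmp$c1, c2 = cmp$c2, c3 = cmp$c3,
                           shape_error = cmp$shape_error),
                      file.path(out_dir, "report.csv"))
  files <- c(files, file.path(out_dir, "report.csv"))
  message(sprintf("compare: c3 = %.6g, shape error %.3e", cmp$c3,
                  cmp$shape_error))
  invisible(list(status = 0L, reason = "", files = files))
}

#' Command-line entry point
#'
#' Usage: `twophase-cli.R <command> --config FILE [--out DIR] [--seed N]`,
#' with `<command>` one of `validate`, `simulate`, `eigen`, `aeg`,
#' `compare`, or `presets` to list the built-in presets. Returns the exit
#' status (0 success) rather than calling `quit()`, so it is testable; the
#' installed script in `inst/scripts/` wraps it.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
tpm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: twophase-cli.R <validate|simulate|eigen|aeg|compare|presets> ",
            "--config FILE [--out DIR] [--seed N]")
    return(invisible(2L))
  }
  command <- args[1L]
  if (command == "presets") {
    cat(paste(preset_catalog(), collapse = "\n"), "\n", sep = "")
    return(invisible(0L))
  }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg <- opt("--config")
  if (is.null(cfg)) {
    message("--config FILE is required")
    return(invisible(2L))
  }
  res <- tryCatch(
    run_from_config(cfg, command, out_dir = opt("--out", "."),
                    seed = opt("--seed")),
    error = function(e) {
      message("error: ", conditionMessage(e))
      list(status = 1L)
    })
  invisible(as.integer(res$status))
}
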