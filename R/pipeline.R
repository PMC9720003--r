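#' Validated run configurations
#'
#' The pipeline entry points (`run_simulation()`, `run_estimation()`,
#' `run_sweep()`, `run_random_envs()`, `run_synth()`) take a configuration —
#' a named list or the path to a JSON file — validate it against the fields
#' the command requires, and write deterministic CSV/JSON outputs that echo
#' the full configuration, its hash and every seed used, so that identical
#' invocations are bit-identical.
#'
#' @param config Named list or path to a JSON file.
#' @param required Character vector of required field names.
#' @return The configuration as a named list (invisibly for the runners).
#' @export
as_run_config <- function(config, required = character()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop_config("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_config("config must be a named list or JSON path.")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop_config("config is missing required field(s): ",
                paste(missing, collapse = ", "))
  config
}

stop_config <- function(...) {
  stop(rlang::error_cnd(class = "plasmidstab_config_error",
                        message = paste0(...)))
}

config_params <- function(cf) {
  p <- cf$params
  if (is.null(p)) stop_config("config needs a `params` block.")
  if (!is.null(p$kappa_n) && !is.null(p$mu_n)) {
    model_params(n = p$n %||% 1, kappa_n = p$kappa_n, mu_n = p$mu_n,
                 alpha = cf$alpha %||% p$alpha %||% 0)
  } else if (!is.null(p$r) && !is.null(p$rho_n) && !is.null(p$sigma) &&
             !is.null(p$n)) {
    derive_interday_params(
      intraday_params(p$r, p$rho_n, p$sigma, p$n),
      alpha = cf$alpha %||% p$alpha %||% 0
    )
  } else {
    stop_config("`params` must give either (kappa_n, mu_n[, n]) or ",
                "(r, rho_n, sigma, n).")
  }
}

config_schedule <- function(cf, horizon) {
  s <- cf$schedule %||% list(kind = "constant")
  switch(
    s$kind %||% "constant",
    constant = constant_schedule(horizon, drug = s$drug %||% 1),
    periodic = periodic_schedule(s$period %||% stop_config("periodic schedule needs `period`."),
                                 horizon),
    random = random_schedule(s$ar %||% stop_config("random schedule needs `ar`."),
                             horizon, seed = s$seed %||% cf$seed),
    none = constant_schedule(horizon, drug = 0),
    stop_config("unknown schedule kind: ", s$kind)
  )
}

run_meta <- function(cf) {
  list(config = cf, config_hash = rlang::hash(cf), seed = cf$seed %||% NULL,
       package = "plasmidstab", version = as.character(utils::packageVersion("plasmidstab")))
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname as_run_config
#' @param out_dir Output directory (created if needed).
#' @details `run_simulation()` needs `params` (either `kappa_n`/`mu_n` or
#'   `r`/`rho_n`/`sigma`/`n`), `horizon`, and optionally `alpha`, `x0`,
#'   `schedule` (`kind` = constant/periodic/random/none plus its parameters)
#'   and `threshold`; it writes `trajectory.csv` and `report.json`.
#' @export
run_simulation <- function(config, out_dir = ".") {
  cf <- as_run_config(config, required = c("params", "horizon"))
  params <- config_params(cf)
  sched <- config_schedule(cf, cf$horizon)
  traj <- simulate_trajectory(sched, params, x0 = cf$x0 %||% 0.5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "trajectory.csv")
  summary <- write_trajectory(traj, csv_path = csv,
                              threshold = cf$threshold %||% 1e-5)
  report <- c(run_meta(cf), summary)
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(trajectory = csv, report = file.path(out_dir, "report.json"),
                 summary = summary))
}

#' @rdname as_run_config
#' @details `run_estimation()` needs `growth_csv`, `competition_csv` and `n`
#'   (the known copy number of the focal plasmid), and optionally `plate_map`,
#'   `window`, `slope_fraction`; it writes `estimates.json` containing a
#'   growth-parameter table (`r`, `rho`, `sigma` and the bridged `mu_n`,
#'   `kappa_n`) and a per-concentration table of fitted `alpha`.
#' @export
run_estimation <- function(config, out_dir = ".") {
  cf <- as_run_config(config, required = c("growth_csv", "competition_csv", "n"))
  curves <- read_growth_csv(cf$growth_csv, plate_map = cf$plate_map)
  growth <- estimate_growth_params(curves, window = cf$window %||% 15,
                                   slope_fraction = cf$slope_fraction %||% 0.5)
  bridged <- derive_interday_params(
    intraday_params(growth$r, max(growth$rho, 0), growth$sigma, cf$n)
  )
  comp <- norm_competition(read_competition_csv(cf$competition_csv))
  if (!"drug" %in% names(comp)) comp$drug <- 0
  drugfree <- comp[comp$drug == 0, , drop = FALSE]
  kappa_fit <- fit_kappa(drugfree, mu_n = bridged$mu_n)
  doses <- sort(unique(comp$drug[comp$drug != 0]))
  alpha_tbl <- purrr::map_dfr(doses, function(dz) {
    fit <- suppressWarnings(
      fit_alpha(comp[comp$drug == dz, , drop = FALSE],
                kappa_n = kappa_fit$estimate, mu_n = bridged$mu_n)
    )
    tibble::tibble(drug_ugml = dz, kappa_n = kappa_fit$estimate,
                   alpha = fit$estimate, alpha_se = fit$se)
  })
  report <- c(run_meta(cf), list(
    growth_parameters = list(
      r = growth$r, rho = growth$rho, sigma = growth$sigma, n = cf$n,
      mu_n = bridged$mu_n, kappa_n = bridged$kappa_n
    ),
    competition_fit = list(kappa_n = kappa_fit$estimate,
                           kappa_n_se = kappa_fit$se),
    alpha_by_drug = alpha_tbl
  ))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "estimates.json")
  write_report(report, path)
  invisible(c(report, list(path = path)))
}

#' @rdname as_run_config
#' @details `run_sweep()` needs `pcn` and `per_copy_cost` grids, and
#'   optionally `horizon`, `x0`, `threshold`; it writes the tidy grid to
#'   `sweep.csv` plus `sweep_meta.json`.
#' @export
run_sweep <- function(config, out_dir = ".") {
  cf <- as_run_config(config, required = c("pcn", "per_copy_cost"))
  sweep <- stability_sweep(pcn = cf$pcn, per_copy_cost = cf$per_copy_cost,
                           horizon = cf$horizon %||% 500,
                           x0 = cf$x0 %||% 0.5,
                           threshold = cf$threshold %||% 1e-5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "sweep.csv")
  readr::write_csv(sweep, csv)
  write_report(run_meta(cf), file.path(out_dir, "sweep_meta.json"))
  invisible(list(sweep = csv, table = sweep))
}

#' @rdname as_run_config
#' @details `run_random_envs()` needs `n_envs`, `alpha`, `per_copy_cost` and
#'   `seed`, and optionally `horizon`, `pcn`; it writes the per-environment
#'   optimal-copy-number table to `random_envs.csv` plus metadata JSON.
#' @export
run_random_envs <- function(config, out_dir = ".") {
  cf <- as_run_config(config,
                      required = c("n_envs", "alpha", "per_copy_cost", "seed"))
  envs <- gen_environment_battery(cf$n_envs, horizon = cf$horizon %||% 1000,
                                  seed = cf$seed)
  study <- random_environment_study(envs, per_copy_cost = cf$per_copy_cost,
                                    alpha = cf$alpha,
                                    pcn = cf$pcn %||% 1:100,
                                    x0 = cf$x0 %||% 0.5,
                                    threshold = cf$threshold %||% 1e-5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "random_envs.csv")
  readr::write_csv(study, csv)
  write_report(run_meta(cf), file.path(out_dir, "random_envs_meta.json"))
  invisible(list(study = csv, table = study))
}

#' @rdname as_run_config
#' @details `run_synth()` needs `dir` and `seed`; it writes a full synthetic
#'   experiment bundle (growth + competition CSVs and the generating truth).
#' @export
run_synth <- function(config, out_dir = NULL) {
  cf <- as_run_config(config, required = c("dir", "seed"))
  paths <- write_experiment_bundle(cf$dir, seed = cf$seed,
                                   format = cf$format %||% "long")
  invisible(paths)
}
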