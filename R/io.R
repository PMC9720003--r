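#' Read and write plate-reader growth CSVs
#'
#' The long dialect has columns `time_h, well, od630` (plus optional
#' `strain`/`replicate`); the wide dialect has a `time_h` column and one OD
#' column per well, and requires a plate map (`well, strain, replicate` and
#' optionally `x0`, `drug_ugml`) to annotate wells. Both are returned in the
#' long annotated form the estimation functions consume.
#'
#' @param path CSV path.
#' @param plate_map Optional path to a plate-map CSV (required for wide
#'   files without `strain` annotation).
#' @return A tibble with columns `time_h`, `od630`, `strain`, `replicate`
#'   (and `well` when present).
#' @export
read_growth_csv <- function(path, plate_map = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(d) == 0) stop("empty growth CSV: ", path, call. = FALSE)
  map <- if (!is.null(plate_map)) readr::read_csv(plate_map, show_col_types = FALSE)
  if (!"time_h" %in% names(d))
    stop("growth CSV must have a `time_h` column.", call. = FALSE)
  if (!"od630" %in% names(d)) {
    # wide: every non-time column is a well
    d <- tidyr::pivot_longer(d, -"time_h", names_to = "well", values_to = "od630")
  }
  if (!"strain" %in% names(d)) {
    if (is.null(map))
      stop("growth CSV lacks `strain`; supply a plate map.", call. = FALSE)
    if (!all(c("well", "strain") %in% names(map)))
      stop("plate map needs `well` and `strain` columns.", call. = FALSE)
    d <- dplyr::inner_join(d, map, by = "well")
    if (nrow(d) == 0) stop("no wells shared between data and plate map.", call. = FALSE)
  }
  if (!"replicate" %in% names(d)) d$replicate <- d$well %||% 1L
  dplyr::arrange(d, .data$strain, .data$replicate, .data$time_h)
}

#' @rdname read_growth_csv
#' @param curves Long growth table (e.g. from [gen_growth_curves()]).
#' @param format `"long"` or `"wide"`; wide also writes `plate_map`.
#' @export
write_growth_csv <- function(curves, path, format = c("long", "wide"),
                             plate_map = NULL) {
  format <- match.arg(format)
  curves <- dplyr::mutate(curves,
                          well = paste0(.data$strain, .data$replicate))
  if (format == "long") {
    readr::write_csv(curves[, c("time_h", "well", "od630", "strain", "replicate")],
                     path)
  } else {
    wide <- tidyr::pivot_wider(curves[, c("time_h", "well", "od630")],
                               names_from = "well", values_from = "od630")
    readr::write_csv(wide, path)
    if (is.null(plate_map))
      stop("wide format needs a `plate_map` path to write.", call. = FALSE)
    readr::write_csv(dplyr::distinct(curves[, c("well", "strain", "replicate")]),
                     plate_map)
  }
  invisible(path)
}

#' Read and write competition-endpoint CSVs
#'
#' Columns `x0, drug_ugml, fluor_norm` (or `pf_final`), `replicate`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_competition_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(d) == 0) stop("empty competition CSV: ", path, call. = FALSE)
  if (!"x0" %in% names(d))
    stop("competition CSV must have an `x0` column.", call. = FALSE)
  d
}

#' @rdname read_competition_csv
#' @param records Competition table (e.g. from [gen_competition_table()]).
#' @export
write_competition_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and write schedule CSVs
#'
#' One row per day with columns `day` and `drug`; the schedule's kind and
#' generating parameters travel as `#`-prefixed comment lines.
#'
#' @param schedule A schedule (see [schedules]).
#' @param path CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  days <- schedule_days(schedule)
  meta <- c(
    kind = attr(schedule, "kind", exact = TRUE) %||% "custom",
    period = attr(schedule, "period", exact = TRUE),
    ar_target = attr(schedule, "ar_target", exact = TRUE),
    seed = attr(schedule, "seed", exact = TRUE),
    ar = antibiotic_rate(days), entropy = schedule_entropy(days)
  )
  header <- sprintf("# %s=%s", names(meta), vapply(meta, format, character(1)))
  writeLines(c(header, "day,drug",
               sprintf("%d,%d", seq_along(days), days)), path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  d <- readr::read_csv(I(grep("^#", lines, value = TRUE, invert = TRUE)),
                       show_col_types = FALSE)
  sched <- new_schedule(d$drug, kind = sub("^# kind=", "", meta_lines[1]))
  sched
}

#' Write a trajectory as CSV plus a JSON summary
#'
#' The CSV carries `day, x, drug`; the JSON echoes the generating parameters
#' and the stability summary ([classify_outcome()]).
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param threshold Extinction threshold passed to the summary.
#' @return Invisibly, the summary list.
#' @export
write_trajectory <- function(traj, csv_path = NULL, json_path = NULL,
                             threshold = 1e-5) {
  stopifnot(inherits(traj, "pb_trajectory"))
  if (!is.null(csv_path))
    readr::write_csv(as.data.frame(traj)[, c("day", "x", "drug")], csv_path)
  params <- attr(traj, "params", exact = TRUE)
  report <- suppressWarnings(classify_outcome(traj, threshold = threshold))
  summary <- list(
    params = params[c("n", "kappa_n", "mu_n", "alpha")],
    schedule_kind = attr(traj, "schedule_kind", exact = TRUE),
    horizon = max(traj$day),
    outcome = report$outcome, t_extinct = report$t_extinct,
    t_stabilize = report$t_stabilize, auc = report$auc,
    final_x = traj$x[nrow(traj)]
  )
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  invisible(summary)
}

#' Write a full synthetic experiment bundle
#'
#' Emits, into `dir`: `growth.csv` (long) or `growth.csv` + `plate_map.csv`
#' (wide), `competition.csv`, and `truth.json` with every generating
#' parameter — a complete self-describing synthetic experiment for exercising
#' the estimation pipeline.
#'
#' @param dir Output directory (created if needed).
#' @param growth_cfg A [growth_sim_config()].
#' @param params A [model_params()] for the competition table.
#' @param seed Seed splitting into growth/competition streams.
#' @param format Growth CSV dialect.
#' @param ... Passed to [gen_competition_table()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_experiment_bundle <- function(dir, growth_cfg = growth_sim_config(),
                                    params = pbgt_params(), seed = 1,
                                    format = c("long", "wide"), ...) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  growth_cfg$seed <- seed
  curves <- gen_growth_curves(growth_cfg)
  comp <- gen_competition_table(params, seed = seed + 1L, ...)
  paths <- list(growth = file.path(dir, "growth.csv"),
                competition = file.path(dir, "competition.csv"),
                truth = file.path(dir, "truth.json"))
  if (format == "wide") {
    paths$plate_map <- file.path(dir, "plate_map.csv")
    write_growth_csv(curves, paths$growth, "wide", paths$plate_map)
  } else {
    write_growth_csv(curves, paths$growth, "long")
  }
  write_competition_csv(comp, paths$competition)
  truth <- c(attr(curves, "truth"), attr(comp, "truth"), list(seed = seed))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Literature survey of plasmid copy numbers and costs
#'
#' Published copy-number and per-day fitness-cost measurements for natural and
#' laboratory plasmid-host pairs, shipped with the package for overlaying on
#' optimal-copy-number predictions.
#'
#' @return A tibble with columns `name`, `plasmid_type`, `species`, `pcn`,
#'   `pcn_sd`, `cost`, `cost_sd`, `reference`.
#' @export
#' @examples
#' literature_plasmids()
literature_plasmids <- function() {
  readr::read_csv(system.file("extdata", "plasmid_literature.csv",
                              package = "plasmidstab"),
                  show_col_types = FALSE)
}
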