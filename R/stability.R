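#' Time to extinction of a trajectory
#'
#' First day on which the PB fraction falls below `threshold`. The default
#' threshold 1e-5 corresponds to fewer than one plasmid-bearing cell at a
#' bottleneck of ~1e5 cells, the population size of the experiments the model
#' describes.
#'
#' @param traj A trajectory from [simulate_trajectory()] (or any data frame
#'   with `day` and `x` columns).
#' @param threshold Extinction threshold on the PB fraction, in (0, 1).
#' @return The day index, or `NA` if the fraction never crosses the threshold
#'   within the horizon.
#' @export
#' @examples
#' traj <- simulate_trajectory(constant_schedule(500, drug = 0), pbgt_params())
#' time_to_extinction(traj)
time_to_extinction <- function(traj, threshold = 1e-5) {
  stopifnot(is.data.frame(traj), all(c("day", "x") %in% names(traj)))
  stopifnot(threshold > 0, threshold < 1)
  hit <- which(traj$x < threshold)
  if (length(hit) == 0) NA_real_ else traj$day[hit[1]]
}

#' Area-under-the-curve persistence score
#'
#' Trapezoidal integral of the PB fraction over the trajectory, in day-units.
#' Unlike time-to-extinction it remains informative when the fraction tends to
#' a positive equilibrium or oscillates, which is why it serves as the
#' objective when optimising copy number across environments. Any log10
#' scaling for display is left to the caller.
#'
#' @inheritParams time_to_extinction
#' @return AUC in day-units, between 0 and the horizon.
#' @export
auc_stability <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("day", "x") %in% names(traj)))
  x <- traj$x
  d <- traj$day
  if (length(x) < 2) return(0)
  sum((x[-1] + x[-length(x)]) / 2 * diff(d))
}

#' Classify the long-run outcome of a trajectory
#'
#' Labels a trajectory `extinction` (the PB fraction crossed `threshold`),
#' `fixation` (it settled above `1 - threshold`), or `coexistence` (it settled
#' at an interior value); trajectories that have not settled by the end of the
#' horizon are `undetermined`, with a warning. Settling is detected on
#' stride-compared values: the trajectory has stabilised after the last day on
#' which `|x[day + stride] - x[day]| >= tol`. For a `T`-periodic environment
#' pass `stride = T` so values are compared phase to phase across cycles.
#'
#' @inheritParams time_to_extinction
#' @param tol Stabilisation tolerance on stride-compared fractions.
#' @param stride Day stride for the comparison (the period, for periodic
#'   schedules).
#' @return A one-row tibble with columns `outcome`, `t_extinct`, `t_stabilize`
#'   and `auc`.
#' @export
#' @examples
#' classify_outcome(simulate_trajectory(constant_schedule(200), pbgt_params(alpha = 0.6)))
classify_outcome <- function(traj, threshold = 1e-5, tol = 1e-6, stride = 1) {
  stopifnot(is.data.frame(traj), all(c("day", "x") %in% names(traj)))
  stopifnot(stride >= 1)
  x <- traj$x
  n <- length(x)
  t_ext <- time_to_extinction(traj, threshold)
  if (!is.na(t_ext)) {
    return(tibble::tibble(outcome = "extinction", t_extinct = t_ext,
                          t_stabilize = t_ext, auc = auc_stability(traj)))
  }
  if (n <= stride) stop("trajectory shorter than the comparison stride.", call. = FALSE)
  dx <- abs(x[(1 + stride):n] - x[seq_len(n - stride)])
  moving <- which(dx >= tol)
  t_stab <- if (length(moving) == 0) 0 else traj$day[moving[length(moving)] + 1]
  settled <- length(moving) == 0 || (moving[length(moving)] + stride) < n
  if (!settled) {
    warning("trajectory has not stabilised within the horizon.", call. = FALSE)
    return(tibble::tibble(outcome = "undetermined", t_extinct = NA_real_,
                          t_stabilize = NA_real_, auc = auc_stability(traj)))
  }
  outcome <- if (x[n] > 1 - threshold) "fixation" else "coexistence"
  tibble::tibble(outcome = outcome, t_extinct = NA_real_,
                 t_stabilize = t_stab, auc = auc_stability(traj))
}

# Vectorised-across-parameter-sets day loop. kappa/mu are parallel vectors
# (one entry per plasmid variant); drug is the 0/1 day sequence. Returns the
# running trapezoidal AUC, the first threshold-crossing day, and the final
# fraction. With absorb = TRUE a variant is held at 0 after crossing the
# threshold (fewer than one cell cannot be rescued by a later pulse).
sim_multi <- function(x0, drug, kappa, mu, alpha, threshold = 1e-5,
                      absorb = FALSE) {
  m <- length(kappa)
  stopifnot(length(mu) == m)
  x <- rep(x0, m)
  auc <- numeric(m)
  t_ext <- rep(NA_real_, m)
  omk <- 1 - kappa
  omm <- 1 - mu
  oma <- 1 - alpha
  for (i in seq_along(drug)) {
    xp <- x
    if (drug[i] == 1L) {
      x <- if (oma == 0) as.numeric(x > 0) else x / (x + oma * (1 - x))
    }
    x <- omk * x * omm / (omk * x + (1 - x))
    crossed <- is.na(t_ext) & x < threshold
    t_ext[crossed] <- i
    if (absorb) x[!is.na(t_ext)] <- 0
    auc <- auc + (xp + x) / 2
  }
  list(auc = auc, t_extinct = t_ext, x_final = x)
}

# Build the kappa/mu vectors for a copy-number grid at one per-copy cost,
# dropping (with a warning) grid points whose total cost reaches 1.
pcn_grid_params <- function(pcn, per_copy_cost, r, sigma) {
  keep <- pcn * per_copy_cost < 1
  if (!all(keep)) {
    warning(sprintf(
      "dropping %d copy-number value(s) with total cost >= 1.", sum(!keep)),
      call. = FALSE)
    pcn <- pcn[keep]
  }
  if (length(pcn) == 0) stop("no copy-number values with total cost < 1.", call. = FALSE)
  par <- lapply(pcn, params_for_pcn, per_copy_cost = per_copy_cost,
                r = r, sigma = sigma)
  list(pcn = pcn,
       kappa = vapply(par, `[[`, numeric(1), "kappa_n"),
       mu = vapply(par, `[[`, numeric(1), "mu_n"))
}

#' Minimum selective pressure across a copy-number grid
#'
#' For each copy number `n` in `pcn`, sets the total cost to
#' `per_copy_cost * n`, derives the matching segregational-loss rate through
#' the within-day bridge ([params_for_pcn()]) and evaluates
#' `MSalpha = kappa_n + mu_n (1 - kappa_n)`. For costly plasmids the curve is
#' nonmonotone in `n`: segregational loss dominates at low copy number, cost
#' at high copy number, so an intermediate copy number needs the least
#' selection.
#'
#' @param pcn Integer grid of plasmid copy numbers.
#' @param per_copy_cost Daily fitness cost per plasmid copy.
#' @param r,sigma Measured growth parameters held fixed across the grid.
#' @return A tibble with columns `n`, `kappa_n`, `mu_n`, `ms_alpha`.
#' @export
#' @examples
#' msalpha_curve(c(2, 19, 40), per_copy_cost = 0.0143)
msalpha_curve <- function(pcn = 1:100, per_copy_cost, r = 0.435435,
                          sigma = 6.074089) {
  g <- pcn_grid_params(pcn, per_copy_cost, r, sigma)
  tibble::tibble(
    n = g$pcn, kappa_n = g$kappa, mu_n = g$mu,
    ms_alpha = g$kappa + g$mu * (1 - g$kappa)
  )
}

#' Drug-free stability sweep over copy number and per-copy cost
#'
#' Simulates drug-free decay trajectories for every combination of copy
#' number and per-copy cost and reports time-to-extinction and the AUC
#' persistence score — the numerical experiment behind cost-by-copy-number
#' stability heatmaps.
#'
#' @param pcn Integer grid of plasmid copy numbers.
#' @param per_copy_cost Numeric grid of per-copy daily costs.
#' @param horizon Days to simulate (default 500, the long-term no-drug
#'   setting).
#' @param x0 Initial PB fraction.
#' @param threshold Extinction threshold.
#' @param r,sigma Measured growth parameters held fixed across the grid.
#' @return A tibble of class `pb_sweep`, one row per grid cell, with columns
#'   `n`, `per_copy_cost`, `kappa_n`, `mu_n`, `t_extinct`, `auc`.
#' @export
#' @examples
#' stability_sweep(c(2, 10, 19, 40), c(0.005, 0.0143), horizon = 200)
stability_sweep <- function(pcn = 1:100,
                            per_copy_cost = 10^seq(-3, -1, length.out = 20),
                            horizon = 500, x0 = 0.5, threshold = 1e-5,
                            r = 0.435435, sigma = 6.074089) {
  drug <- rep(0L, horizon)
  out <- purrr::map_dfr(per_copy_cost, function(cost) {
    g <- pcn_grid_params(pcn, cost, r, sigma)
    res <- sim_multi(x0, drug, g$kappa, g$mu, alpha = 0, threshold = threshold)
    tibble::tibble(n = g$pcn, per_copy_cost = cost, kappa_n = g$kappa,
                   mu_n = g$mu, t_extinct = res$t_extinct, auc = res$auc)
  })
  class(out) <- c("pb_sweep", class(out))
  out
}

#' Maximum drug-free rescue time across copy numbers
#'
#' Longest run of drug-free days a PB population can endure and still be
#' rescued by a subsequent strong pulse. A pulse with kill probability near 1
#' rescues any population that still contains at least one PB cell, so the
#' binding criterion is that the PB fraction has not yet crossed the
#' extinction threshold: the rescue time at copy number `n` is the largest
#' `d` with `x_d >= threshold` along the drug-free decay from `x0`.
#'
#' @inheritParams stability_sweep
#' @param per_copy_cost Single per-copy daily cost.
#' @return A tibble with columns `n` and `rescue_days` (`horizon` when the
#'   threshold is never crossed).
#' @export
#' @examples
#' max_rescue_time(c(2, 19, 40), per_copy_cost = 0.0143, horizon = 200)
max_rescue_time <- function(pcn = 1:100, per_copy_cost, horizon = 500,
                            x0 = 0.5, threshold = 1e-5,
                            r = 0.435435, sigma = 6.074089) {
  g <- pcn_grid_params(pcn, per_copy_cost, r, sigma)
  res <- sim_multi(x0, rep(0L, horizon), g$kappa, g$mu, alpha = 0,
                   threshold = threshold)
  rescue <- ifelse(is.na(res$t_extinct), horizon, res$t_extinct - 1)
  tibble::tibble(n = g$pcn, rescue_days = rescue)
}

#' Longest pulsing period that avoids plasmid loss
#'
#' Critical period of a periodic antibiotic environment: persistence holds for
#' all periods up to the returned value and fails beyond it (pulses are then
#' too far apart and the PB fraction crosses the extinction threshold between
#' them). Scans periods upward from 1; returns `NA` when even daily pulses
#' cannot maintain the plasmid (`alpha` below the constant-exposure minimum
#' selective pressure). Reported as the minimal pulsing *frequency* required
#' for maintenance: stronger selection (larger `alpha`) permits longer
#' periods.
#'
#' @param params A [model_params()] object; its `alpha` is the pulse strength.
#' @param threshold Extinction threshold on the PB fraction.
#' @param horizon Days simulated for each candidate period.
#' @param max_period Largest period scanned.
#' @param x0 Initial PB fraction.
#' @return The critical period in days, `NA` if `T = 1` already fails, or
#'   `max_period` (with a warning) if no failure is seen within the scan.
#' @export
#' @examples
#' min_period(pbgt_params(alpha = 0.99), horizon = 400, max_period = 20)
min_period <- function(params, threshold = 1e-5, horizon = 1000,
                       max_period = 100, x0 = 0.5) {
  stopifnot(inherits(params, "model_params"))
  persists <- function(T) {
    sched <- suppressWarnings(periodic_schedule(T, horizon))
    traj <- simulate_trajectory(sched, params, x0 = x0)
    !any(traj$x < threshold)
  }
  if (!persists(1L)) return(NA_real_)
  for (T in 2:max_period) {
    if (!persists(T)) return(T - 1)
  }
  warning("persistence holds up to `max_period`; returning it.", call. = FALSE)
  max_period
}

#' AUC persistence score across a copy-number grid for one environment
#'
#' Simulates every copy number in `pcn` (per-copy cost fixed) under the given
#' schedule and pulse strength and reports the AUC persistence score plus an
#' extinction flag. By default a variant whose fraction crosses the extinction
#' threshold is absorbed at zero — fewer than one cell cannot be rescued by a
#' later pulse — so long drug-free gaps genuinely kill high-cost variants.
#'
#' @param schedule A schedule (see [schedules]) or 0/1 vector.
#' @param per_copy_cost Daily fitness cost per plasmid copy.
#' @param alpha Per-pulse kill probability on drug days.
#' @param pcn Integer grid of plasmid copy numbers.
#' @param x0 Initial PB fraction.
#' @param threshold Extinction threshold.
#' @param absorb Hold variants at zero after crossing the threshold.
#' @param r,sigma Measured growth parameters held fixed across the grid.
#' @return A tibble with columns `n`, `auc`, `t_extinct`, `outcome`.
#' @export
#' @examples
#' pcn_auc_sweep(constant_schedule(200), 0.0143, alpha = 0.99, pcn = c(2, 19, 40))
pcn_auc_sweep <- function(schedule, per_copy_cost, alpha, pcn = 1:100,
                          x0 = 0.5, threshold = 1e-5, absorb = TRUE,
                          r = 0.435435, sigma = 6.074089) {
  drug <- schedule_days(schedule)
  g <- pcn_grid_params(pcn, per_copy_cost, r, sigma)
  res <- sim_multi(x0, drug, g$kappa, g$mu, alpha = alpha,
                   threshold = threshold, absorb = absorb)
  tibble::tibble(
    n = g$pcn, auc = res$auc, t_extinct = res$t_extinct,
    outcome = ifelse(is.na(res$t_extinct), "persistence", "extinction")
  )
}

#' Optimal plasmid copy number for an environment
#'
#' The copy number maximising the AUC persistence score under the given
#' schedule, cost and pulse strength ([pcn_auc_sweep()]). Ties are broken
#' toward the smallest copy number.
#'
#' @inheritParams pcn_auc_sweep
#' @return A single integer, the optimal copy number.
#' @export
#' @examples
#' optimal_pcn(constant_schedule(200, drug = 0), 0.0143, alpha = 0, pcn = 1:40)
optimal_pcn <- function(schedule, per_copy_cost, alpha, pcn = 1:100,
                        x0 = 0.5, threshold = 1e-5, absorb = TRUE,
                        r = 0.435435, sigma = 6.074089) {
  sweep <- pcn_auc_sweep(schedule, per_copy_cost, alpha, pcn = pcn, x0 = x0,
                         threshold = threshold, absorb = absorb,
                         r = r, sigma = sigma)
  sweep$n[which.max(sweep$auc)]
}

#' Optimal copy number across a battery of random environments
#'
#' For every random environment in `envs` and every pulse strength in
#' `alpha`, finds the optimal copy number and the fate of the optimal
#' trajectory, together with the environment's antibiotic rate, entropy and
#' High/Low class. This is the numerical experiment linking environmental
#' statistics to the distribution of optimal copy numbers.
#'
#' @param envs An environment battery from [gen_environment_battery()] (a
#'   tibble with an `env_id` column and a `schedule` list-column).
#' @param per_copy_cost Daily fitness cost per plasmid copy.
#' @param alpha Vector of pulse strengths to cross with the environments.
#' @inheritParams pcn_auc_sweep
#' @return A tibble with one row per environment x `alpha`: `env_id`,
#'   `alpha`, `ar`, `entropy`, `ar_class`, `pcn_opt`, `outcome`, `auc_opt`.
#' @export
#' @examples
#' envs <- gen_environment_battery(3, horizon = 300, seed = 1)
#' random_environment_study(envs, 0.0143, alpha = 0.99, pcn = seq(1, 60, 3))
random_environment_study <- function(envs, per_copy_cost, alpha,
                                     pcn = 1:100, x0 = 0.5, threshold = 1e-5,
                                     absorb = TRUE, r = 0.435435,
                                     sigma = 6.074089) {
  stopifnot(is.data.frame(envs), all(c("env_id", "schedule") %in% names(envs)))
  # truncate the copy-number grid once so each sweep does not re-warn
  keep <- pcn * per_copy_cost < 1
  if (!all(keep)) {
    warning(sprintf("dropping %d copy-number value(s) with total cost >= 1.",
                    sum(!keep)), call. = FALSE)
    pcn <- pcn[keep]
  }
  purrr::map_dfr(seq_len(nrow(envs)), function(i) {
    sched <- envs$schedule[[i]]
    purrr::map_dfr(alpha, function(a) {
      sweep <- pcn_auc_sweep(sched, per_copy_cost, a, pcn = pcn, x0 = x0,
                             threshold = threshold, absorb = absorb,
                             r = r, sigma = sigma)
      best <- which.max(sweep$auc)
      tibble::tibble(
        env_id = envs$env_id[i], alpha = a,
        ar = antibiotic_rate(sched), entropy = schedule_entropy(sched),
        ar_class = classify_ar(sched),
        pcn_opt = sweep$n[best], outcome = sweep$outcome[best],
        auc_opt = sweep$auc[best]
      )
    })
  })
}
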