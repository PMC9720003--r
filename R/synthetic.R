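#' Configuration for synthetic growth-curve experiments
#'
#' Defaults emulate a 96-well plate growth experiment with the reference
#' plasmid-host pair: PB cells growing at the measured 0.435435/h, PF cells
#' 0.052334/h faster, a 2-hour lag, a standard 1:100 LB inoculum (starting
#' OD630 0.01, carrying capacity 1.0), readings every 10 minutes for 24 hours,
#' three replicates, and multiplicative log-normal observation noise with
#' log-scale standard deviation 0.02.
#'
#' @param r_pb,r_pf Malthusian rates of the two strains (per hour).
#' @param lag Lag-phase duration (hours).
#' @param K Carrying-capacity OD.
#' @param od0 Inoculum OD (K > od0 > 0).
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   observation noise (0 for noiseless curves).
#' @param replicates Replicate wells per strain.
#' @param interval_min Sampling interval in minutes.
#' @param hours Experiment duration in hours.
#' @param seed Optional integer seed.
#' @return A list of class `growth_sim_config`.
#' @export
#' @examples
#' growth_sim_config(seed = 1)
growth_sim_config <- function(r_pb = 0.435435, r_pf = 0.435435 + 0.052334,
                              lag = 2, K = 1, od0 = 0.01, noise_sd = 0.02,
                              replicates = 3, interval_min = 10, hours = 24,
                              seed = NULL) {
  stopifnot(r_pb > 0, r_pf > 0, lag >= 0, K > od0, od0 > 0, noise_sd >= 0,
            replicates >= 1, interval_min > 0, hours > lag)
  structure(
    list(r_pb = r_pb, r_pf = r_pf, lag = lag, K = K, od0 = od0,
         noise_sd = noise_sd, replicates = as.integer(replicates),
         interval_min = interval_min, hours = hours, seed = seed),
    class = "growth_sim_config"
  )
}

# Lagged logistic: flat at od0 during the lag, then logistic growth from od0
# toward K at Malthusian rate r.
lagged_logistic <- function(t, r, lag, K, od0) {
  tau <- pmax(t - lag, 0)
  e <- exp(r * tau)
  K * od0 * e / (K + od0 * (e - 1))
}

#' Generate synthetic growth curves
#'
#' Lagged-logistic OD trajectories for the PB and PF strains with
#' multiplicative log-normal noise, in the long plate-reader format the
#' estimation functions read. The generating truth — including the implied
#' exponential-phase duration `log(K/od0)/r` for each strain, the time for the
#' culture to complete its fold-growth — is attached as the `truth` attribute.
#'
#' @param cfg A [growth_sim_config()].
#' @return A tibble with columns `time_h`, `od630`, `strain`, `replicate` and
#'   attribute `truth`.
#' @export
#' @examples
#' curves <- gen_growth_curves(growth_sim_config(seed = 1))
#' dplyr::count(curves, strain, replicate)
gen_growth_curves <- function(cfg) {
  stopifnot(inherits(cfg, "growth_sim_config"))
  times <- seq(0, cfg$hours, by = cfg$interval_min / 60)
  rates <- c(PB = cfg$r_pb, PF = cfg$r_pf)
  gen <- function() {
    purrr::map_dfr(names(rates), function(strain) {
      det <- lagged_logistic(times, rates[[strain]], cfg$lag, cfg$K, cfg$od0)
      purrr::map_dfr(seq_len(cfg$replicates), function(rep) {
        noise <- if (cfg$noise_sd > 0) {
          exp(stats::rnorm(length(times), 0, cfg$noise_sd))
        } else 1
        tibble::tibble(time_h = times, od630 = det * noise,
                       strain = strain, replicate = rep)
      })
    })
  }
  out <- if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
  attr(out, "truth") <- list(
    r_pb = cfg$r_pb, r_pf = cfg$r_pf, rho = cfg$r_pf - cfg$r_pb,
    lag = cfg$lag, K = cfg$K, od0 = cfg$od0,
    sigma_pb = log(cfg$K / cfg$od0) / cfg$r_pb,
    sigma_pf = log(cfg$K / cfg$od0) / cfg$r_pf
  )
  out
}

#' Generate a synthetic one-day competition table
#'
#' Endpoint PB fractions for mixtures started at each initial fraction in
#' `x0_grid` and exposed to each drug concentration named in `alpha_by_drug`:
#' the deterministic endpoint is the drug-free interday map at concentration 0
#' and the pulse-then-growth map otherwise, observed through truncated
#' Gaussian noise on the fraction scale (clipped to \[0, 1\]). The default
#' dose-to-alpha profile is the fitted pBGT panel over 0-6 ug/ml ampicillin,
#' including the negative low-dose values.
#'
#' @param params A [model_params()] object supplying `kappa_n` and `mu_n`.
#' @param alpha_by_drug Named numeric vector mapping drug concentration
#'   (ug/ml, as names) to pulse kill probability.
#' @param x0_grid Initial PB fractions.
#' @param noise_sd Standard deviation of the endpoint observation noise.
#' @param replicates Replicates per (x0, drug) cell.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x0`, `drug_ugml`, `fluor_norm`, `replicate`
#'   and attribute `truth` (the generating parameters and alpha profile).
#' @export
#' @examples
#' comp <- gen_competition_table(pbgt_params(), seed = 1)
#' head(comp)
gen_competition_table <- function(params,
                                  alpha_by_drug = c(`0` = 0, `1` = -0.37781,
                                                    `2` = -0.332662, `2.5` = -0.058457,
                                                    `3` = 0.992911, `3.5` = 0.9801,
                                                    `4` = 0.992075, `6` = 0.99373),
                                  x0_grid = seq(0.1, 0.9, length.out = 8),
                                  noise_sd = 0.02, replicates = 3, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(names(alpha_by_drug)) || any(names(alpha_by_drug) == ""))
    stop("`alpha_by_drug` must be named by drug concentration.", call. = FALSE)
  check_fraction(x0_grid, "x0_grid")
  grid <- tidyr::expand_grid(
    drug_ugml = as.numeric(names(alpha_by_drug)),
    x0 = x0_grid,
    replicate = seq_len(replicates)
  )
  alpha <- alpha_by_drug[match(grid$drug_ugml, as.numeric(names(alpha_by_drug)))]
  det <- vapply(seq_len(nrow(grid)), function(i) {
    pr <- model_params(params$n, params$kappa_n, params$mu_n, alpha = alpha[[i]])
    if (grid$drug_ugml[i] == 0) interday_map(grid$x0[i], pr)
    else pulsed_day_map(grid$x0[i], pr, method = "closed")
  }, numeric(1))
  gen <- function() {
    if (noise_sd > 0) pmin(pmax(det + stats::rnorm(length(det), 0, noise_sd), 0), 1)
    else det
  }
  y <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble::tibble(x0 = grid$x0, drug_ugml = grid$drug_ugml,
                        fluor_norm = y, replicate = grid$replicate)
  attr(out, "truth") <- list(kappa_n = params$kappa_n, mu_n = params$mu_n,
                             n = params$n, alpha_by_drug = alpha_by_drug,
                             noise_sd = noise_sd)
  out
}

#' Generate calibration mixtures
#'
#' Pairs of known PB fraction and observed normalized fluorescence for
#' calibrating the fluorescence-to-fraction conversion; fluorescence is
#' `intercept + slope * fraction` plus Gaussian noise.
#'
#' @param n Number of mixtures.
#' @param slope,intercept True calibration line.
#' @param noise_sd Fluorescence noise standard deviation.
#' @param seed Optional integer seed.
#' @return A tibble with columns `fraction` and `fluor`.
#' @export
gen_calibration_pairs <- function(n = 24, slope = 1, intercept = 0,
                                  noise_sd = 0.02, seed = NULL) {
  stopifnot(n >= 3)
  fraction <- seq(0, 1, length.out = n)
  gen <- function() intercept + slope * fraction +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  fluor <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tibble::tibble(fraction = fraction, fluor = fluor)
}

#' Generate a battery of random drug environments
#'
#' Draws `n_envs` independent random schedules, each with its own antibiotic
#' rate drawn from `ar_law` (uniform on \[0, 1\] by default, or a constant
#' rate), reproducibly from one seed.
#'
#' @param n_envs Number of environments, >= 1.
#' @param horizon Days per environment, >= 1.
#' @param ar_law `"uniform"` or `"constant"`.
#' @param ar Rate used when `ar_law = "constant"`.
#' @param seed Optional integer seed for the whole battery.
#' @return A tibble with columns `env_id`, `ar_target`, `ar`, `entropy`,
#'   `ar_class` and a `schedule` list-column of schedules.
#' @export
#' @examples
#' gen_environment_battery(3, horizon = 100, seed = 1)
gen_environment_battery <- function(n_envs, horizon = 1000,
                                    ar_law = c("uniform", "constant"),
                                    ar = 0.5, seed = NULL) {
  stopifnot(is.numeric(n_envs), n_envs >= 1)
  if (horizon < 1) stop("`horizon` must be >= 1.", call. = FALSE)
  ar_law <- match.arg(ar_law)
  gen <- function() {
    purrr::map_dfr(seq_len(n_envs), function(i) {
      ar_i <- if (ar_law == "uniform") stats::runif(1) else ar
      sched <- random_schedule(ar_i, horizon)
      tibble::tibble(env_id = i, ar_target = ar_i,
                     ar = antibiotic_rate(sched),
                     entropy = schedule_entropy(sched),
                     ar_class = classify_ar(sched),
                     schedule = list(sched))
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
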