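#' Drug-free interday map for the plasmid-bearing fraction
#'
#' One day of serial-dilution dynamics without antibiotics. A culture starting
#' the day with PB fraction `x` ends it with fraction
#' \deqn{f(x) = \frac{(1-\kappa_n)\,x\,(1-\mu_n)}{(1-\kappa_n)\,x + (1-x)},}
#' the PB subpopulation being discounted by its fitness cost `kappa_n` and
#' thinned by segregational loss `mu_n`. The bottleneck transfer is treated
#' deterministically (the bottleneck is large enough that sampling noise in
#' the transferred fraction is negligible).
#'
#' @param x PB fraction(s) in \[0, 1\]. Vectorised.
#' @param params A [model_params()] object.
#' @return The PB fraction(s) at the start of the next day.
#' @export
#' @examples
#' p <- pbgt_params()
#' interday_map(0.5, p)
interday_map <- function(x, params) {
  check_fraction(x, "x")
  stopifnot(inherits(params, "model_params"))
  omk <- 1 - params$kappa_n
  omk * x * (1 - params$mu_n) / (omk * x + (1 - x))
}

#' Antibiotic-pulse map
#'
#' Instantaneous effect of one antibiotic pulse: PF cells are killed with
#' probability `alpha` while PB cells all survive, so the PB fraction jumps
#' from `x` to `x / (x + (1 - alpha)(1 - x))`. With `alpha = 1` every PF cell
#' dies and any positive `x` maps to 1. Negative `alpha` (a PF advantage at
#' sub-inhibitory doses) is permitted.
#'
#' @param x PB fraction(s) in \[0, 1\]. Vectorised.
#' @param alpha Kill probability of PF cells, <= 1.
#' @return The PB fraction(s) immediately after the pulse.
#' @export
#' @examples
#' pulse_map(0.5, 0.5)  # 2/3
pulse_map <- function(x, alpha) {
  check_fraction(x, "x")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha > 1)
    stop("`alpha` must be a single value <= 1.", call. = FALSE)
  out <- x / (x + (1 - alpha) * (1 - x))
  # alpha = 1, x = 0 gives 0/0; the drug-only day leaves an empty PB class empty
  out[x == 0] <- 0
  out
}

#' Interday map on a drug day (pulse then growth)
#'
#' Composition of the pulse and the drug-free day, `f(g(x))`. The closed form
#' \deqn{\frac{(1-\kappa_n)\,x\,(1-\mu_n)}{(1-\alpha) + (\alpha-\kappa_n)\,x}}
#' is algebraically identical to the composition; `method` selects the route
#' (the two must agree to floating tolerance and are cross-checked in the test
#' suite).
#'
#' @inheritParams interday_map
#' @param method `"compose"` evaluates `interday_map(pulse_map(x))`;
#'   `"closed"` evaluates the closed form directly.
#' @return The PB fraction(s) at the start of the next day.
#' @export
#' @examples
#' pulsed_day_map(0.5, pbgt_params(alpha = 0.6))
pulsed_day_map <- function(x, params, method = c("compose", "closed")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "model_params"))
  if (method == "compose") {
    interday_map(pulse_map(x, params$alpha), params)
  } else {
    check_fraction(x, "x")
    a <- params$alpha
    omk <- 1 - params$kappa_n
    out <- omk * x * (1 - params$mu_n) / ((1 - a) + (a - params$kappa_n) * x)
    out[x == 0] <- 0
    out
  }
}

#' Simulate a trajectory of daily PB fractions
#'
#' Iterates the interday dynamics over a drug-exposure schedule: on days the
#' schedule marks as antibiotic days the pulse-then-growth map applies
#' ([pulsed_day_map()]), otherwise the drug-free map ([interday_map()]).
#'
#' @param schedule A schedule created by [periodic_schedule()],
#'   [random_schedule()] or [constant_schedule()], or a plain 0/1 vector.
#' @param params A [model_params()] object (its `alpha` applies on drug days).
#' @param x0 Initial PB fraction (day 0).
#' @param horizon Number of days to simulate; defaults to the schedule length
#'   and must not exceed it.
#' @return A tibble of class `pb_trajectory` with columns `day` (0..horizon),
#'   `x` (PB fraction at the start of the day) and `drug` (1 if the day's
#'   growth followed a pulse; 0 on day 0). The parameters are attached as the
#'   `params` attribute.
#' @export
#' @examples
#' traj <- simulate_trajectory(constant_schedule(50), pbgt_params(alpha = 0.6))
#' tail(traj)
simulate_trajectory <- function(schedule, params, x0 = 0.5, horizon = NULL) {
  drug <- schedule_days(schedule)
  stopifnot(inherits(params, "model_params"))
  check_fraction(x0, "x0")
  stopifnot(length(x0) == 1)
  if (is.null(horizon)) horizon <- length(drug)
  if (horizon < 1) stop("`horizon` must be >= 1.", call. = FALSE)
  if (horizon > length(drug))
    stop("schedule is shorter than the requested horizon.", call. = FALSE)
  drug <- drug[seq_len(horizon)]
  x <- sim_days(x0, drug, params$kappa_n, params$mu_n, params$alpha)
  out <- tibble::tibble(day = 0:horizon, x = x, drug = c(0L, as.integer(drug)))
  attr(out, "params") <- params
  attr(out, "schedule_kind") <- attr(schedule, "kind", exact = TRUE) %||% "custom"
  class(out) <- c("pb_trajectory", class(out))
  out
}

# Inner loop shared by the public simulators. Pure map iteration, no
# absorption: the deterministic recursion never reaches 0 exactly from x0 > 0.
sim_days <- function(x0, drug, kappa, mu, alpha) {
  H <- length(drug)
  x <- numeric(H + 1)
  x[1] <- xi <- x0
  omk <- 1 - kappa
  omm <- 1 - mu
  oma <- 1 - alpha
  for (i in seq_len(H)) {
    if (drug[i] == 1L && xi > 0) {
      xi <- if (oma == 0) 1 else xi / (xi + oma * (1 - xi))
    }
    xi <- omk * xi * omm / (omk * xi + (1 - xi))
    x[i + 1] <- xi
  }
  x
}

#' Interior steady state under daily pulses
#'
#' With the drug present every day (period 1) and `alpha > kappa_n`, the
#' pulsed map has the interior fixed point
#' \deqn{x^* = 1 - \frac{\mu_n (1-\kappa_n)}{\alpha - \kappa_n},}
#' reached from any starting fraction in (0, 1\]. The fixed point is positive
#' exactly when `alpha` exceeds the minimum selective pressure
#' ([min_selective_alpha()]); for `kappa_n < alpha <` MSalpha the formula is
#' negative, meaning no interior equilibrium exists and the plasmid is lost.
#'
#' @param params A [model_params()] object.
#' @return The fixed point, or `NA` when `alpha <= kappa_n`.
#' @export
#' @examples
#' steady_state(pbgt_params(alpha = 0.6))
steady_state <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$alpha <= params$kappa_n) return(NA_real_)
  1 - params$mu_n * (1 - params$kappa_n) / (params$alpha - params$kappa_n)
}

#' Minimum selective pressure for plasmid persistence
#'
#' The critical kill probability
#' \deqn{MS\alpha = \kappa_n + \mu_n (1 - \kappa_n)}
#' above which daily pulses maintain the plasmid at a positive equilibrium and
#' below which the PB fraction decays to zero. It is the model analogue of the
#' minimum selective concentration: since the PF strain's MIC corresponds to
#' `alpha = 1`, MSalpha is directly comparable to an MSC/MIC ratio.
#'
#' @param params A [model_params()] object.
#' @return The minimum selective `alpha`.
#' @export
#' @examples
#' min_selective_alpha(pbgt_params())
min_selective_alpha <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$kappa_n + params$mu_n * (1 - params$kappa_n)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be numeric in [0, 1].", name), call. = FALSE)
  invisible(x)
}
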