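#' Generator of the within-day two-type branching process
#'
#' The mean dynamics of the within-day growth phase follow a continuous-time
#' two-type branching process in which PF cells (type 0) divide at rate
#' `r + rho_n` and PB cells (type 1) at rate `r`, each PB division sending all
#' plasmid copies to one daughter with probability `2^-n` and thereby creating
#' a PF cell. The matrix of mean growth rates is
#' \deqn{A = \begin{pmatrix} r+\rho_n & 0 \\ r 2^{-n} & r(1 - 2^{-n}) \end{pmatrix}}
#' with index 0 = PF and 1 = PB, so that the mean matrix is `M(t) = exp(tA)`.
#'
#' @param p An [intraday_params()] object.
#' @return A 2x2 matrix with dimnames `PF`/`PB`; `A["PB","PF"]` is the mean
#'   rate at which PB founders shed PF cells.
#' @export
#' @examples
#' rate_matrix(pbgt_growth_params())
rate_matrix <- function(p) {
  stopifnot(inherits(p, "intraday_params"))
  loss <- p$r * 2^(-p$n)
  matrix(c(p$r + p$rho_n, loss, 0, p$r - loss),
         nrow = 2, dimnames = list(c("PF", "PB"), c("PF", "PB")))
}

#' Mean matrix of the within-day branching process
#'
#' Closed-form matrix exponential `M(t) = exp(tA)` of the two-type process:
#' `M[i, j]` is the expected number of type-`j` cells at time `t` descending
#' from one type-`i` founder (0 = PF, 1 = PB). PF founders never produce PB
#' cells, so `M[PF, PB] = 0` for all `t`. The off-diagonal entry is evaluated
#' through `expm1` so that the degenerate direction `r 2^-n + rho_n -> 0`
#' reduces smoothly to its analytic limit `r 2^-n t e^{rt}`.
#'
#' @param t Elapsed time in hours, >= 0.
#' @param p An [intraday_params()] object.
#' @return A 2x2 matrix with dimnames `PF`/`PB`.
#' @export
#' @examples
#' mean_matrix(6.074089, pbgt_growth_params())
mean_matrix <- function(t, p) {
  stopifnot(inherits(p, "intraday_params"))
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  loss <- p$r * 2^(-p$n)          # r 2^-n, the mean PF-shedding rate
  d <- loss + p$rho_n             # gap between the two diagonal rates
  m00 <- exp((p$r + p$rho_n) * t)
  m11 <- exp((p$r - loss) * t)
  scale <- if (d == 0) t else expm1(d * t) / d
  m10 <- loss * m11 * scale
  matrix(c(m00, m10, 0, m11),
         nrow = 2, dimnames = list(c("PF", "PB"), c("PF", "PB")))
}

#' Duration of the within-day growth phase
#'
#' Time for the culture to expand `gamma`-fold from the bottleneck. The
#' default `"approx"` mode uses `log(gamma) / r`, accurate when the PF
#' advantage is small relative to `r`. The `"exact"` mode solves for the time
#' at which the expected number of descendants per founding cell reaches
#' `gamma`, i.e. the root of
#' `x0 (M[PB,PF] + M[PB,PB]) + (1 - x0) M[PF,PF] = gamma`.
#'
#' @param p An [intraday_params()] object.
#' @param x0 PB fraction among the founding cells (used by `"exact"` mode).
#' @param mode `"approx"` or `"exact"`.
#' @return Duration in hours.
#' @export
#' @examples
#' growth_duration(pbgt_growth_params())
#' growth_duration(pbgt_growth_params(), x0 = 1, mode = "exact")
growth_duration <- function(p, x0 = 1, mode = c("approx", "exact")) {
  stopifnot(inherits(p, "intraday_params"))
  mode <- match.arg(mode)
  if (mode == "approx") return(log(p$gamma) / p$r)
  check_fraction(x0, "x0")
  expectation <- function(t) {
    M <- mean_matrix(t, p)
    x0 * (M["PB", "PF"] + M["PB", "PB"]) + (1 - x0) * M["PF", "PF"] - p$gamma
  }
  upper <- (log(p$gamma) + 30) / (p$r * (1 - 2^(-p$n)))
  root <- tryCatch(
    stats::uniroot(expectation, c(0, upper), tol = 1e-10),
    error = function(e) stop("saturation time not bracketed: ", conditionMessage(e),
                             call. = FALSE)
  )
  root$root
}

#' PB fraction at the end of a growth day
#'
#' Expected PB fraction after `sigma` hours of within-day growth started from
#' PB fraction `x`, computed from the mean-matrix ratio
#' \deqn{\frac{x M_{11}}{(1-x)(M_{00}+M_{01}) + x (M_{10}+M_{11})}.}
#' Substituting the bridge parameters of [derive_interday_params()] into the
#' drug-free interday map reproduces this quantity identically; that exact
#' correspondence is what lets experimentally measured `(r, rho_n, sigma)`
#' parameterise the day-scale model.
#'
#' @param x PB fraction(s) at the start of the day. Vectorised.
#' @param p An [intraday_params()] object.
#' @return PB fraction(s) at the end of the day.
#' @export
#' @examples
#' end_of_day_fraction(0.5, pbgt_growth_params())
end_of_day_fraction <- function(x, p) {
  stopifnot(inherits(p, "intraday_params"))
  check_fraction(x, "x")
  M <- mean_matrix(p$sigma, p)
  num <- x * M["PB", "PB"]
  den <- (1 - x) * (M["PF", "PF"] + M["PF", "PB"]) +
    x * (M["PB", "PF"] + M["PB", "PB"])
  num / den
}

#' Bridge from within-day growth to interday parameters
#'
#' Maps the measurable within-day quantities `(r, rho_n, sigma, n)` onto the
#' interday segregational-loss probability and fitness cost. Writing
#' `s = r 2^-n + rho_n`,
#' \deqn{\mu_n = 1 - \frac{s}{r 2^{-n} e^{s\sigma} + \rho_n}, \qquad
#'       \kappa_n = \frac{\rho_n (1 - e^{-s\sigma})}{s}.}
#' With these parameters the drug-free interday map equals
#' [end_of_day_fraction()] exactly for every starting fraction.
#'
#' @param p An [intraday_params()] object.
#' @param alpha Per-pulse kill probability carried into the result.
#' @return A [model_params()] object.
#' @export
#' @examples
#' derive_interday_params(pbgt_growth_params())  # mu_19 ~ 5.94e-6, kappa_19 ~ 0.2723
derive_interday_params <- function(p, alpha = 0) {
  stopifnot(inherits(p, "intraday_params"))
  loss <- p$r * 2^(-p$n)
  s <- loss + p$rho_n
  # cancellation-free: 1 - s/(a e^{s sigma} + rho) == a expm1(s sigma) / (...)
  mu <- loss * expm1(s * p$sigma) / (loss * exp(s * p$sigma) + p$rho_n)
  kappa <- if (p$rho_n == 0) 0 else p$rho_n * (-expm1(-s * p$sigma)) / s
  model_params(n = p$n, kappa_n = kappa, mu_n = mu, alpha = alpha)
}

#' Growth-rate advantage implied by a daily fitness cost
#'
#' Inverse of the cost half of the bridge in the regime where segregational
#' loss is negligible (`r 2^-n << rho_n`): a per-day cost `kappa_n` accrued
#' over a growth phase of `sigma` hours corresponds to a PF Malthusian
#' advantage of `-log(1 - kappa_n) / sigma` per hour. Used to drive copy-number
#' sweeps from a single per-copy cost; round-tripping through
#' [derive_interday_params()] recovers `kappa_n` to about `2^-n`-sized error.
#'
#' @param kappa_n Per-day fitness cost, in \[0, 1).
#' @param sigma Growth-phase duration in hours.
#' @return PF growth advantage in per hour.
#' @export
#' @examples
#' rho_from_kappa(0.272313, 6.074089)  # ~0.05233, the measured advantage
rho_from_kappa <- function(kappa_n, sigma) {
  if (any(kappa_n < 0) || any(kappa_n >= 1))
    stop("`kappa_n` must be in [0, 1).", call. = FALSE)
  stopifnot(is.numeric(sigma), sigma > 0)
  -log1p(-kappa_n) / sigma
}

#' Interday parameters for a copy-number sweep
#'
#' Builds the interday parameters of a hypothetical plasmid with `n` copies
#' and per-copy daily cost `per_copy_cost`, holding the host's growth
#' physiology (`r`, `sigma`) fixed at measured values. The total cost is
#' `kappa_n = per_copy_cost * n`; the implied PF growth advantage
#' `rho_n = rho_from_kappa(kappa_n, sigma)` then yields `mu_n` through the
#' bridge, so that a single per-copy cost consistently drives both the
#' linear-in-`n` cost and the exponentially-decaying-in-`n` loss rate.
#'
#' @param n Plasmid copy number (single integer).
#' @param per_copy_cost Daily fitness cost per plasmid copy; `n * per_copy_cost`
#'   must be < 1.
#' @param r PB Malthusian rate (per hour). Defaults to the pBGT measurement.
#' @param sigma Growth-phase duration (hours). Defaults to the pBGT measurement.
#' @param alpha Per-pulse kill probability carried into the result.
#' @return A [model_params()] object.
#' @export
#' @examples
#' params_for_pcn(19, 0.0143)
params_for_pcn <- function(n, per_copy_cost, r = 0.435435, sigma = 6.074089,
                           alpha = 0) {
  stopifnot(length(n) == 1, n >= 1)
  kappa <- per_copy_cost * n
  if (kappa < 0 || kappa >= 1)
    stop("total cost `per_copy_cost * n` must be in [0, 1).", call. = FALSE)
  rho <- rho_from_kappa(kappa, sigma)
  loss <- r * 2^(-n)
  s <- loss + rho
  mu <- loss * expm1(s * sigma) / (loss * exp(s * sigma) + rho)
  model_params(n = n, kappa_n = kappa, mu_n = mu, alpha = alpha)
}
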