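#' Interday model parameters
#'
#' Bundle the parameters of the day-to-day recursion for the plasmid-bearing
#' (PB) fraction of a serially diluted culture: the plasmid copy number `n`,
#' the total per-day fitness cost of carriage `kappa_n`, the per-day
#' probability `mu_n` that a PB lineage segregates to plasmid-free (PF), and
#' the per-pulse kill probability `alpha` of PF cells under antibiotic
#' exposure.
#'
#' `alpha` is nominally in \[0, 1\] (the PF minimum inhibitory concentration
#' corresponds to `alpha = 1`), but negative values are accepted: a negative
#' `alpha` encodes a PF advantage at sub-inhibitory drug concentrations, as
#' observed when fitting competition data at low doses.
#'
#' @param n Plasmid copy number, integer >= 1.
#' @param kappa_n Per-day fitness cost of plasmid carriage, in \[0, 1).
#' @param mu_n Per-day segregational-loss probability, in \[0, 1).
#' @param alpha Per-pulse kill probability of plasmid-free cells, <= 1.
#'
#' @return An object of class `model_params`.
#' @seealso [derive_interday_params()] to obtain `kappa_n` and `mu_n` from
#'   measurable growth quantities, [pbgt_params()] for the reference plasmid.
#' @export
#' @examples
#' model_params(n = 19, kappa_n = 0.272313, mu_n = 5.938e-6, alpha = 0.6)
model_params <- function(n, kappa_n, mu_n, alpha = 0) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (!is.numeric(kappa_n) || length(kappa_n) != 1 || kappa_n < 0 || kappa_n >= 1)
    stop("`kappa_n` must be a single value in [0, 1).", call. = FALSE)
  if (!is.numeric(mu_n) || length(mu_n) != 1 || mu_n < 0 || mu_n >= 1)
    stop("`mu_n` must be a single value in [0, 1).", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha > 1)
    stop("`alpha` must be a single value <= 1.", call. = FALSE)
  structure(
    list(n = as.integer(round(n)), kappa_n = kappa_n, mu_n = mu_n, alpha = alpha),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Interday model parameters\n")
  cat(sprintf("  n (copy number):        %d\n", x$n))
  cat(sprintf("  kappa_n (fitness cost): %.6g /day\n", x$kappa_n))
  cat(sprintf("  mu_n (segregant rate):  %.6g /day\n", x$mu_n))
  cat(sprintf("  alpha (pulse kill):     %.6g\n", x$alpha))
  invisible(x)
}

#' Within-day branching-process parameters
#'
#' Parameters of the continuous-time two-type branching process describing
#' within-day growth: PB cells divide at Malthusian rate `r` per hour and PF
#' cells at `r + rho_n`; a PB division produces one PF daughter with
#' probability `2^-n` (all plasmid copies segregating to one cell). Growth
#' lasts `sigma` hours, the time for the culture to expand `gamma`-fold from
#' the bottleneck size `N` to saturation.
#'
#' @param r Malthusian rate of PB cells (per hour), > 0.
#' @param rho_n Malthusian advantage of PF cells (per hour), >= 0.
#' @param sigma Duration of the growth phase (hours), > 0.
#' @param n Plasmid copy number, integer >= 1.
#' @param gamma Fold-growth from bottleneck to saturation, > 1. Only used by
#'   [growth_duration()]; the default 1000 corresponds to a 1:1000 daily
#'   dilution.
#' @param N Bottleneck population size (cells).
#'
#' @return An object of class `intraday_params`.
#' @export
#' @examples
#' intraday_params(r = 0.435435, rho_n = 0.052334, sigma = 6.074089, n = 19)
intraday_params <- function(r, rho_n, sigma, n, gamma = 1000, N = 1e5) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0)
  stopifnot(is.numeric(rho_n), length(rho_n) == 1, rho_n >= 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 1)
  structure(
    list(r = r, rho_n = rho_n, sigma = sigma, n = as.integer(round(n)),
         gamma = gamma, N = N),
    class = "intraday_params"
  )
}

#' @export
print.intraday_params <- function(x, ...) {
  cat("Within-day branching-process parameters\n")
  cat(sprintf("  r:     %.6g /h   (PB Malthusian rate)\n", x$r))
  cat(sprintf("  rho_n: %.6g /h   (PF advantage)\n", x$rho_n))
  cat(sprintf("  sigma: %.6g h    (growth-phase duration)\n", x$sigma))
  cat(sprintf("  n:     %d        (copy number)\n", x$n))
  cat(sprintf("  gamma: %.6g      (fold-growth), N: %.3g cells\n", x$gamma, x$N))
  invisible(x)
}

#' Reference parameters for the pBGT plasmid
#'
#' Measured growth parameters for *Escherichia coli* K12 carrying pBGT, a
#' ColE1-like multicopy plasmid (~19 copies per cell) encoding a TEM-1
#' beta-lactamase: PB growth rate `r = 0.435435`/h, PF growth advantage
#' `rho_n = 0.052334`/h, exponential-phase duration `sigma = 6.074089` h.
#'
#' @param alpha Per-pulse kill probability passed through to the derived
#'   interday parameters.
#' @return `pbgt_growth_params()` returns an [intraday_params()] object;
#'   `pbgt_params()` returns the corresponding [model_params()] (with
#'   `kappa_n` and `mu_n` computed through the within-day bridge).
#' @export
#' @examples
#' pbgt_params(alpha = 0.6)
pbgt_growth_params <- function() {
  intraday_params(r = 0.435435, rho_n = 0.052334, sigma = 6.074089, n = 19,
                  gamma = exp(0.435435 * 6.074089), N = 1e5)
}

#' @rdname pbgt_growth_params
#' @export
pbgt_params <- function(alpha = 0) {
  derive_interday_params(pbgt_growth_params(), alpha = alpha)
}
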