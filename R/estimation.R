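#' Fit objects
#'
#' Light container for single-parameter least-squares fits returned by the
#' estimation functions. Supports [generics::tidy()] and [generics::glance()].
#'
#' @param estimate Fitted value.
#' @param se Standard error.
#' @param residual_ss Residual sum of squares.
#' @param n_obs Observations used.
#' @param term Parameter name.
#' @param extra Named list of method-specific extras (e.g. intercept,
#'   r.squared, window placement).
#' @return An object of class `pb_fit`.
#' @keywords internal
new_pb_fit <- function(estimate, se, residual_ss, n_obs, term, extra = list()) {
  structure(
    c(list(estimate = estimate, se = se, residual_ss = residual_ss,
           n_obs = n_obs, term = term), extra),
    class = "pb_fit"
  )
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Least-squares fit of %s\n", x$term))
  cat(sprintf("  estimate: %.6g (se %.3g)\n", x$estimate, x$se))
  cat(sprintf("  residual SS: %.3g on %d observations\n", x$residual_ss, x$n_obs))
  invisible(x)
}

# Map tolerant column naming onto (time, od): accepts time_h/time and
# od630/od/OD630.
norm_growth_cols <- function(curve) {
  nms <- tolower(names(curve))
  tcol <- match(TRUE, nms %in% c("time_h", "time", "t"))
  ocol <- match(TRUE, nms %in% c("od630", "od", "od600"))
  if (is.na(tcol) || is.na(ocol))
    stop("growth curve needs a time column (`time_h`) and an OD column (`od630`).",
         call. = FALSE)
  out <- tibble::tibble(time = curve[[tcol]], od = curve[[ocol]])
  if ("replicate" %in% nms) out$replicate <- curve[[which(nms == "replicate")[1]]]
  out
}

# Replicate-averaged log-OD series: floor the (optionally blank-corrected)
# readings, log them, and average across replicates at each time point.
log_od_series <- function(curve, blank = 0, floor = 1e-4) {
  d <- norm_growth_cols(curve)
  if (any(!is.finite(d$od)) || all(d$od <= blank))
    stop("OD readings must be finite and exceed the blank.", call. = FALSE)
  d$log_od <- log(pmax(d$od - blank, floor))
  d <- dplyr::summarise(dplyr::group_by(d, .data$time),
                        log_od = mean(.data$log_od), .groups = "drop")
  dplyr::arrange(d, .data$time)
}

# OLS slope/intercept/se over each window of `w` consecutive points.
rolling_slopes <- function(time, y, w) {
  n <- length(time)
  k <- n - w + 1
  slope <- se <- rss <- mid <- t0 <- t1 <- numeric(k)
  for (i in seq_len(k)) {
    idx <- i:(i + w - 1)
    t <- time[idx]; yy <- y[idx]
    tc <- t - mean(t)
    sxx <- sum(tc^2)
    b <- sum(tc * yy) / sxx
    resid <- yy - mean(yy) - b * tc
    rss[i] <- sum(resid^2)
    se[i] <- sqrt(rss[i] / (w - 2) / sxx)
    slope[i] <- b
    mid[i] <- mean(t); t0[i] <- t[1]; t1[i] <- t[w]
  }
  tibble::tibble(slope = slope, se = se, rss = rss, mid = mid, t0 = t0, t1 = t1)
}

#' Maximum growth rate from a growth curve
#'
#' Slides an ordinary-least-squares window over log OD versus time and returns
#' the steepest slope — the maximal per-hour Malthusian rate of the strain. If
#' the curve carries replicates they are averaged on the log scale first. The
#' 15-point default window (2.3 h at 10-minute sampling) balances slope
#' precision against the curvature bias of including near-saturation readings.
#'
#' @param curve Data frame with columns `time_h` and `od630` (`time`/`od`
#'   also accepted) and optionally `replicate`; one strain per call.
#' @param window Points per regression window, >= 4.
#' @param blank Background OD subtracted before logging (default none).
#' @param floor Lower bound applied before logging.
#' @return A `pb_fit` whose `estimate` is the maximum slope (per hour); the
#'   fitted window's placement is kept in `window_start`/`window_end`.
#' @export
#' @examples
#' curve <- data.frame(time_h = seq(0, 5, 1/6), od630 = 0.01 * exp(0.435 * seq(0, 5, 1/6)))
#' fit_max_growth_rate(curve)$estimate
fit_max_growth_rate <- function(curve, window = 15, blank = 0, floor = 1e-4) {
  stopifnot(window >= 4)
  d <- log_od_series(curve, blank, floor)
  if (nrow(d) < window)
    stop("growth curve has fewer points than the regression window.", call. = FALSE)
  win <- rolling_slopes(d$time, d$log_od, window)
  best <- which.max(win$slope)
  if (win$slope[best] <= sqrt(.Machine$double.eps))
    stop("no growth detected: maximum log-OD slope is not positive.", call. = FALSE)
  new_pb_fit(win$slope[best], win$se[best], win$rss[best], window,
             term = "max_growth_rate",
             extra = list(window_start = win$t0[best], window_end = win$t1[best]))
}

#' Duration of the exponential phase
#'
#' Operationalises "start of exponential phase to reaching carrying capacity"
#' as the time between the first and last window whose local log-OD slope is
#' at least `slope_fraction` of the maximum slope. A curve qualifies as having
#' an exponential phase only if log OD gains at least one e-fold across that
#' span; linear or flat series fail this check and raise an error.
#'
#' @inheritParams fit_max_growth_rate
#' @param slope_fraction Fraction of the maximum slope delimiting the phase.
#' @return Duration in hours, with attributes `start` and `end` (window
#'   midpoints) and `max_slope`.
#' @export
#' @examples
#' tt <- seq(0, 24, 1/6)
#' curve <- data.frame(time_h = tt, od630 = 0.01 * exp(0.4354 * pmin(tt, 10)))
#' estimate_sigma(curve)
estimate_sigma <- function(curve, slope_fraction = 0.5, window = 15,
                           blank = 0, floor = 1e-4) {
  stopifnot(slope_fraction > 0, slope_fraction < 1)
  d <- log_od_series(curve, blank, floor)
  if (nrow(d) < window)
    stop("growth curve has fewer points than the regression window.", call. = FALSE)
  win <- rolling_slopes(d$time, d$log_od, window)
  mx <- max(win$slope)
  if (mx <= sqrt(.Machine$double.eps))
    stop("no exponential phase detected: maximum log-OD slope is not positive.",
         call. = FALSE)
  in_phase <- which(win$slope >= slope_fraction * mx)
  first <- in_phase[1]; last <- in_phase[length(in_phase)]
  gain <- max(d$log_od[d$time >= win$t0[first] & d$time <= win$t1[last]]) -
    min(d$log_od[d$time >= win$t0[first] & d$time <= win$t1[last]])
  if (gain < 1)
    stop("no exponential phase detected: less than one e-fold of growth ",
         "within the candidate phase.", call. = FALSE)
  out <- win$mid[last] - win$mid[first]
  attr(out, "start") <- win$mid[first]
  attr(out, "end") <- win$mid[last]
  attr(out, "max_slope") <- mx
  out
}

#' Growth parameters from paired strain curves
#'
#' Convenience wrapper: maximum growth rate of the PB strain (`r`), the PF
#' excess over PB (`rho`), and the PB exponential-phase duration (`sigma`)
#' from a long-format table of both strains' curves.
#'
#' @param curves Data frame with columns `time_h`, `od630`, `strain`
#'   (`"PB"`/`"PF"`) and optionally `replicate`.
#' @inheritParams fit_max_growth_rate
#' @param slope_fraction Passed to [estimate_sigma()].
#' @return A one-row tibble with columns `r`, `rho`, `sigma` and the two
#'   strains' standard errors.
#' @export
estimate_growth_params <- function(curves, window = 15, slope_fraction = 0.5,
                                   blank = 0, floor = 1e-4) {
  stopifnot("strain" %in% names(curves))
  pb <- curves[curves$strain == "PB", , drop = FALSE]
  pf <- curves[curves$strain == "PF", , drop = FALSE]
  if (nrow(pb) == 0 || nrow(pf) == 0)
    stop("`curves` must contain both PB and PF strains.", call. = FALSE)
  fit_pb <- fit_max_growth_rate(pb, window, blank, floor)
  fit_pf <- fit_max_growth_rate(pf, window, blank, floor)
  sig <- estimate_sigma(pb, slope_fraction, window, blank, floor)
  tibble::tibble(
    r = fit_pb$estimate, r_se = fit_pb$se,
    rho = fit_pf$estimate - fit_pb$estimate,
    rho_se = sqrt(fit_pb$se^2 + fit_pf$se^2),
    sigma = as.numeric(sig)
  )
}

#' Fluorescence-to-fraction calibration
#'
#' Ordinary least-squares line relating normalized fluorescence intensity to
#' the known PB fraction of calibration mixtures, used to convert endpoint
#' fluorescence readings into PB fractions (predictions are clipped to
#' \[0, 1\] by [apply_calibration()]).
#'
#' @param pairs Data frame with columns `fluor` (normalized fluorescence) and
#'   `fraction` (true PB fraction); >= 3 rows.
#' @return A `pb_fit` with `estimate` = slope and extras `intercept` and
#'   `r.squared`.
#' @export
#' @examples
#' pairs <- data.frame(fluor = seq(0, 1, 0.1), fraction = seq(0, 1, 0.1))
#' calibrate_fluorescence(pairs)$r.squared
calibrate_fluorescence <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("fluor", "fraction") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 calibration pairs.", call. = FALSE)
  if (stats::var(pairs$fluor) == 0)
    stop("degenerate calibration: fluorescence has zero variance.", call. = FALSE)
  fit <- stats::lm(fraction ~ fluor, data = pairs)
  sm <- summary(fit)
  new_pb_fit(stats::coef(fit)[["fluor"]], sm$coefficients["fluor", "Std. Error"],
             sum(stats::residuals(fit)^2), nrow(pairs),
             term = "calibration_slope",
             extra = list(intercept = stats::coef(fit)[["(Intercept)"]],
                          r.squared = sm$r.squared))
}

#' @rdname calibrate_fluorescence
#' @param fluor Fluorescence readings to convert.
#' @param fit A fit from `calibrate_fluorescence()`.
#' @export
apply_calibration <- function(fluor, fit) {
  stopifnot(inherits(fit, "pb_fit"), identical(fit$term, "calibration_slope"))
  pmin(pmax(fit$intercept + fit$estimate * fluor, 0), 1)
}

# Normalise competition records to (x0, y[, drug]); y may arrive as y,
# fluor_norm, pb_final or pf_final (the latter converted to a PB fraction).
norm_competition <- function(records) {
  nms <- names(records)
  if (!"x0" %in% nms) stop("competition records need an `x0` column.", call. = FALSE)
  ycol <- intersect(c("y", "fluor_norm", "pb_final", "pf_final"), nms)[1]
  if (is.na(ycol)) stop("competition records need an endpoint column ",
                        "(`fluor_norm`, `pb_final` or `pf_final`).", call. = FALSE)
  y <- records[[ycol]]
  if (ycol == "pf_final") y <- 1 - y
  out <- tibble::tibble(x0 = records$x0, y = y)
  dcol <- intersect(c("drug", "drug_ugml"), nms)[1]
  if (!is.na(dcol)) out$drug <- records[[dcol]]
  check_fraction(out$x0, "x0")
  check_fraction(out$y, "y")
  out
}

check_competition_design <- function(rec) {
  if (length(unique(rec$x0)) < 2)
    stop("need at least 2 distinct initial fractions.", call. = FALSE)
  if (!any(rec$x0 > 0 & rec$x0 < 1))
    stop("no interior initial fractions: endpoints x0 = 0 and 1 carry no ",
         "information about the fitted parameter.", call. = FALSE)
}

# One-parameter least squares via Brent, with a curvature-based standard
# error: var(theta) ~ 2 sigma^2 / d2SSR (Gauss-Newton at the optimum). The
# second derivative is taken on a stencil shifted to stay inside the feasible
# interval when the optimum sits on a boundary.
ls_fit_1d <- function(ssr, interval, term, n_obs, tol = 1e-10) {
  opt <- stats::optimize(ssr, interval, tol = tol)
  h <- max(1e-6, 1e-5 * abs(opt$minimum))
  centre <- min(max(opt$minimum, interval[1] + h), interval[2] - h)
  d2 <- (ssr(centre + h) - 2 * ssr(centre) + ssr(centre - h)) / h^2
  sigma2 <- opt$objective / max(n_obs - 1, 1)
  se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  new_pb_fit(opt$minimum, se, opt$objective, n_obs, term)
}

#' Plasmid cost from drug-free competition endpoints
#'
#' Least-squares fit of the fitness cost `kappa_n` in the drug-free interday
#' map to one-day competition endpoints: each record contributes
#' `(y - f(x0; kappa_n, mu_n))^2`, with the segregational-loss probability
#' held fixed (it is orders of magnitude below endpoint noise and cannot be
#' identified from one day of competition).
#'
#' @param records Data frame with columns `x0` and an endpoint column
#'   (`fluor_norm`, `pb_final` or `pf_final`); if a `drug` column is present
#'   it must be all zero.
#' @param mu_n Fixed per-day segregational-loss probability.
#' @return A `pb_fit` for `kappa_n`, bounded to \[0, 1).
#' @export
#' @examples
#' p <- pbgt_params()
#' rec <- data.frame(x0 = seq(0.1, 0.9, 0.1))
#' rec$pb_final <- interday_map(rec$x0, p)
#' fit_kappa(rec, mu_n = p$mu_n)$estimate
fit_kappa <- function(records, mu_n) {
  rec <- norm_competition(records)
  if ("drug" %in% names(rec) && any(rec$drug != 0))
    stop("`fit_kappa` expects drug-free records only.", call. = FALSE)
  check_competition_design(rec)
  ssr <- function(k) {
    pr <- model_params(n = 1, kappa_n = k, mu_n = mu_n)
    sum((rec$y - interday_map(rec$x0, pr))^2)
  }
  fit <- ls_fit_1d(ssr, c(0, 1 - 1e-9), "kappa_n", nrow(rec))
  fit
}

#' Pulse kill probability from drugged competition endpoints
#'
#' Least-squares fit of `alpha` in the pulse-then-growth day map to one-day
#' competition endpoints at a single drug concentration, holding `kappa_n` and
#' `mu_n` fixed. The estimate is bounded above by 1 but allowed to go
#' negative: at sub-inhibitory doses the plasmid-free strain can gain an
#' advantage, which shows up as fitted `alpha < 0` (flagged with a warning).
#'
#' @param records Data frame as in [fit_kappa()]; if a `drug` column is
#'   present all records must share one concentration.
#' @param kappa_n,mu_n Fixed interday parameters.
#' @return A `pb_fit` for `alpha`.
#' @export
#' @examples
#' p <- pbgt_params(alpha = 0.99)
#' rec <- data.frame(x0 = seq(0.1, 0.9, 0.1))
#' rec$pb_final <- pulsed_day_map(rec$x0, p)
#' fit_alpha(rec, kappa_n = p$kappa_n, mu_n = p$mu_n)$estimate
fit_alpha <- function(records, kappa_n, mu_n) {
  rec <- norm_competition(records)
  if ("drug" %in% names(rec) && length(unique(rec$drug)) > 1)
    stop("`fit_alpha` expects records at a single drug concentration.", call. = FALSE)
  check_competition_design(rec)
  ssr <- function(a) {
    pr <- model_params(n = 1, kappa_n = kappa_n, mu_n = mu_n, alpha = a)
    sum((rec$y - pulsed_day_map(rec$x0, pr, method = "closed"))^2)
  }
  fit <- ls_fit_1d(ssr, c(-2, 1), "alpha", nrow(rec))
  if (fit$estimate < 0)
    warning("fitted alpha is negative: plasmid-free advantage at this dose.",
            call. = FALSE)
  fit
}
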