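#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-parameter fit
#'
#' @param x A `pb_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.pb_fit <- function(x, ...) {
  tibble::tibble(term = x$term, estimate = x$estimate, std.error = x$se)
}

#' Glance at a single-parameter fit
#'
#' @param x A `pb_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `residual_ss`, `n_obs` and, when the fit
#'   carries one, `r.squared`.
#' @export
glance.pb_fit <- function(x, ...) {
  out <- tibble::tibble(residual_ss = x$residual_ss, n_obs = x$n_obs)
  if (!is.null(x$r.squared)) out$r.squared <- x$r.squared
  out
}
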