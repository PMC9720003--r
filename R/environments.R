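#' Drug-exposure schedules
#'
#' A schedule is a tibble with columns `day` (1-based) and `drug` (0/1, 1
#' meaning an antibiotic pulse is applied at the start of that day, before
#' growth). Constructors tag the result with its kind and generating
#' parameters.
#'
#' `periodic_schedule()` places pulses on days `T, 2T, ...`; a period of 1 is
#' constant exposure. `random_schedule()` draws each day independently as
#' Bernoulli(`ar`), the simplest model of an environment that switches between
#' drug and drug-free days at a given long-run antibiotic rate;
#' `markov_schedule()` offers a two-state alternative with tunable switching
#' probabilities for sensitivity analyses. `constant_schedule()` is all drug
#' (or all drug-free) days.
#'
#' @param period Days between pulses, integer >= 1.
#' @param horizon Schedule length in days, >= 1.
#' @param ar Target antibiotic rate (Bernoulli probability per day) in \[0, 1\].
#' @param seed Optional integer seed; identical seeds give identical schedules
#'   and the global RNG state is left untouched.
#' @param drug For `constant_schedule()`, 1 (default) or 0 for every day.
#' @param p01,p10 For `markov_schedule()`, the daily probabilities of
#'   switching drug-free -> drug and drug -> drug-free.
#' @return A tibble of class `pb_schedule` with columns `day` and `drug` and
#'   attributes `kind` plus the generating parameters.
#' @name schedules
#' @examples
#' periodic_schedule(3, 7)$drug  # 0 0 1 0 0 1 0
#' antibiotic_rate(random_schedule(0.5, 1000, seed = 1))
NULL

new_schedule <- function(drug, kind, ...) {
  out <- tibble::tibble(day = seq_along(drug), drug = as.integer(drug))
  attr(out, "kind") <- kind
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("pb_schedule", class(out))
  out
}

#' @rdname schedules
#' @export
periodic_schedule <- function(period, horizon) {
  stopifnot(is.numeric(period), length(period) == 1, period >= 1,
            is.numeric(horizon), length(horizon) == 1, horizon >= 1)
  period <- as.integer(round(period))
  if (period > horizon)
    warning("period exceeds horizon: schedule contains no pulses.", call. = FALSE)
  new_schedule(seq_len(horizon) %% period == 0L, "periodic", period = period)
}

#' @rdname schedules
#' @export
random_schedule <- function(ar, horizon, seed = NULL) {
  stopifnot(is.numeric(ar), length(ar) == 1, ar >= 0, ar <= 1,
            is.numeric(horizon), length(horizon) == 1, horizon >= 1)
  draw <- function() stats::rbinom(horizon, 1L, ar)
  days <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_schedule(days, "random", ar_target = ar, seed = seed)
}

#' @rdname schedules
#' @export
markov_schedule <- function(p01, p10, horizon, seed = NULL) {
  stopifnot(p01 >= 0, p01 <= 1, p10 >= 0, p10 <= 1, horizon >= 1)
  draw <- function() {
    days <- integer(horizon)
    state <- stats::rbinom(1L, 1L, if (p01 + p10 > 0) p01 / (p01 + p10) else 0)
    for (i in seq_len(horizon)) {
      days[i] <- state
      flip <- if (state == 0L) p01 else p10
      if (stats::runif(1) < flip) state <- 1L - state
    }
    days
  }
  days <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_schedule(days, "markov", p01 = p01, p10 = p10, seed = seed)
}

#' @rdname schedules
#' @export
constant_schedule <- function(horizon, drug = 1) {
  stopifnot(is.numeric(horizon), length(horizon) == 1, horizon >= 1,
            drug %in% c(0, 1))
  new_schedule(rep(as.integer(drug), horizon), "constant")
}

# Accept a pb_schedule, a data frame with a `drug` column, or a bare 0/1
# vector, and return the 0/1 integer day sequence.
schedule_days <- function(schedule) {
  days <- if (is.data.frame(schedule)) {
    if (!"drug" %in% names(schedule))
      stop("schedule data frame must have a `drug` column.", call. = FALSE)
    schedule$drug
  } else {
    schedule
  }
  if (length(days) == 0) stop("schedule is empty.", call. = FALSE)
  if (!all(days %in% c(0, 1)))
    stop("schedule entries must be 0 or 1.", call. = FALSE)
  as.integer(days)
}

#' Antibiotic rate of a schedule
#'
#' Fraction of days with drug exposure.
#'
#' @param schedule A schedule (see [schedules]) or 0/1 vector.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' antibiotic_rate(c(0, 0, 1, 0))  # 0.25
antibiotic_rate <- function(schedule) {
  mean(schedule_days(schedule))
}

#' Shannon entropy of a schedule
#'
#' Binary entropy (in bits) of the empirical antibiotic rate `p`:
#' `H = -p log2(p) - (1-p) log2(1-p)`, with `0 log 0 = 0`. H is symmetric in
#' `p` and `1 - p`, so each entropy value corresponds to two antibiotic rates.
#'
#' @inheritParams antibiotic_rate
#' @return Entropy in bits, in \[0, 1\].
#' @export
#' @examples
#' schedule_entropy(c(1, 0, 1, 0))  # 1 bit
schedule_entropy <- function(schedule) {
  binary_entropy(antibiotic_rate(schedule))
}

#' @rdname schedule_entropy
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Classify a schedule's antibiotic rate as High or Low
#'
#' `"High"` when the antibiotic rate exceeds 0.5, `"Low"` otherwise (a rate of
#' exactly 0.5 is classed Low, reading the threshold strictly).
#'
#' @inheritParams antibiotic_rate
#' @return `"High"` or `"Low"`.
#' @export
#' @examples
#' classify_ar(c(1, 1, 1, 0))  # "High"
classify_ar <- function(schedule) {
  if (antibiotic_rate(schedule) > 0.5) "High" else "Low"
}
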