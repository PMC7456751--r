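#' Power-family error-spending specification
#'
#' Defines a one-sided power-family (Kim-DeMets) spending function that
#' allocates a total error probability (type I error \eqn{\alpha} for
#' efficacy, type II error \eqn{\beta} for futility) across interim looks as
#' \deqn{f(t) = \mathrm{total} \cdot t^{\rho},}
#' where \eqn{t} is the information fraction. Larger exponents spend less
#' error early, so interim boundaries are more conservative.
#'
#' @param total_error Total error probability to spend, in (0, 1).
#' @param exponent Spending exponent \eqn{\rho > 0}. The default 3 spends
#'   very little at early looks (e.g. \eqn{0.05 \cdot (1/3)^3 \approx 0.0019}
#'   at the first of three equally spaced looks).
#' @return An object of class `"spending_spec"`.
#' @seealso [cumulative_spend()], [incremental_spend()], [compute_boundaries()]
#' @examples
#' sp <- spending_spec(0.05, 3)
#' cumulative_spend(c(1 / 3, 2 / 3, 1), sp)
#' @export
spending_spec <- function(total_error, exponent = 3) {
  .assert_prob(total_error, "total_error")
  if (!is.numeric(exponent) || length(exponent) != 1L || is.na(exponent) ||
      exponent <= 0) {
    stop("'exponent' must be a positive number", call. = FALSE)
  }
  structure(
    list(total_error = total_error, exponent = exponent, side = "one-sided"),
    class = "spending_spec"
  )
}

#' @export
print.spending_spec <- function(x, ...) {
  cat(sprintf(
    "Power-family spending: f(t) = %.4g * t^%g (one-sided)\n",
    x$total_error, x$exponent
  ))
  invisible(x)
}

#' Cumulative error spent at an information fraction
#'
#' @param t Information fraction(s) in \[0, 1\]: the proportion of the planned
#'   maximum statistical information (here, of planned evaluated patients)
#'   accrued at a look.
#' @param spec A [spending_spec()].
#' @return Cumulative error spent by `t`; 0 at `t = 0` and the total error
#'   at `t = 1`.
#' @export
cumulative_spend <- function(t, spec) {
  stopifnot(inherits(spec, "spending_spec"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0) || any(t > 1)) {
    stop("information fraction 't' must lie in [0, 1]", call. = FALSE)
  }
  spec$total_error * t^spec$exponent
}

#' Per-look error increments over a look schedule
#'
#' Differences of [cumulative_spend()] across an increasing schedule of
#' information fractions ending at 1; the increments are non-negative and sum
#' to the total error.
#'
#' @param fractions Strictly increasing information fractions in (0, 1\],
#'   last element 1.
#' @inheritParams cumulative_spend
#' @return Numeric vector of per-look increments.
#' @export
incremental_spend <- function(fractions, spec) {
  stopifnot(inherits(spec, "spending_spec"))
  .check_fractions(fractions)
  diff(c(0, cumulative_spend(fractions, spec)))
}

.check_fractions <- function(fractions) {
  if (!is.numeric(fractions) || length(fractions) < 1L || anyNA(fractions)) {
    stop("'fractions' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(diff(fractions) <= 0)) {
    stop("'fractions' must be strictly increasing", call. = FALSE)
  }
  if (any(fractions <= 0) || abs(fractions[length(fractions)] - 1) > 1e-12) {
    stop("'fractions' must lie in (0, 1] with last element 1", call. = FALSE)
  }
  invisible(fractions)
}

#' Look schedule for a group-sequential design
#'
#' @param fractions Strictly increasing information fractions in (0, 1\],
#'   last element 1 (the final analysis).
#' @return An object of class `"look_schedule"`.
#' @examples
#' look_schedule(c(1 / 3, 2 / 3, 1))
#' @export
look_schedule <- function(fractions) {
  .check_fractions(fractions)
  structure(
    list(fractions = as.numeric(fractions), count = length(fractions)),
    class = "look_schedule"
  )
}

#' @export
print.look_schedule <- function(x, ...) {
  cat(sprintf(
    "%d-look schedule at information fractions %s\n",
    x$count, paste(signif(x$fractions, 4), collapse = ", ")
  ))
  invisible(x)
}

.as_schedule <- function(x) {
  if (inherits(x, "look_schedule")) x else look_schedule(x)
}
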