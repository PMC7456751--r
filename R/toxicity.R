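# Sequential binomial toxicity monitoring: a step-function boundary b(n)
# stops the treatment arm as soon as the cumulative toxicity count among n
# evaluated patients reaches b(n).

#' Toxicity stopping boundary
#'
#' A non-decreasing step function over the number of evaluated subjects:
#' at `n` subjects the trial stops when the cumulative toxicity count
#' reaches `b(n)`, the boundary value at the most recent change point at or
#' below `n`. Below the first change point no stopping is possible.
#'
#' @param change_points data.frame with columns `n` (subjects observed,
#'   strictly increasing) and `b` (minimal stopping count, non-decreasing,
#'   `b <= n`).
#' @param n_max Largest monitored number of subjects.
#' @param p_tox Monitored toxicity probability the boundary was calibrated
#'   for (informational).
#' @param alpha_tox Stated calibration level (informational; see
#'   [toxicity_crossing_probability()] for what the boundary actually
#'   implies).
#' @param rule Label recording how the boundary was constructed.
#' @return An object of class `"toxicity_boundary"`.
#' @seealso [covid_toxicity_boundary()], [monitor_toxicity()],
#'   [construct_toxicity_boundary()]
#' @export
toxicity_boundary <- function(change_points, n_max = max(change_points$n),
                              p_tox = NA_real_, alpha_tox = NA_real_,
                              rule = "custom") {
  if (!is.data.frame(change_points) ||
      !all(c("n", "b") %in% names(change_points))) {
    stop("'change_points' must be a data.frame with columns 'n' and 'b'",
         call. = FALSE)
  }
  cp <- change_points[order(change_points$n), c("n", "b")]
  if (nrow(cp) > 0L) {
    cp$n <- .assert_count(cp$n, "n", min = 1L)
    cp$b <- .assert_count(cp$b, "b", min = 1L)
    if (any(diff(cp$n) <= 0)) stop("'n' must be strictly increasing", call. = FALSE)
    if (any(diff(cp$b) < 0)) stop("'b' must be non-decreasing", call. = FALSE)
    if (any(cp$b > cp$n)) stop("'b' must not exceed 'n'", call. = FALSE)
  }
  # an empty change-point set is a boundary that never stops (b = Inf)
  n_max <- .assert_count(n_max, "n_max",
                         min = if (nrow(cp)) max(cp$n) else 1L)
  structure(list(
    change_points = cp, n_max = n_max, p_tox = p_tox, alpha_tox = alpha_tox,
    rule = rule
  ), class = "toxicity_boundary")
}

#' @export
print.toxicity_boundary <- function(x, ...) {
  cat(sprintf(
    "Toxicity stopping boundary (rule: %s; p_tox = %s, stated level = %s, n_max = %d)\n",
    x$rule, format(x$p_tox), format(x$alpha_tox), x$n_max
  ))
  print(x$change_points, row.names = FALSE)
  invisible(x)
}

#' Packaged toxicity boundary at 25% monitored toxicity
#'
#' The abbreviated sequential stopping boundary for a monitored toxicity
#' probability of 0.25 at a stated level of 0.01, shipped as change points
#' with step-function interpolation in between. The first change point is
#' (5, 2): with 2 toxicities among the first 5 treated subjects the trial
#' stops. Note the overall crossing probability of this boundary under a
#' true 25% toxicity rate is far above 0.01 (the stated level does not
#' describe the overall crossing probability; see
#' [toxicity_crossing_probability()]).
#'
#' @return A [toxicity_boundary()] with `n_max = 164`.
#' @examples
#' bd <- covid_toxicity_boundary()
#' monitor_toxicity(5, 2, bd)$decision # "stop"
#' @export
covid_toxicity_boundary <- function() {
  path <- system.file("extdata", "toxicity_boundary_p25_a01.csv",
                      package = "gsbinom", mustWork = TRUE)
  cp <- utils::read.csv(path)
  toxicity_boundary(cp, p_tox = 0.25, alpha_tox = 0.01, rule = "published")
}

#' Boundary value b(n)
#'
#' Vectorized lookup of the stopping count at `n` subjects; `Inf` below the
#' first change point (no stopping possible).
#'
#' @param boundary A [toxicity_boundary()].
#' @param n Number(s) of subjects observed, at most `n_max`.
#' @return Numeric vector of minimal stopping counts.
#' @export
boundary_at <- function(boundary, n) {
  stopifnot(inherits(boundary, "toxicity_boundary"))
  n <- .assert_count(n, "n", min = 0L)
  if (any(n > boundary$n_max)) {
    stop("n exceeds the monitored maximum n_max = ", boundary$n_max,
         call. = FALSE)
  }
  cp <- boundary$change_points
  if (nrow(cp) == 0L) return(rep(Inf, length(n)))
  idx <- findInterval(n, cp$n)
  ifelse(idx == 0L, Inf, cp$b[pmax(idx, 1L)])
}

#' Toxicity stopping decision
#'
#' Applies the boundary to the currently observed counts: the trial stops
#' when the number of toxicities reaches the boundary value at the current
#' number of evaluated subjects.
#'
#' @param n_observed Treatment-arm subjects evaluated so far.
#' @param n_toxic Toxicities (pre-adjudicated binary flags) among them.
#' @param boundary A [toxicity_boundary()].
#' @return An object of class `"toxicity_decision"` with fields `decision`
#'   (`"stop"` or `"continue"`), `n_observed`, `n_toxic` and
#'   `boundary_value_at_n`.
#' @examples
#' bd <- covid_toxicity_boundary()
#' monitor_toxicity(5, 2, bd)$decision # "stop"
#' monitor_toxicity(5, 1, bd)$decision # "continue"
#' @export
monitor_toxicity <- function(n_observed, n_toxic, boundary) {
  stopifnot(inherits(boundary, "toxicity_boundary"))
  n_observed <- .assert_count(n_observed, "n_observed", min = 0L)
  n_toxic <- .assert_count(n_toxic, "n_toxic", min = 0L)
  if (n_toxic > n_observed) {
    stop("'n_toxic' cannot exceed 'n_observed'", call. = FALSE)
  }
  b <- boundary_at(boundary, n_observed)
  structure(list(
    decision = if (n_toxic >= b) "stop" else "continue",
    n_observed = n_observed, n_toxic = n_toxic, boundary_value_at_n = b
  ), class = "toxicity_decision")
}

#' @export
print.toxicity_decision <- function(x, ...) {
  cat(sprintf(
    "Toxicity monitor: %d/%d toxic, boundary b(%d) = %s -> %s\n",
    x$n_toxic, x$n_observed, x$n_observed,
    format(x$boundary_value_at_n), toupper(x$decision)
  ))
  invisible(x)
}

#' Construct a sequential toxicity boundary
#'
#' Two deterministic constructions are supported:
#' \describe{
#'   \item{`"pointwise"`}{exact-binomial rule: at each `n`, stop at the
#'     smallest count `k` with upper-tail probability
#'     \eqn{P(\mathrm{Bin}(n, p_{tox}) \ge k) \le} `level` (per-test level
#'     `alpha_tox`).}
#'   \item{`"pocock"`}{constant nominal level chosen by bisection so that
#'     the *overall* crossing probability of the resulting boundary under
#'     `p_tox`, computed exactly by [toxicity_crossing_probability()],
#'     equals `alpha_tox`.}
#' }
#' Counts larger than `n` cannot stop, so early `n` may have no attainable
#' boundary; such `n` are simply absent from the change points.
#'
#' @param p_tox Monitored toxicity probability.
#' @param alpha_tox Per-test level (pointwise) or target overall crossing
#'   probability (pocock).
#' @param n_max Largest monitored number of subjects.
#' @param rule `"pointwise"` or `"pocock"`.
#' @return A [toxicity_boundary()]; the rule and tuning constants are
#'   recorded in its `rule` label and `calibration` field.
#' @examples
#' b <- construct_toxicity_boundary(0.25, 0.05, 20, rule = "pointwise")
#' boundary_at(b, 10) # 6
#' @export
construct_toxicity_boundary <- function(p_tox, alpha_tox, n_max,
                                        rule = c("pointwise", "pocock")) {
  .assert_prob(p_tox, "p_tox")
  .assert_prob(alpha_tox, "alpha_tox")
  n_max <- .assert_count(n_max, "n_max", min = 1L)
  rule <- match.arg(rule)

  pointwise_b <- function(level) {
    ns <- seq_len(n_max)
    vapply(ns, function(n) {
      k <- match(TRUE, pbinom(0:n - 1, n, p_tox, lower.tail = FALSE) <= level)
      if (is.na(k)) Inf else as.numeric(k - 1)  # counts are 0-based offsets
    }, numeric(1))
  }
  build <- function(level, label, calibration) {
    bvec <- pointwise_b(level)
    keep <- is.finite(bvec) & bvec >= 1
    cp <- if (any(keep)) {
      ns <- which(keep)
      bs <- bvec[keep]
      first <- !duplicated(bs) # change points: first n at which b attains a value
      data.frame(n = ns[first], b = bs[first])
    } else {
      data.frame(n = integer(0), b = integer(0)) # never stops at this level
    }
    bd <- toxicity_boundary(cp, n_max = n_max, p_tox = p_tox,
                            alpha_tox = alpha_tox, rule = label)
    bd$calibration <- calibration
    bd
  }

  if (rule == "pointwise") {
    return(build(alpha_tox, "pointwise exact-binomial",
                 list(per_test_level = alpha_tox)))
  }
  # pocock: bisection on the constant nominal level
  cross <- function(level) {
    bd <- tryCatch(build(level, "pocock", NULL), error = function(e) NULL)
    if (is.null(bd)) return(0)
    toxicity_crossing_probability(bd, p_tox)
  }
  lo <- 1e-10; hi <- 0.999
  if (cross(hi) < alpha_tox) {
    stop("target overall level not attainable by n_max = ", n_max,
         call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (cross(mid) > alpha_tox) hi <- mid else lo <- mid
  }
  # conservative side of the discrete jump: crossing <= target
  build(lo, "pocock",
        list(nominal_level = lo, target_crossing = alpha_tox,
             attained_crossing = cross(lo)))
}

#' Exact boundary-crossing probability under i.i.d. Bernoulli toxicity
#'
#' Dynamic programming over (subjects, cumulative count) states, excluding
#' already-stopped paths: the exact probability that the monitored toxicity
#' count ever reaches the boundary by `n_max`.
#'
#' @param boundary A [toxicity_boundary()].
#' @param p True per-subject toxicity probability.
#' @return Probability in \[0, 1\].
#' @export
toxicity_crossing_probability <- function(boundary, p) {
  stopifnot(inherits(boundary, "toxicity_boundary"))
  .assert_prob(p, "p", open = FALSE)
  n_max <- boundary$n_max
  bvec <- boundary_at(boundary, seq_len(n_max))
  if (!any(is.finite(bvec))) return(0)
  # counts can grow freely while b = Inf, so the state cap must cover both
  # the largest finite boundary and the pre-boundary run
  maxb <- max(max(bvec[is.finite(bvec)]), which(is.finite(bvec))[1] - 1)
  # q[c + 1] = P(still monitoring, cumulative count = c); counts >= b stop
  q <- c(1, rep(0, maxb))
  stopped <- 0
  for (n in seq_len(n_max)) {
    q <- c(q * (1 - p), 0) + c(0, q * p)
    q <- q[seq_len(maxb + 1)]
    b <- bvec[n]
    if (is.finite(b)) {
      over <- seq.int(b + 1, maxb + 1)
      stopped <- stopped + sum(q[over])
      q[over] <- 0
    }
  }
  stopped
}
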