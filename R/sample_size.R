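# Sample-size machinery for two-arm binomial comparisons with unequal
# allocation. Statistical information for the risk difference is
# I(n1, n2) = 1 / (p0 q0 / n1 + p1 q1 / n2) (unpooled variances), so the
# drift at full information is delta = |p1 - p0| * sqrt(I_max).

#' Specify a two-arm binomial trial design
#'
#' Bundles the parameters of a one-sided two-arm comparison of proportions:
#' control and treatment event probabilities, level, power, allocation ratio
#' and (for group-sequential designs) the look schedule and spending
#' exponents.
#'
#' `direction` states which change is beneficial. For a response endpoint
#' (e.g. discharge by day 15) benefit is an *increase*; for a mortality
#' endpoint benefit is a *decrease*. With `"auto"` the direction is taken
#' from the sign of `p1 - p0`. Internally the design is mapped to the
#' canonical increasing-benefit scale; boundaries are unaffected.
#'
#' @param p0 Event probability in the control (standard-care) arm.
#' @param p1 Event probability in the treatment arm (must differ from `p0`).
#' @param alpha One-sided type-I error level.
#' @param power Target power `1 - beta`.
#' @param ratio Allocation ratio treatment:control, i.e. `n2 = ratio * n1`
#'   (1 for 1:1, 2 for 1:2 control:treatment).
#' @param looks Information fractions of the analyses (last = 1). Use `1`
#'   for a fixed-sample design.
#' @param rho_eff,rho_fut Power-family spending exponents for efficacy and
#'   futility.
#' @param binding Logical; binding futility (see [compute_boundaries()]).
#' @param direction `"auto"`, `"increase"` or `"decrease"`.
#' @return An object of class `"design_input"`.
#' @examples
#' design_input(p0 = 0.40, p1 = 0.60, power = 0.90, ratio = 1)
#' @export
design_input <- function(p0, p1, alpha = 0.05, power = 0.90, ratio = 1,
                         looks = c(1 / 3, 2 / 3, 1), rho_eff = 3, rho_fut = 3,
                         binding = FALSE,
                         direction = c("auto", "increase", "decrease")) {
  .assert_prob(p0, "p0")
  .assert_prob(p1, "p1")
  if (p0 == p1) stop("'p0' and 'p1' must differ (zero effect)", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("'alpha' must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(power) || power <= 0.5 || power >= 1) {
    stop("'power' must lie in (0.5, 1)", call. = FALSE)
  }
  if (!is.numeric(ratio) || ratio <= 0) {
    stop("'ratio' must be a positive allocation ratio", call. = FALSE)
  }
  direction <- match.arg(direction)
  if (direction == "auto") {
    direction <- if (p1 > p0) "increase" else "decrease"
  }
  beneficial <- (direction == "increase" && p1 > p0) ||
    (direction == "decrease" && p1 < p0)
  if (!beneficial) {
    warning("treatment rate is not beneficial under the stated direction; ",
            "power is computed for the stated alternative anyway")
  }
  structure(list(
    p0 = p0, p1 = p1, alpha = alpha, power = power, ratio = ratio,
    schedule = .as_schedule(looks), rho_eff = rho_eff, rho_fut = rho_fut,
    binding = binding, direction = direction
  ), class = "design_input")
}

#' @export
print.design_input <- function(x, ...) {
  cat(sprintf(
    paste0("Two-arm binomial design: p0 = %.3g, p1 = %.3g (benefit = %s), ",
           "one-sided alpha = %.3g, power = %.3g, allocation 1:%g\n"),
    x$p0, x$p1, x$direction, x$alpha, x$power, x$ratio
  ))
  print(x$schedule)
  invisible(x)
}

# unit-information variance term: p0 q0 + p1 q1 / ratio, so that
# 1/I = (p0 q0 / n1 + p1 q1 / n2) = term / n1 when n2 = ratio * n1
.variance_term <- function(design) {
  with(design, p0 * (1 - p0) + p1 * (1 - p1) / ratio)
}

.new_sample_size_result <- function(design, n1, n2, boundaries, delta,
                                    attained_power, inflation_factor,
                                    kind) {
  frac <- design$schedule$fractions
  per_look <- data.frame(
    look = seq_along(frac),
    fraction = frac,
    n1 = ceiling(frac * n1),
    n2 = ceiling(frac * n2)
  )
  per_look$total <- per_look$n1 + per_look$n2
  structure(list(
    design = design, n1 = n1, n2 = n2, total = n1 + n2,
    per_look = per_look, boundaries = boundaries, delta = delta,
    attained_power = attained_power, inflation_factor = inflation_factor,
    dropout_fraction = 0, kind = kind
  ), class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(
    "%s sample size: n1 = %d (control), n2 = %d (treatment), total = %d\n",
    if (x$kind == "fixed") "Fixed-sample" else "Group-sequential",
    x$n1, x$n2, x$total
  ))
  if (x$dropout_fraction > 0) {
    cat(sprintf("  after %.0f%% dropout inflation (pre-inflation total %d)\n",
                100 * x$dropout_fraction, x$pre_inflation_total))
  }
  cat(sprintf("  attained power %.4f (target %.2f), inflation over fixed %.4f\n",
              x$attained_power, x$design$power, x$inflation_factor))
  if (x$kind == "gs") {
    cat("  cumulative enrollment per look:\n")
    print(x$per_look, row.names = FALSE)
  }
  invisible(x)
}

#' Fixed-sample (no-interim) sample size
#'
#' Smallest integer control-arm size `n1` (with `n2 = ratio * n1`) such that
#' \deqn{(z_\alpha + z_{power})^2 (p_0 q_0 / n_1 + p_1 q_1 / n_2) \le (p_1 - p_0)^2,}
#' i.e. the classical one-sided two-proportion formula with unpooled
#' variances and no continuity correction; ceiling applied per arm.
#'
#' @param design A [design_input()]; the look schedule is ignored.
#' @return A `"sample_size_result"` with `n1`, `n2`, `total` and the attained
#'   normal-approximation power.
#' @examples
#' fixed_sample_size(design_input(0.40, 0.60, power = 0.90))$n1 # 103
#' @export
fixed_sample_size <- function(design) {
  stopifnot(inherits(design, "design_input"))
  delta_fix <- qnorm(1 - design$alpha) + qnorm(design$power)
  theta <- abs(design$p1 - design$p0)
  n1c <- delta_fix^2 * .variance_term(design) / theta^2
  n1 <- ceiling(n1c - 1e-9)
  n2 <- ceiling(design$ratio * n1 - 1e-9)
  info <- 1 / (design$p0 * (1 - design$p0) / n1 +
                 design$p1 * (1 - design$p1) / n2)
  attained <- pnorm(theta * sqrt(info) - qnorm(1 - design$alpha))
  fixed_design <- design
  fixed_design$schedule <- look_schedule(1)
  .new_sample_size_result(fixed_design, n1, n2, boundaries = NULL,
                          delta = theta * sqrt(info),
                          attained_power = attained,
                          inflation_factor = 1, kind = "fixed")
}

#' Group-sequential sample size by maximum-information solving
#'
#' Solves the design drift from the error-spending boundaries (see
#' [compute_boundaries()]), converts the implied maximum information to
#' per-arm sample sizes through the unpooled-variance information formula,
#' and ceilings per arm. The attained power at the integer sizes is
#' evaluated through [crossing_probabilities()] with the futility boundary
#' honored.
#'
#' @param design A [design_input()] with a look schedule.
#' @param ngrid Number of Simpson nodes for the boundary recursion.
#' @return A `"sample_size_result"`: `n1`, `n2`, `total`, cumulative
#'   per-look enrollment (`per_look`, ceiling of the schedule fractions),
#'   the boundaries, the design drift, the attained power and the inflation
#'   factor over the fixed-sample information.
#' @examples
#' \donttest{
#' d <- design_input(0.40, 0.60, power = 0.90, ratio = 1)
#' gs_sample_size(d)$n1 # 108
#' }
#' @export
gs_sample_size <- function(design, ngrid = .GS_NGRID) {
  stopifnot(inherits(design, "design_input"))
  bd <- compute_boundaries(
    design$schedule,
    spending_spec(design$alpha, design$rho_eff),
    spending_spec(1 - design$power, design$rho_fut),
    binding = design$binding, ngrid = ngrid
  )
  theta <- abs(design$p1 - design$p0)
  i_max <- (bd$drift / theta)^2
  n1c <- i_max * .variance_term(design)
  n1 <- ceiling(n1c - 1e-9)
  n2 <- ceiling(design$ratio * n1 - 1e-9)
  info_n <- 1 / (design$p0 * (1 - design$p0) / n1 +
                   design$p1 * (1 - design$p1) / n2)
  drift_n <- theta * sqrt(info_n)
  attained <- sum(crossing_probabilities(bd, drift = drift_n,
                                         ngrid = ngrid)$efficacy)
  delta_fix <- qnorm(1 - design$alpha) + qnorm(design$power)
  .new_sample_size_result(design, n1, n2, boundaries = bd, delta = bd$drift,
                          attained_power = attained,
                          inflation_factor = (bd$drift / delta_fix)^2,
                          kind = "gs")
}

#' Inflate a sample size for anticipated dropout
#'
#' Multiplies the total by `1 + fraction` and ceilings; the inflated total
#' is split across arms preserving the allocation ratio (control arm
#' `ceiling(total / (1 + ratio))`, treatment arm the remainder).
#'
#' @param result A `"sample_size_result"`.
#' @param fraction Anticipated dropout proportion (>= 0); 0.05 is typical
#'   for hospitalized populations with short follow-up.
#' @return The result with inflated `n1`, `n2`, `total` (per-look enrollment
#'   recomputed) and the pre-inflation total recorded.
#' @examples
#' \donttest{
#' r <- gs_sample_size(design_input(0.40, 0.60, power = 0.90, ratio = 2))
#' inflate_for_dropout(r, 0.05)$total # 256
#' }
#' @export
inflate_for_dropout <- function(result, fraction = 0.05) {
  stopifnot(inherits(result, "sample_size_result"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0) {
    stop("'fraction' must be a single non-negative number", call. = FALSE)
  }
  if (fraction == 0) return(result)
  ratio <- result$design$ratio
  total_inf <- ceiling(result$total * (1 + fraction) - 1e-9)
  n1_inf <- ceiling(total_inf / (1 + ratio) - 1e-9)
  n2_inf <- total_inf - n1_inf
  out <- result
  out$pre_inflation_total <- result$total
  out$dropout_fraction <- fraction
  out$n1 <- n1_inf
  out$n2 <- n2_inf
  out$total <- total_inf
  frac <- result$design$schedule$fractions
  out$per_look <- data.frame(
    look = seq_along(frac), fraction = frac,
    n1 = ceiling(frac * n1_inf), n2 = ceiling(frac * n2_inf)
  )
  out$per_look$total <- out$per_look$n1 + out$per_look$n2
  out
}
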