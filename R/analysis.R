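# Interim/final efficacy testing: per-stratum 2x2 summaries pooled into a
# one-sided z statistic, compared against group-sequential boundaries.

.orient <- function(direction) if (direction == "decrease") -1 else 1

.new_test_result <- function(z, estimate, per_stratum, weighting) {
  structure(list(
    z = z,
    p_one_sided = pnorm(z, lower.tail = FALSE),
    estimate = estimate,
    per_stratum = per_stratum,
    weighting = weighting
  ), class = "strat_test")
}

#' @export
print.strat_test <- function(x, ...) {
  cat(sprintf(
    "Stratified one-sided test (%s): z = %.4f, p = %.6f, pooled diff = %.4f\n",
    x$weighting, x$z, x$p_one_sided, x$estimate
  ))
  invisible(x)
}

#' One-sided two-proportion z test (single stratum)
#'
#' \deqn{z = (\hat p_2 - \hat p_1) / \sqrt{\hat p_1 \hat q_1 / n_1 + \hat p_2 \hat q_2 / n_2}}
#' with unpooled variances, oriented so that treatment benefit is positive
#' (`direction = "decrease"` flips the sign for mortality-type endpoints).
#' If both arms have zero variance the statistic is defined as 0 with a
#' warning.
#'
#' @param x1,n1 Control-arm successes and size.
#' @param x2,n2 Treatment-arm successes and size.
#' @param direction `"increase"` if larger treatment proportion is
#'   beneficial, `"decrease"` otherwise.
#' @return A `"strat_test"` with `z`, `p_one_sided` (upper tail) and the
#'   oriented difference in proportions.
#' @export
unstratified_z <- function(x1, n1, x2, n2, direction = "increase") {
  counts <- data.frame(stratum = 1L, n1 = n1, x1 = x1, n2 = n2, x2 = x2)
  stratified_z(counts, direction = direction)
}

.check_counts <- function(counts) {
  need <- c("n1", "x1", "n2", "x2")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop("'counts' must be a data.frame with columns n1, x1, n2, x2",
         call. = FALSE)
  }
  for (v in need) .assert_count(counts[[v]], v, min = 0L)
  if (any(counts$x1 > counts$n1) || any(counts$x2 > counts$n2)) {
    stop("successes cannot exceed arm sizes", call. = FALSE)
  }
  if (is.null(counts$stratum)) counts$stratum <- seq_len(nrow(counts))
  counts
}

# merge strata with < min_per_arm patients in either arm into the nearest
# stratum in canonical order (previous if any, else next)
.merge_sparse <- function(counts, min_per_arm = 2L, warn = TRUE) {
  counts <- counts[order(counts$stratum), , drop = FALSE]
  repeat {
    sparse <- which(counts$n1 < min_per_arm | counts$n2 < min_per_arm)
    if (length(sparse) == 0L || nrow(counts) == 1L) break
    i <- sparse[1]
    j <- if (i > 1L) i - 1L else i + 1L
    if (warn) {
      warning(sprintf(
        "stratum %s has fewer than %d patients in an arm; merged into stratum %s",
        counts$stratum[i], min_per_arm, counts$stratum[j]
      ), call. = FALSE)
    }
    for (v in c("n1", "x1", "n2", "x2")) {
      counts[[v]][j] <- counts[[v]][j] + counts[[v]][i]
    }
    counts <- counts[-i, , drop = FALSE]
  }
  counts
}

#' Stratified one-sided z statistic pooled across strata
#'
#' Default pooling is the inverse-variance weighted combination of
#' per-stratum risk differences:
#' \deqn{Z = \sum_s w_s d_s / \sqrt{\sum_s w_s}, \quad w_s = 1 / v_s,}
#' with \eqn{d_s} the oriented difference in proportions and \eqn{v_s} its
#' unpooled variance. Strata where both arms are degenerate (zero variance)
#' receive a continuity adjustment of 0.5 added to every cell. With a single
#' stratum the statistic reduces exactly to [unstratified_z()]. The
#' alternative `"cmh"` scheme is the one-sided Cochran-Mantel-Haenszel
#' statistic on the pooled counts.
#'
#' Strata with fewer than `min_per_arm` patients in either arm are merged
#' into the nearest stratum in canonical order (with a warning) before
#' pooling. The default of 8 per arm protects the test's level: with very
#' small strata the estimated per-stratum variances are unstable (and often
#' zero), which inflates the inverse-variance statistic; merging until every
#' pooled stratum has moderate arms keeps decisions in close agreement with
#' the pooled test when there are no stratum effects.
#'
#' @param counts data.frame with columns `stratum` (optional), `n1`, `x1`
#'   (control size/successes), `n2`, `x2` (treatment).
#' @param weighting `"inverse_variance"` (default) or `"cmh"`.
#' @param direction See [unstratified_z()].
#' @param min_per_arm Sparse-stratum threshold for merging (set to 0 to
#'   disable).
#' @param warn_sparse Emit a warning when merging sparse strata.
#' @return A `"strat_test"` with the pooled `z`, one-sided `p`, pooled
#'   estimate and per-stratum contributions.
#' @examples
#' counts <- data.frame(n1 = c(40, 41), x1 = c(15, 17), n2 = c(80, 82), x2 = c(47, 50))
#' stratified_z(counts)
#' @export
stratified_z <- function(counts, weighting = c("inverse_variance", "cmh"),
                         direction = "increase", min_per_arm = 8L,
                         warn_sparse = TRUE) {
  weighting <- match.arg(weighting)
  counts <- .check_counts(counts)
  if (!any(counts$n1 >= 1L & counts$n2 >= 1L)) {
    stop("no stratum has patients in both arms", call. = FALSE)
  }
  if (min_per_arm > 0L && nrow(counts) > 1L) {
    counts <- .merge_sparse(counts, min_per_arm, warn = warn_sparse)
  }
  sgn <- .orient(direction)

  if (weighting == "cmh") {
    N <- counts$n1 + counts$n2
    m <- counts$x1 + counts$x2
    num <- sum(counts$x2 - counts$n2 * m / N)
    v <- sum(counts$n1 * counts$n2 * m * (N - m) / (N^2 * pmax(N - 1, 1)))
    if (v == 0) {
      warning("zero variance in all strata; statistic defined as 0")
      z <- 0
    } else {
      z <- sgn * num / sqrt(v)
    }
    p1 <- counts$x1 / counts$n1
    p2 <- counts$x2 / counts$n2
    est <- sgn * (sum(counts$x2) / sum(counts$n2) -
                    sum(counts$x1) / sum(counts$n1))
    per <- data.frame(stratum = counts$stratum, d = sgn * (p2 - p1))
    return(.new_test_result(z, est, per, "cmh"))
  }

  p1 <- counts$x1 / counts$n1
  p2 <- counts$x2 / counts$n2
  v <- p1 * (1 - p1) / counts$n1 + p2 * (1 - p2) / counts$n2
  degenerate <- v == 0
  if (any(degenerate)) {
    warning("zero-variance stratum; continuity adjustment (0.5 per cell) applied",
            call. = FALSE)
    # continuity adjustment: add 0.5 to every cell of the degenerate stratum
    a1 <- (counts$x1[degenerate] + 0.5) / (counts$n1[degenerate] + 1)
    a2 <- (counts$x2[degenerate] + 0.5) / (counts$n2[degenerate] + 1)
    p1[degenerate] <- a1
    p2[degenerate] <- a2
    v[degenerate] <- a1 * (1 - a1) / (counts$n1[degenerate] + 1) +
      a2 * (1 - a2) / (counts$n2[degenerate] + 1)
  }
  d <- sgn * (p2 - p1)
  w <- 1 / v
  z <- sum(w * d) / sqrt(sum(w))
  est <- sum(w * d) / sum(w)
  per <- data.frame(stratum = counts$stratum, d = d, variance = v, weight = w)
  .new_test_result(z, est, per, "inverse_variance")
}

#' Group-sequential decision at a look
#'
#' Compares an observed one-sided p-value with the nominal boundaries at a
#' look: at an interim the trial stops for efficacy when
#' `p < efficacy_p[look]`, for futility when `p > futility_p[look]`, and
#' continues otherwise; at the final look the null is rejected when
#' `p < efficacy_p[K]` and accepted otherwise.
#'
#' @param result A `"strat_test"` or a one-sided p-value.
#' @param look Look index.
#' @param boundaries A [compute_boundaries()] result.
#' @return One of `"stop_efficacy"`, `"stop_futility"`, `"continue"`,
#'   `"reject"`, `"accept"`.
#' @examples
#' b <- compute_boundaries(c(1 / 3, 2 / 3, 1),
#'                         spending_spec(0.05, 3), spending_spec(0.10, 3))
#' decide_at_look(0.001, 1, b) # "stop_efficacy"
#' @export
decide_at_look <- function(result, look, boundaries) {
  stopifnot(inherits(boundaries, "gs_boundaries"))
  p <- if (inherits(result, "strat_test")) result$p_one_sided else result
  .assert_prob(p, "p", open = FALSE)
  K <- boundaries$schedule$count
  look <- .assert_count(look, "look", min = 1L)
  if (look > K) stop("'look' exceeds the number of looks", call. = FALSE)
  if (look == K) {
    return(if (p < boundaries$efficacy_p[K]) "reject" else "accept")
  }
  if (p < boundaries$efficacy_p[look]) return("stop_efficacy")
  if (p > boundaries$futility_p[look]) return("stop_futility")
  "continue"
}
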