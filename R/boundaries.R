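# Group-sequential boundaries for the canonical one-sided normal statistic.
#
# The joint law of the sequentially computed z-statistics (Z_1, ..., Z_K) at
# information fractions t_1 < ... < t_K = 1 is multivariate normal with
# Cov(Z_j, Z_k) = sqrt(t_j / t_k) and E[Z_k] = delta * sqrt(t_k), where delta
# is the drift (expected z at full information). All recursions below work on
# the score scale S_k = Z_k * sqrt(t_k), whose increments are independent
# N(delta * dt, dt); the sub-density of the non-stopped score is propagated
# across looks on a Simpson grid restricted to the continuation region.

.GS_NGRID <- 401L
.GS_ZRANGE <- 8

# One full boundary pass at a given drift. Efficacy boundaries spend the
# alpha increments under drift 0; futility boundaries spend the beta
# increments under `delta`. With binding = TRUE the null recursion also
# truncates at the futility bound. Returns z-scale boundaries plus a status:
# "ok", "infeasible" (futility >= efficacy at an interim) or "unspendable"
# (continuation mass under the drift smaller than a beta increment).
.gs_recursion <- function(frac, da, db, delta, binding = FALSE,
                          ngrid = .GS_NGRID, zrange = .GS_ZRANGE) {
  K <- length(frac)
  az <- bz <- rep(NA_real_, K)
  az[1] <- qnorm(1 - da[1])
  bz[1] <- qnorm(db[1]) + delta * sqrt(frac[1])
  if (K == 1L) {
    return(list(efficacy_z = az, futility_z = bz, status = "ok", look = NA))
  }
  if (ngrid %% 2L == 0L) ngrid <- ngrid + 1L
  mkgrid <- function(lo, hi) {
    x <- seq(lo, hi, length.out = ngrid)
    list(x = x, w = .simpson_weights(ngrid, x[2] - x[1]))
  }
  sd1 <- sqrt(frac[1])
  lo0 <- if (binding) bz[1] else -zrange
  if (binding && bz[1] >= az[1]) {
    return(list(efficacy_z = az, futility_z = bz, status = "infeasible",
                look = 1L))
  }
  g0 <- mkgrid(lo0 * sd1, az[1] * sd1)
  h0 <- dnorm(g0$x, 0, sd1)
  g1 <- mkgrid(bz[1] * sd1, az[1] * sd1)
  h1 <- dnorm(g1$x, delta * frac[1], sd1)

  for (k in 2:K) {
    dt <- frac[k] - frac[k - 1]
    s <- sqrt(dt)
    sk <- sqrt(frac[k])
    up0 <- function(cc) sum(g0$w * h0 * pnorm((cc - g0$x) / s, lower.tail = FALSE))
    lo1 <- function(cc) sum(g1$w * h1 * pnorm((cc - g1$x - delta * dt) / s))
    az[k] <- tryCatch(
      uniroot(function(z) up0(z * sk) - da[k], c(-zrange, zrange + 4),
              tol = 1e-11)$root,
      error = function(e) NA_real_
    )
    if (is.na(az[k])) {
      return(list(efficacy_z = az, futility_z = bz, status = "no_root",
                  look = k))
    }
    if (lo1(az[k] * sk) < db[k]) {
      return(list(efficacy_z = az, futility_z = bz, status = "unspendable",
                  look = k))
    }
    bz[k] <- uniroot(function(z) lo1(z * sk) - db[k],
                     c(-zrange - 4, az[k]), tol = 1e-11)$root
    if (k < K) {
      if (bz[k] >= az[k]) {
        return(list(efficacy_z = az, futility_z = bz, status = "infeasible",
                    look = k))
      }
      lo0k <- if (binding) bz[k] else -zrange
      g0n <- mkgrid(lo0k * sk, az[k] * sk)
      h0n <- vapply(g0n$x, function(y) {
        sum(g0$w * h0 * dnorm((y - g0$x) / s) / s)
      }, numeric(1))
      g1n <- mkgrid(bz[k] * sk, az[k] * sk)
      h1n <- vapply(g1n$x, function(y) {
        sum(g1$w * h1 * dnorm((y - g1$x - delta * dt) / s) / s)
      }, numeric(1))
      g0 <- g0n; h0 <- h0n
      g1 <- g1n; h1 <- h1n
    }
  }
  list(efficacy_z = az, futility_z = bz, status = "ok", look = NA)
}

# Solve the drift at which the beta-spending futility bound meets the
# efficacy bound at the final look (so attained power = 1 - total beta).
.solve_drift <- function(frac, da, db, binding, ngrid = .GS_NGRID) {
  mismatch <- function(d) {
    r <- .gs_recursion(frac, da, db, d, binding = binding, ngrid = ngrid)
    K <- length(frac)
    switch(r$status,
      ok = r$efficacy_z[K] - r$futility_z[K],
      infeasible = -10,
      unspendable = -10,
      no_root = stop("boundary root search failed at look ", r$look,
                     call. = FALSE)
    )
  }
  alpha <- sum(da)
  beta <- sum(db)
  lo <- qnorm(1 - alpha)           # roughly 50% power
  hi <- qnorm(1 - alpha) + qnorm(1 - beta) + 3
  flo <- mismatch(lo)
  tries <- 0
  while (flo < 0 && tries < 6) {
    lo <- lo - 1
    flo <- mismatch(lo)
    tries <- tries + 1
  }
  if (flo < 0) stop("could not bracket the design drift (lower)", call. = FALSE)
  uniroot(mismatch, c(lo, hi), f.lower = flo, tol = 1e-9)$root
}

#' Compute group-sequential efficacy and futility boundaries
#'
#' Computes per-look one-sided stopping boundaries for the canonical
#' sequential normal statistic by first-passage recursion. Efficacy
#' boundaries spend cumulative type-I error per `alpha_spec` under the null
#' (drift 0); futility boundaries spend cumulative type-II error per
#' `beta_spec` under the design alternative (the drift). At the final look
#' the futility boundary coincides with the efficacy boundary, so there is
#' no continuation region.
#'
#' With `drift = NULL` (the default) the drift is solved so that the two
#' spending tracks meet exactly at the final look, i.e. the design attains
#' power `1 - beta_spec$total_error` at the returned drift. By default the
#' futility boundary is *non-binding*: efficacy boundaries are computed from
#' alpha-spending alone, so the type-I error is protected even if a monitor
#' overrides a futility stop. `binding = TRUE` credits futility stops when
#' spending alpha (a more aggressive convention, retained as an option).
#'
#' @param schedule A [look_schedule()] or a vector of information fractions.
#' @param alpha_spec [spending_spec()] for the efficacy (alpha) spending.
#' @param beta_spec [spending_spec()] for the futility (beta) spending.
#' @param drift Expected z-statistic at full information under the design
#'   alternative, \eqn{\theta\sqrt{I_{max}}}; `NULL` to solve for the drift
#'   consistent with the beta spending.
#' @param binding Logical; honor the futility bound when spending alpha.
#' @param ngrid Number of Simpson nodes for the continuation-density grid.
#' @return An object of class `"gs_boundaries"`: per-look `efficacy_z`,
#'   `futility_z` (z scale), `efficacy_p`, `futility_p` (nominal one-sided
#'   upper-tail p scale), the drift, the binding flag and the cumulative
#'   spending tracks. A trial stops for efficacy at look k when the observed
#'   one-sided p-value is below `efficacy_p[k]`, and for futility when it
#'   exceeds `futility_p[k]`.
#' @examples
#' b <- compute_boundaries(
#'   c(1 / 3, 2 / 3, 1),
#'   spending_spec(0.05, 3), spending_spec(0.10, 3)
#' )
#' round(b$efficacy_p, 3) # 0.002, 0.014, 0.046
#' round(b$futility_p, 3) # 0.830, 0.298, 0.046
#' @export
compute_boundaries <- function(schedule, alpha_spec, beta_spec, drift = NULL,
                               binding = FALSE, ngrid = .GS_NGRID) {
  schedule <- .as_schedule(schedule)
  stopifnot(inherits(alpha_spec, "spending_spec"),
            inherits(beta_spec, "spending_spec"))
  if (alpha_spec$total_error + beta_spec$total_error >= 1) {
    stop("alpha and beta totals must sum to less than 1", call. = FALSE)
  }
  frac <- schedule$fractions
  da <- incremental_spend(frac, alpha_spec)
  db <- incremental_spend(frac, beta_spec)
  solved <- is.null(drift)
  if (solved) {
    drift <- .solve_drift(frac, da, db, binding, ngrid)
  } else if (!is.numeric(drift) || length(drift) != 1L || drift < 0) {
    stop("'drift' must be a single non-negative number", call. = FALSE)
  }
  r <- .gs_recursion(frac, da, db, drift, binding = binding, ngrid = ngrid)
  if (r$status == "infeasible") {
    stop("futility boundary meets or exceeds the efficacy boundary at look ",
         r$look, call. = FALSE)
  }
  if (r$status != "ok") {
    stop("boundary computation failed (", r$status, ") at look ", r$look,
         call. = FALSE)
  }
  K <- schedule$count
  az <- r$efficacy_z
  bz <- r$futility_z
  final_gap <- az[K] - bz[K]
  bz[K] <- az[K] # no continuation region at the final analysis
  structure(list(
    schedule = schedule,
    efficacy_z = az,
    futility_z = bz,
    efficacy_p = pnorm(az, lower.tail = FALSE),
    futility_p = pnorm(bz, lower.tail = FALSE),
    binding = binding,
    drift = drift,
    drift_solved = solved,
    final_gap = final_gap,
    alpha_spec = alpha_spec,
    beta_spec = beta_spec,
    cum_alpha = cumsum(da),
    cum_beta = cumsum(db)
  ), class = "gs_boundaries")
}

#' @export
print.gs_boundaries <- function(x, ...) {
  K <- x$schedule$count
  cat(sprintf(
    "Group-sequential boundaries (%d looks, %s futility, drift = %.4f)\n",
    K, if (x$binding) "binding" else "non-binding", x$drift
  ))
  df <- data.frame(
    look = seq_len(K),
    fraction = signif(x$schedule$fractions, 4),
    efficacy_z = round(x$efficacy_z, 4),
    efficacy_p = signif(x$efficacy_p, 6),
    futility_z = round(x$futility_z, 4),
    futility_p = signif(x$futility_p, 6),
    cum_alpha = signif(x$cum_alpha, 6),
    cum_beta = signif(x$cum_beta, 6)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-look boundary-crossing probabilities under a given drift
#'
#' Propagates the sub-density of the non-stopped sequential statistic across
#' looks and returns the probability of stopping for efficacy (upper
#' crossing) and futility (lower crossing) at each look. At the final look
#' the "futility" column is the probability of finishing below the efficacy
#' boundary (acceptance). With `honor_futility = FALSE` the lower boundary
#' is ignored, which is how the type-I error of a non-binding design is
#' evaluated.
#'
#' @param boundaries A [compute_boundaries()] result.
#' @param drift Drift under which to evaluate the crossing probabilities
#'   (0 = null hypothesis; defaults to the design drift).
#' @param honor_futility Logical; stop at the futility boundary.
#' @param ngrid Number of Simpson nodes.
#' @return A data.frame with columns `look`, `fraction`, `efficacy`,
#'   `futility`, `continue`; efficacy + futility + continue at each look
#'   equals the probability of reaching that look.
#' @export
crossing_probabilities <- function(boundaries, drift = boundaries$drift,
                                   honor_futility = TRUE,
                                   ngrid = .GS_NGRID) {
  stopifnot(inherits(boundaries, "gs_boundaries"))
  frac <- boundaries$schedule$fractions
  az <- boundaries$efficacy_z
  bz <- boundaries$futility_z
  K <- length(frac)
  zrange <- .GS_ZRANGE
  if (ngrid %% 2L == 0L) ngrid <- ngrid + 1L
  eff <- fut <- cont <- numeric(K)

  sd1 <- sqrt(frac[1])
  eff[1] <- pnorm(az[1] - drift * sd1, lower.tail = FALSE)
  lo1 <- if (honor_futility && K > 1L) bz[1] else -zrange
  if (K == 1L) {
    fut[1] <- 1 - eff[1]
    cont[1] <- 0
    return(data.frame(look = 1L, fraction = frac, efficacy = eff,
                      futility = fut, continue = cont))
  }
  fut[1] <- pnorm(lo1 - drift * sd1)
  cont[1] <- 1 - eff[1] - fut[1]
  x <- seq(lo1 * sd1, az[1] * sd1, length.out = ngrid)
  w <- .simpson_weights(ngrid, x[2] - x[1])
  h <- dnorm(x, drift * frac[1], sd1)
  for (k in 2:K) {
    dt <- frac[k] - frac[k - 1]
    s <- sqrt(dt)
    sk <- sqrt(frac[k])
    eff[k] <- sum(w * h * pnorm((az[k] * sk - x - drift * dt) / s,
                                lower.tail = FALSE))
    lok <- if (honor_futility || k == K) bz[k] else -zrange
    fut[k] <- sum(w * h * pnorm((lok * sk - x - drift * dt) / s))
    cont[k] <- max(0, sum(w * h) - eff[k] - fut[k])
    if (k < K) {
      xn <- seq(lok * sk, az[k] * sk, length.out = ngrid)
      wn <- .simpson_weights(ngrid, xn[2] - xn[1])
      hn <- vapply(xn, function(y) {
        sum(w * h * dnorm((y - x - drift * dt) / s) / s)
      }, numeric(1))
      x <- xn; w <- wn; h <- hn
    } else {
      cont[k] <- 0
    }
  }
  data.frame(look = seq_len(K), fraction = frac, efficacy = eff,
             futility = fut, continue = cont)
}
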