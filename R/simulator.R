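# Patient-level Monte-Carlo simulation of the group-sequential designs:
# synthetic patient streams, single-trial execution (randomization,
# continuous toxicity monitoring, interim looks) and operating
# characteristics over many replicates.

#' Configure a trial simulation
#'
#' @param sizes A [gs_sample_size()] result carrying the design, the
#'   boundaries and the per-look enrollment.
#' @param true_p0,true_p1 True per-arm event probabilities (scalars, or
#'   vectors over strata); default to the design rates.
#' @param stratum_mix Prevalence vector over strata (sums to 1). `NULL`
#'   simulates a single homogeneous stratum, which leaves the design's
#'   operating characteristics unchanged when the true rates carry no
#'   stratum effect.
#' @param risk_group `"intermediate"` or `"high"`; controls the patient
#'   profiles emitted by [simulate_patients()] and the default stratum set.
#' @param toxicity_rate Treatment-arm toxicity probability, or `NULL` for no
#'   toxicity monitoring (the high-risk design).
#' @param tox_boundary A [toxicity_boundary()]; defaults to
#'   [covid_toxicity_boundary()] when `toxicity_rate` is given.
#' @param n_reps Number of simulated trials.
#' @param seed Master seed; per-replicate substreams are derived from it.
#' @param weighting Pooling scheme passed to [stratified_z()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(sizes, true_p0 = NULL, true_p1 = NULL,
                       stratum_mix = NULL,
                       risk_group = c("intermediate", "high"),
                       toxicity_rate = NULL, tox_boundary = NULL,
                       n_reps = 1000L, seed = 1L,
                       weighting = "inverse_variance") {
  stopifnot(inherits(sizes, "sample_size_result"))
  if (is.null(sizes$boundaries)) {
    stop("'sizes' must come from gs_sample_size() (boundaries required)",
         call. = FALSE)
  }
  risk_group <- match.arg(risk_group)
  design <- sizes$design
  if (is.null(true_p0)) true_p0 <- design$p0
  if (is.null(true_p1)) true_p1 <- design$p1
  .assert_prob(true_p0, "true_p0", open = FALSE)
  .assert_prob(true_p1, "true_p1", open = FALSE)
  if (is.null(stratum_mix)) {
    stratum_mix <- 1
  } else {
    if (abs(sum(stratum_mix) - 1) > 1e-8 || any(stratum_mix < 0)) {
      stop("'stratum_mix' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (!is.null(toxicity_rate)) {
    .assert_prob(toxicity_rate, "toxicity_rate", open = FALSE)
    if (is.null(tox_boundary)) tox_boundary <- covid_toxicity_boundary()
    stopifnot(inherits(tox_boundary, "toxicity_boundary"))
  }
  n_reps <- .assert_count(n_reps, "n_reps", min = 1L)
  structure(list(
    sizes = sizes, design = design, boundaries = sizes$boundaries,
    true_p0 = true_p0, true_p1 = true_p1, stratum_mix = stratum_mix,
    risk_group = risk_group, toxicity_rate = toxicity_rate,
    tox_boundary = tox_boundary, n_reps = n_reps, seed = seed,
    weighting = weighting
  ), class = "sim_config")
}

# lean permuted-block arm stream for one stratum: 0 = control, 1 = treatment
.block_arms <- function(m, ratio, block_sizes) {
  arms <- integer(0)
  while (length(arms) < m) {
    size <- if (length(block_sizes) == 1L) block_sizes else
      sample(block_sizes, 1L)
    arms <- c(arms, sample(rep(
      c(0L, 1L), c(size / (1 + ratio), size * ratio / (1 + ratio))
    )))
  }
  arms[seq_len(m)]
}

# draw one enrollment stream under the current RNG state
.sim_stream <- function(cfg) {
  n <- cfg$sizes$n1 + cfg$sizes$n2
  ratio <- cfg$design$ratio
  block_sizes <- if (ratio == 1) c(4L, 6L) else 6L
  ns <- length(cfg$stratum_mix)
  stratum <- if (ns == 1L) rep.int(1L, n) else
    sample.int(ns, n, replace = TRUE, prob = cfg$stratum_mix)
  arm <- integer(n)
  if (ns == 1L) {
    arm <- .block_arms(n, ratio, block_sizes)
  } else {
    for (s in seq_len(ns)) {
      idx <- which(stratum == s)
      if (length(idx)) arm[idx] <- .block_arms(length(idx), ratio, block_sizes)
    }
  }
  p0 <- rep_len(cfg$true_p0, ns)
  p1 <- rep_len(cfg$true_p1, ns)
  pr <- ifelse(arm == 1L, p1[stratum], p0[stratum])
  outcome <- rbinom(n, 1L, pr)
  tox <- if (is.null(cfg$toxicity_rate)) integer(n) else
    as.integer(arm == 1L & runif(n) < cfg$toxicity_rate)
  list(stratum = stratum, arm = arm, outcome = outcome, toxicity = tox)
}

#' Simulate a synthetic patient stream
#'
#' Draws an ordered enrollment stream for one trial: stratum membership from
#' the configured mix, arms by Zelen permuted blocks within stratum, binary
#' outcomes as independent Bernoulli draws at the arm's true rate, and
#' independent Bernoulli toxicity flags on the treatment arm. Patient
#' profiles (WHO stage, age, sex, cardiovascular risk) are decoded from the
#' canonical stratum table of the configured risk group.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed for this stream (caller's RNG restored).
#' @return data.frame in enrollment order with columns `id`, `stratum`,
#'   `who_stage`, `age`, `sex`, `cvd_risk`, `arm`, `outcome`, `toxicity`.
#' @export
simulate_patients <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    st <- .sim_stream(config)
    n <- length(st$arm)
    ns <- length(config$stratum_mix)
    tab <- .strata_table(config$risk_group)
    if (ns == 1L) {
      prof <- tab[rep(1L, n), , drop = FALSE]
    } else {
      if (ns != nrow(tab)) {
        stop("'stratum_mix' length must match the ", nrow(tab), " strata of the ",
             config$risk_group, " risk group to decode profiles", call. = FALSE)
      }
      prof <- tab[st$stratum, , drop = FALSE]
    }
    who_stage <- if (config$risk_group == "intermediate") {
      ifelse(prof$stage_group == "5", 5L,
             sample(c(3L, 4L), n, replace = TRUE))
    } else {
      sample(c(6L, 7L), n, replace = TRUE, prob = c(0.9, 0.1))
    }
    young <- grepl("^<", prof$age_group)
    cut <- if (config$risk_group == "intermediate") 60L else 65L
    age <- ifelse(young, sample(seq(30L, cut - 1L), n, replace = TRUE),
                  sample(seq(cut, 90L), n, replace = TRUE))
    data.frame(
      id = seq_len(n), stratum = st$stratum, who_stage = who_stage,
      age = age, sex = prof$sex, cvd_risk = prof$cvd_risk,
      arm = c("control", "treatment")[st$arm + 1L],
      outcome = st$outcome, toxicity = st$toxicity,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

# counts data.frame for stratified_z from a stream subset
.look_counts <- function(st, sel) {
  stratum <- st$stratum[sel]
  arm <- st$arm[sel]
  outcome <- st$outcome[sel]
  ns <- max(stratum)
  n1 <- tabulate(stratum[arm == 0L], ns)
  x1 <- tabulate(stratum[arm == 0L & outcome == 1L], ns)
  n2 <- tabulate(stratum[arm == 1L], ns)
  x2 <- tabulate(stratum[arm == 1L & outcome == 1L], ns)
  keep <- (n1 + n2) > 0L
  data.frame(stratum = seq_len(ns)[keep], n1 = n1[keep], x1 = x1[keep],
             n2 = n2[keep], x2 = x2[keep])
}

#' Run a single simulated trial
#'
#' Enrolls one synthetic patient stream, applies the toxicity stopping rule
#' continuously on the treatment arm (when configured), evaluates the
#' stratified one-sided statistic at each look's cumulative enrollment and
#' applies the group-sequential decision rule.
#'
#' @param config A [sim_config()].
#' @param seed Optional replicate seed.
#' @return A list: `decision` (`"stop_efficacy"`, `"stop_futility"`,
#'   `"stop_toxicity"`, `"reject"` or `"accept"`), `look` (look index at
#'   stop, `NA` for toxicity stops), `n_enrolled` and `p_values` (one-sided
#'   p at each evaluated look).
#' @export
run_single_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, .run_trial(config))
}

.run_trial <- function(cfg) {
  st <- .sim_stream(cfg)
  per_look <- cfg$sizes$per_look
  K <- nrow(per_look)
  m_look <- per_look$n1 + per_look$n2
  direction <- cfg$design$direction

  # continuous toxicity monitoring: enrollment position of the treatment
  # patient at which the cumulative toxicity count first reaches b(j)
  tox_pos <- Inf
  if (!is.null(cfg$toxicity_rate)) {
    trt_pos <- which(st$arm == 1L)
    j_max <- min(length(trt_pos), cfg$tox_boundary$n_max)
    if (j_max > 0L) {
      bvec <- boundary_at(cfg$tox_boundary, seq_len(j_max))
      cum <- cumsum(st$toxicity[trt_pos])[seq_len(j_max)]
      hit <- which(cum >= bvec)
      if (length(hit)) tox_pos <- trt_pos[hit[1]]
    }
  }

  p_values <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (tox_pos <= m_look[k]) {
      return(list(decision = "stop_toxicity", look = NA_integer_,
                  n_enrolled = as.integer(tox_pos), p_values = p_values))
    }
    sel <- seq_len(min(m_look[k], length(st$arm)))
    counts <- .look_counts(st, sel)
    res <- suppressWarnings(
      stratified_z(counts, weighting = cfg$weighting, direction = direction,
                   warn_sparse = FALSE)
    )
    p_values[k] <- res$p_one_sided
    dec <- decide_at_look(res, k, cfg$boundaries)
    if (dec != "continue") {
      return(list(decision = dec, look = k,
                  n_enrolled = as.integer(max(sel)), p_values = p_values))
    }
  }
  list(decision = "accept", look = K,
       n_enrolled = as.integer(m_look[K]), p_values = p_values)
}

#' Estimate operating characteristics by Monte-Carlo simulation
#'
#' Replicates [run_single_trial()] and summarizes the design's frequentist
#' behavior: efficacy rejection rate (interim efficacy stops plus final
#' rejections), futility and toxicity stop rates, the stopping distribution
#' over looks, and the expected total enrollment, each with a Monte-Carlo
#' standard error. Fully reproducible from the master seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `"operating_characteristics"`.
#' @export
estimate_operating_characteristics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$n_reps
  decisions <- character(R)
  looks <- integer(R)
  n_enrolled <- integer(R)
  with_seed(config$seed, {
    for (i in seq_len(R)) {
      r <- .run_trial(config)
      decisions[i] <- r$decision
      looks[i] <- if (is.na(r$look)) -1L else r$look
      n_enrolled[i] <- r$n_enrolled
    }
  })
  rate <- function(x) {
    p <- mean(x)
    c(estimate = p, se = sqrt(p * (1 - p) / R))
  }
  K <- nrow(config$sizes$per_look)
  stop_dist <- c(
    toxicity = mean(looks == -1L),
    vapply(seq_len(K), function(k) mean(looks == k), numeric(1))
  )
  names(stop_dist)[-1] <- paste0("look", seq_len(K))
  structure(list(
    n_reps = R,
    efficacy_rejection = rate(decisions %in% c("stop_efficacy", "reject")),
    futility_stop = rate(decisions == "stop_futility"),
    toxicity_stop = rate(decisions == "stop_toxicity"),
    accept = rate(decisions == "accept"),
    stop_distribution = stop_dist,
    expected_n = c(estimate = mean(n_enrolled),
                   se = sd(n_enrolled) / sqrt(R)),
    config = config
  ), class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d replicates)\n", x$n_reps))
  show <- function(lbl, v) {
    cat(sprintf("  %-22s %.4f (MC se %.4f)\n", lbl, v["estimate"], v["se"]))
  }
  show("efficacy rejection", x$efficacy_rejection)
  show("futility stop", x$futility_stop)
  show("toxicity stop", x$toxicity_stop)
  show("accept at final", x$accept)
  cat(sprintf("  %-22s %.1f (MC se %.2f)\n", "expected total n",
              x$expected_n["estimate"], x$expected_n["se"]))
  cat("  stop distribution:",
      paste(names(x$stop_distribution),
            sprintf("%.3f", x$stop_distribution), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
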