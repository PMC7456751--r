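# WHO-ordinal-scale risk grouping, stratum assignment and Zelen stratified
# permuted-block randomization.

#' Classify WHO ordinal stage into a risk group
#'
#' WHO patient-status stages: 1-2 ambulatory (low risk, not enrolled),
#' 3 hospitalized without oxygen, 4 oxygen by mask/nasal prongs,
#' 5 non-invasive ventilation or high-flow oxygen (intermediate risk),
#' 6 intubation and mechanical ventilation, 7 ventilation with additional
#' organ support (high risk), 8 death (not randomizable).
#'
#' @param who_stage Integer stage(s) in 1..8.
#' @return Character vector: `"low"`, `"intermediate"`, `"high"` or
#'   `"deceased"`.
#' @examples
#' classify_risk_group(c(4, 7, 8))
#' @export
classify_risk_group <- function(who_stage) {
  who_stage <- .assert_count(who_stage, "who_stage", min = 1L)
  if (any(who_stage > 8L)) {
    stop("'who_stage' must lie in 1..8", call. = FALSE)
  }
  out <- character(length(who_stage))
  out[who_stage <= 2L] <- "low"
  out[who_stage >= 3L & who_stage <= 5L] <- "intermediate"
  out[who_stage %in% c(6L, 7L)] <- "high"
  out[who_stage == 8L] <- "deceased"
  out
}

# Canonical stratum tables. Factor order (slowest-varying last, built with
# expand.grid so the FIRST factor varies fastest) is fixed and documented:
# intermediate: stage group (3-4 vs 5), age (<60 vs >=60), sex (M, F),
# CVD risk (no, yes) -> 16 strata; high risk: age (<65 vs >=65), sex,
# CVD risk -> 8 strata (stage 6 vs 7 is NOT a factor).
.strata_table <- function(risk_group = c("intermediate", "high")) {
  risk_group <- match.arg(risk_group)
  tab <- if (risk_group == "intermediate") {
    expand.grid(
      stage_group = c("3-4", "5"),
      age_group = c("<60", ">=60"),
      sex = c("male", "female"),
      cvd_risk = c(FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    expand.grid(
      age_group = c("<65", ">=65"),
      sex = c("male", "female"),
      cvd_risk = c(FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  tab$stratum <- seq_len(nrow(tab))
  tab$label <- do.call(paste, c(tab[setdiff(names(tab), c("stratum", "label"))],
                                sep = "/"))
  tab
}

#' Enumerate the canonical strata of a risk group
#'
#' @param risk_group `"intermediate"` (16 strata: stage 3-4 vs 5, age < 60
#'   vs >= 60, sex, cardiovascular risk factor yes/no) or `"high"`
#'   (8 strata: age < 65 vs >= 65, sex, cardiovascular risk; stage 6 vs 7
#'   is deliberately not a factor because stage-7 patients are scarce).
#' @return data.frame of factor levels with the canonical `stratum` index
#'   and a human-readable `label`.
#' @export
strata_table <- function(risk_group = c("intermediate", "high")) {
  .strata_table(match.arg(risk_group))
}

.norm_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(substr(s, 1, 1) == "m", "male",
                ifelse(substr(s, 1, 1) == "f", "female", NA_character_))
  if (anyNA(out)) stop("'sex' must be male/female", call. = FALSE)
  out
}

#' Assign patients to their randomization stratum
#'
#' Maps patient profiles to the canonical stratum of their risk group.
#' Intermediate-risk strata cross stage group (3-4 vs 5, i.e. ward vs ICU),
#' age (< 60 vs >= 60 years), sex and presence of at least one
#' cardiovascular risk factor (obesity, hypertension or diabetes); the
#' high-risk age cut is 65 years and stage is not a factor.
#'
#' @param who_stage Integer stage(s) 3..7 (low-risk and deceased profiles
#'   are not randomizable and raise an error).
#' @param age Age in years.
#' @param sex `"male"`/`"female"` (or abbreviations).
#' @param cvd_risk Logical: at least one of obesity, hypertension, diabetes.
#' @return data.frame with `risk_group`, `stratum` (canonical index within
#'   the risk group) and `label`.
#' @examples
#' assign_stratum(5, 59, "female", TRUE)
#' @export
assign_stratum <- function(who_stage, age, sex, cvd_risk) {
  risk <- classify_risk_group(who_stage)
  if (any(risk %in% c("low", "deceased"))) {
    stop("not eligible: low-risk (stage 1-2) and deceased (stage 8) ",
         "patients cannot be randomized", call. = FALSE)
  }
  if (!is.numeric(age) || anyNA(age) || any(age < 0)) {
    stop("'age' must be non-negative", call. = FALSE)
  }
  sex <- .norm_sex(sex)
  cvd_risk <- as.logical(cvd_risk)
  if (anyNA(cvd_risk)) stop("'cvd_risk' must be logical", call. = FALSE)
  n <- length(risk)
  stopifnot(length(age) == n, length(sex) == n, length(cvd_risk) == n)

  stratum <- integer(n)
  label <- character(n)
  for (grp in unique(risk)) {
    sel <- risk == grp
    tab <- .strata_table(grp)
    key <- if (grp == "intermediate") {
      paste(ifelse(who_stage[sel] <= 4L, "3-4", "5"),
            ifelse(age[sel] < 60, "<60", ">=60"),
            sex[sel], cvd_risk[sel], sep = "|")
    } else {
      paste(ifelse(age[sel] < 65, "<65", ">=65"), sex[sel], cvd_risk[sel],
            sep = "|")
    }
    tabkey <- do.call(paste, c(tab[setdiff(names(tab), c("stratum", "label"))],
                               list(sep = "|")))
    idx <- match(key, tabkey)
    stratum[sel] <- tab$stratum[idx]
    label[sel] <- tab$label[idx]
  }
  data.frame(risk_group = risk, stratum = stratum, label = label,
             stringsAsFactors = FALSE)
}

#' Zelen stratified permuted-block randomization
#'
#' Runs an independent permuted-block stream within each stratum. For 1:1
#' allocation the block size is drawn uniformly from `block_sizes`
#' (default 4 or 6) for every new block; for 1:2 allocation blocks are of
#' fixed size 6 (a 1:2 ratio cannot be balanced in a block of 4). Within a
#' block, arms appear in exact ratio proportion in uniformly random order,
#' so every completed block is exactly balanced and the running imbalance
#' within a stratum is bounded by the block size.
#'
#' @param patients data.frame with columns `who_stage`, `age`, `sex`,
#'   `cvd_risk` (and optionally `id`), in enrollment order; all patients
#'   must belong to the same risk group.
#' @param ratio Allocation ratio treatment:control (1 or 2; other integer
#'   ratios are accepted when `block_sizes` are multiples of `1 + ratio`).
#' @param seed Integer seed making the assignment fully reproducible; the
#'   caller's RNG state is restored afterwards.
#' @param block_sizes Candidate block sizes; defaults to `c(4, 6)` for 1:1
#'   and `6` for 1:2.
#' @return data.frame in enrollment order: `id`, `risk_group`, `stratum`,
#'   `label`, `arm` (`"control"`/`"treatment"`), `block` (block ordinal
#'   within the stratum) and `block_position`.
#' @examples
#' pts <- data.frame(who_stage = 4, age = 55, sex = "m", cvd_risk = FALSE)[rep(1, 6), ]
#' table(zelen_randomize(pts, ratio = 2, seed = 1)$arm) # 2 control, 4 treatment
#' @export
zelen_randomize <- function(patients, ratio = 1, seed = NULL,
                            block_sizes = NULL) {
  stopifnot(is.data.frame(patients))
  need <- c("who_stage", "age", "sex", "cvd_risk")
  if (!all(need %in% names(patients))) {
    stop("'patients' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1 ||
      ratio != floor(ratio)) {
    stop("'ratio' must be a positive integer (treatment per control)",
         call. = FALSE)
  }
  if (is.null(block_sizes)) {
    if (ratio == 1) {
      block_sizes <- c(4L, 6L)
    } else if (ratio == 2) {
      block_sizes <- 6L
    } else {
      stop("ratio 1:", ratio, " requires explicit 'block_sizes' ",
           "(multiples of ", 1 + ratio, ")", call. = FALSE)
    }
  }
  if (any(block_sizes %% (1 + ratio) != 0)) {
    stop("'block_sizes' must be multiples of 1 + ratio = ", 1 + ratio,
         call. = FALSE)
  }
  st <- assign_stratum(patients$who_stage, patients$age, patients$sex,
                       patients$cvd_risk)
  if (length(unique(st$risk_group)) > 1L) {
    stop("all patients must belong to the same risk group", call. = FALSE)
  }
  id <- if ("id" %in% names(patients)) patients$id else seq_len(nrow(patients))

  out <- data.frame(
    id = id, risk_group = st$risk_group, stratum = st$stratum,
    label = st$label, arm = NA_character_, block = NA_integer_,
    block_size = NA_integer_, block_position = NA_integer_,
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    for (s in sort(unique(st$stratum))) {
      rows <- which(st$stratum == s)
      m <- length(rows)
      arms <- character(0)
      blk <- pos <- bsz <- integer(0)
      b <- 0L
      while (length(arms) < m) {
        b <- b + 1L
        size <- if (length(block_sizes) == 1L) block_sizes else
          sample(block_sizes, 1L)
        units <- rep(c("control", "treatment"),
                     c(size / (1 + ratio), size * ratio / (1 + ratio)))
        units <- sample(units)
        arms <- c(arms, units)
        blk <- c(blk, rep(b, size))
        bsz <- c(bsz, rep(size, size))
        pos <- c(pos, seq_len(size))
      }
      out$arm[rows] <- arms[seq_len(m)]
      out$block[rows] <- blk[seq_len(m)]
      out$block_size[rows] <- bsz[seq_len(m)]
      out$block_position[rows] <- pos[seq_len(m)]
    }
  })
  out
}
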