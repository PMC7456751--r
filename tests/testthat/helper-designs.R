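# Shared design objects (computed once per test run) and Monte-Carlo
# oracles independent of the package's grid recursion.

three_looks <- c(1 / 3, 2 / 3, 1)

alpha_sp <- spending_spec(0.05, 3)
beta10_sp <- spending_spec(0.10, 3)
beta20_sp <- spending_spec(0.20, 3)

bound90 <- compute_boundaries(three_looks, alpha_sp, beta10_sp)
bound80 <- compute_boundaries(three_looks, alpha_sp, beta20_sp)

size_11 <- gs_sample_size(design_input(0.40, 0.60, power = 0.90, ratio = 1))
size_12 <- gs_sample_size(design_input(0.40, 0.60, power = 0.90, ratio = 2))

tox_fixture <- covid_toxicity_boundary()

# Monte-Carlo oracle for group-sequential crossing probabilities: simulate
# the correlated z-path directly from independent score increments.
mc_gs_crossing <- function(frac, efficacy_z, futility_z, delta, npaths,
                           honor_futility = TRUE) {
  K <- length(frac)
  dt <- diff(c(0, frac))
  S <- matrix(rnorm(npaths * K, mean = rep(delta * dt, each = npaths),
                    sd = rep(sqrt(dt), each = npaths)), npaths, K)
  if (K > 1) for (k in 2:K) S[, k] <- S[, k - 1] + S[, k]
  Z <- sweep(S, 2, sqrt(frac), "/")
  active <- rep(TRUE, npaths)
  eff <- fut <- numeric(K)
  for (k in seq_len(K)) {
    up <- active & Z[, k] >= efficacy_z[k]
    if (k < K) {
      dn <- if (honor_futility) active & !up & Z[, k] <= futility_z[k] else
        rep(FALSE, npaths)
    } else {
      dn <- active & !up
    }
    eff[k] <- mean(up)
    fut[k] <- mean(dn)
    active <- active & !up & !dn
  }
  list(efficacy = eff, futility = fut)
}

# Monte-Carlo oracle for the toxicity boundary crossing probability,
# chunked to bound memory.
mc_tox_crossing <- function(boundary, p, npaths, chunk = 50000L) {
  bvec <- boundary_at(boundary, seq_len(boundary$n_max))
  hits <- 0L
  done <- 0L
  while (done < npaths) {
    m <- min(chunk, npaths - done)
    x <- matrix(rbinom(m * boundary$n_max, 1L, p), nrow = boundary$n_max)
    cum <- apply(x, 2, cumsum)
    hits <- hits + sum(colSums(cum >= bvec) > 0L)
    done <- done + m
  }
  hits / npaths
}
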