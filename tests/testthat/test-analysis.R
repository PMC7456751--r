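test_that("unstratified z matches the unpooled-variance closed form", {
  # symmetric arms give exactly zero
  expect_equal(unstratified_z(20, 50, 20, 50)$z, 0)
  # hand evaluation of the formula at the 1:2 design's interim counts
  x1 <- 32; n1 <- 81; x2 <- 97; n2 <- 162
  p1 <- x1 / n1; p2 <- x2 / n2
  zref <- (p2 - p1) / sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  res <- unstratified_z(x1, n1, x2, n2)
  expect_equal(res$z, zref, tolerance = 1e-12)
  expect_equal(res$p_one_sided, pnorm(zref, lower.tail = FALSE))
  # treatment worse than control is negative under benefit = increase
  expect_lt(unstratified_z(30, 50, 20, 50)$z, 0)
  # mortality orientation: fewer treatment deaths is a benefit
  expect_gt(unstratified_z(40, 50, 25, 50, direction = "decrease")$z, 0)
  expect_warning(unstratified_z(50, 50, 50, 50), "zero-variance")
})

test_that("stratified z reduces to the unstratified statistic", {
  counts <- data.frame(n1 = 81, x1 = 32, n2 = 162, x2 = 97)
  expect_equal(stratified_z(counts)$z, unstratified_z(32, 81, 97, 162)$z,
               tolerance = 1e-9)
  # two identical null strata pool to zero
  c2 <- data.frame(n1 = c(40, 40), x1 = c(16, 16), n2 = c(40, 40),
                   x2 = c(16, 16))
  expect_equal(stratified_z(c2)$z, 0)
})

test_that("inverse-variance pooling matches a hand-computed combination", {
  counts <- data.frame(n1 = c(40, 41), x1 = c(15, 17), n2 = c(80, 82),
                       x2 = c(47, 50))
  p1 <- counts$x1 / counts$n1; p2 <- counts$x2 / counts$n2
  v <- p1 * (1 - p1) / counts$n1 + p2 * (1 - p2) / counts$n2
  w <- 1 / v
  zref <- sum(w * (p2 - p1)) / sqrt(sum(w))
  res <- stratified_z(counts)
  expect_equal(res$z, zref, tolerance = 1e-12)
  expect_equal(res$estimate, sum(w * (p2 - p1)) / sum(w), tolerance = 1e-12)
  expect_equal(nrow(res$per_stratum), 2)
})

test_that("balanced equal-rate strata give the same answer as pooling", {
  counts <- data.frame(n1 = rep(30, 4), x1 = rep(12, 4), n2 = rep(30, 4),
                       x2 = rep(18, 4))
  pooled <- unstratified_z(sum(counts$x1), sum(counts$n1),
                           sum(counts$x2), sum(counts$n2))
  expect_equal(stratified_z(counts)$z, pooled$z, tolerance = 1e-9)
  # the CMH alternative agrees closely on balanced tables
  expect_equal(stratified_z(counts, weighting = "cmh")$z, pooled$z,
               tolerance = 0.05)
})

test_that("sparse strata are merged before pooling", {
  counts <- data.frame(stratum = 1:3, n1 = c(40, 1, 40), x1 = c(15, 1, 16),
                       n2 = c(40, 2, 40), x2 = c(22, 1, 24))
  expect_warning(res <- stratified_z(counts), "merged")
  expect_equal(nrow(res$per_stratum), 2)
  merged <- data.frame(n1 = c(41, 40), x1 = c(16, 16), n2 = c(42, 40),
                       x2 = c(23, 24))
  expect_equal(res$z, stratified_z(merged)$z, tolerance = 1e-12)
  expect_error(stratified_z(data.frame(n1 = 0, x1 = 0, n2 = 5, x2 = 2)),
               "both arms")
})

test_that("look decisions follow the nominal boundaries and are monotone", {
  expect_equal(decide_at_look(0.001, 1, bound90), "stop_efficacy")
  expect_equal(decide_at_look(0.9, 1, bound90), "stop_futility")
  expect_equal(decide_at_look(0.5, 1, bound90), "continue")
  expect_equal(decide_at_look(0.04, 3, bound90), "reject")
  expect_equal(decide_at_look(0.05, 3, bound90), "accept")
  ps <- seq(0.0001, 0.9999, length.out = 200)
  for (k in 1:2) {
    dec <- vapply(ps, decide_at_look, character(1), look = k,
                  boundaries = bound90)
    # ordered regions: efficacy, continue, futility
    expect_equal(dec, dec[order(match(dec, c("stop_efficacy", "continue",
                                             "stop_futility")))])
  }
  expect_error(decide_at_look(0.5, 4, bound90), "exceeds")
})

test_that("stratification barely perturbs decisions without stratum effects", {
  set.seed(123)
  agree <- 0L
  reps <- 400L
  for (i in seq_len(reps)) {
    stratum <- sample.int(16, 243, replace = TRUE)
    arm <- c(rep(0L, 81), rep(1L, 162))[sample.int(243)]
    outcome <- rbinom(243, 1, ifelse(arm == 1L, 0.6, 0.4))
    ns <- 16L
    counts <- data.frame(
      stratum = 1:ns,
      n1 = tabulate(stratum[arm == 0L], ns),
      x1 = tabulate(stratum[arm == 0L & outcome == 1L], ns),
      n2 = tabulate(stratum[arm == 1L], ns),
      x2 = tabulate(stratum[arm == 1L & outcome == 1L], ns)
    )
    zs <- suppressWarnings(stratified_z(counts, warn_sparse = FALSE))
    zu <- unstratified_z(sum(counts$x1), sum(counts$n1),
                         sum(counts$x2), sum(counts$n2))
    agree <- agree + (decide_at_look(zs, 3, bound90) ==
                        decide_at_look(zu, 3, bound90))
  }
  expect_gte(agree / reps, 0.99)
})
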