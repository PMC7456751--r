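test_that("WHO stages map to the published risk groups", {
  expect_equal(classify_risk_group(4), "intermediate")
  expect_equal(classify_risk_group(7), "high")
  expect_equal(classify_risk_group(c(1, 2)), c("low", "low"))
  expect_equal(classify_risk_group(8), "deceased")
  expect_equal(classify_risk_group(3:5), rep("intermediate", 3))
  expect_error(classify_risk_group(0), "integer")
  expect_error(classify_risk_group(9), "1..8")
})

test_that("stratum assignment uses the published factors and cutoffs", {
  s <- assign_stratum(5, 59, "female", TRUE)
  expect_equal(s$risk_group, "intermediate")
  expect_equal(s$label, "5/<60/female/TRUE")
  h <- assign_stratum(6, 70, "male", FALSE)
  expect_equal(h$risk_group, "high")
  expect_equal(h$label, ">=65/male/FALSE")
  # the intermediate age cut is 60, the high-risk cut 65
  expect_equal(assign_stratum(3, 60, "m", FALSE)$label, "3-4/>=60/male/FALSE")
  expect_equal(assign_stratum(7, 64, "f", TRUE)$label, "<65/female/TRUE")
  expect_error(assign_stratum(1, 40, "m", FALSE), "not eligible")
  expect_error(assign_stratum(8, 70, "f", TRUE), "not eligible")
})

test_that("the factor products span exactly 16 and 8 strata", {
  inter <- expand.grid(stage = 3:5, age = c(40, 70), sex = c("m", "f"),
                       cvd = c(TRUE, FALSE))
  si <- assign_stratum(inter$stage, inter$age, inter$sex, inter$cvd)
  expect_equal(sort(unique(si$stratum)), 1:16)
  expect_equal(nrow(strata_table("intermediate")), 16)
  high <- expand.grid(stage = 6:7, age = c(50, 80), sex = c("m", "f"),
                      cvd = c(TRUE, FALSE))
  sh <- assign_stratum(high$stage, high$age, high$sex, high$cvd)
  expect_equal(sort(unique(sh$stratum)), 1:8)
  expect_equal(nrow(strata_table("high")), 8)
  # stage 6 vs 7 does not split high-risk strata
  expect_equal(assign_stratum(6, 70, "m", TRUE)$stratum,
               assign_stratum(7, 70, "m", TRUE)$stratum)
})

test_that("Zelen blocks balance the allocation ratio exactly", {
  pts6 <- data.frame(who_stage = 4, age = 50, sex = "m", cvd_risk = FALSE)[rep(1, 6), ]
  a <- zelen_randomize(pts6, ratio = 2, seed = 5)
  expect_equal(sum(a$arm == "control"), 2)
  expect_equal(sum(a$arm == "treatment"), 4)
  # identical seed reproduces the assignment; a different seed need not
  b <- zelen_randomize(pts6, ratio = 2, seed = 5)
  expect_identical(a, b)
  # every completed block carries the ratio exactly
  set.seed(9)
  n <- 500
  pts <- data.frame(
    who_stage = sample(3:5, n, TRUE), age = sample(30:85, n, TRUE),
    sex = sample(c("m", "f"), n, TRUE), cvd_risk = sample(c(TRUE, FALSE), n, TRUE)
  )
  r <- zelen_randomize(pts, ratio = 1, seed = 21)
  blocks <- split(r, list(r$stratum, r$block), drop = TRUE)
  complete <- Filter(function(blk) nrow(blk) == blk$block_size[1], blocks)
  expect_gt(length(complete), 50)
  for (blk in complete) {
    expect_true(blk$block_size[1] %in% c(4, 6))
    expect_equal(sum(blk$arm == "control"), blk$block_size[1] / 2)
  }
  expect_error(zelen_randomize(pts6, ratio = 3), "block_sizes")
  expect_error(zelen_randomize(pts6[, -1], ratio = 1), "columns")
})

test_that("large streams stay balanced within and across strata", {
  set.seed(31)
  n <- 10000
  pts <- data.frame(
    who_stage = sample(3:5, n, TRUE), age = sample(30:85, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    cvd_risk = sample(c(TRUE, FALSE), n, TRUE)
  )
  r <- zelen_randomize(pts, ratio = 1, seed = 13)
  # running imbalance within a stratum is bounded by half the largest block
  for (s in unique(r$stratum)) {
    arms <- r$arm[r$stratum == s]
    running <- cumsum(arms == "treatment") - cumsum(arms == "control")
    expect_lte(max(abs(running)), 3)
  }
  # marginal allocation converges to the ratio
  expect_lt(abs(mean(r$arm == "treatment") - 0.5), 0.01)
  r2 <- zelen_randomize(pts, ratio = 2, seed = 13)
  expect_lt(abs(mean(r2$arm == "treatment") - 2 / 3), 0.01)
})

test_that("mixed risk groups are refused", {
  pts <- data.frame(who_stage = c(4, 6), age = 50, sex = "m", cvd_risk = FALSE)
  expect_error(zelen_randomize(pts, ratio = 1, seed = 1), "same risk group")
})
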