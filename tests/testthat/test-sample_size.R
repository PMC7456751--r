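test_that("fixed-sample sizes match the closed form", {
  # (z_.95 + z_.90)^2 * 0.48 / 0.04 = 102.8 -> 103 per arm
  r <- fixed_sample_size(design_input(0.40, 0.60, power = 0.90, ratio = 1))
  expect_equal(r$n1, 103)
  expect_equal(r$n2, 103)
  # mortality design, 1:2 allocation: 8.565 * (0.21 + 0.12375) / 0.0225 -> 128
  rh <- fixed_sample_size(design_input(0.70, 0.55, power = 0.90, ratio = 2))
  expect_equal(rh$n1, 128)
  expect_equal(rh$n2, 256)
  expect_gte(rh$attained_power, 0.90)
  expect_error(design_input(0.40, 0.40), "zero effect")
})

test_that("group-sequential solver reproduces the recommended designs", {
  expect_equal(size_11$n1, 108)
  expect_equal(size_11$n2, 108)
  expect_equal(size_12$n1, 81)
  expect_equal(size_12$n2, 162)
  expect_equal(size_12$total, 243)
  rh <- gs_sample_size(design_input(0.70, 0.55, power = 0.90, ratio = 2))
  expect_equal(rh$n1, 133)
  expect_equal(rh$n2, 266)
  r10 <- gs_sample_size(design_input(0.40, 0.50, power = 0.90, ratio = 2))
  expect_equal(r10$total, 978)
  # sequential designs never need fewer patients than the fixed design
  expect_gte(size_11$inflation_factor, 1)
  expect_gte(size_11$n1, fixed_sample_size(size_11$design)$n1)
})

test_that("per-look enrollment is the ceiling of the schedule fractions", {
  pl <- size_12$per_look
  expect_equal(pl$n2, c(54, 108, 162)) # first look: 54 of 162 treated
  expect_equal(pl$n1, c(27, 54, 81))
  expect_true(all(diff(pl$total) > 0))
  expect_equal(unlist(pl[3, c("n1", "n2")], use.names = FALSE),
               c(size_12$n1, size_12$n2))
})

test_that("returned n attains the target power and is minimal", {
  for (r in list(size_11, size_12)) {
    expect_gte(r$attained_power, r$design$power)
    d <- r$design
    theta <- abs(d$p1 - d$p0)
    n1m <- r$n1 - 1
    n2m <- ceiling(d$ratio * n1m)
    info <- 1 / (d$p0 * (1 - d$p0) / n1m + d$p1 * (1 - d$p1) / n2m)
    pow <- sum(crossing_probabilities(r$boundaries,
                                      drift = theta * sqrt(info))$efficacy)
    expect_lt(pow, d$power)
  }
})

test_that("sample size is symmetric under complementing both rates", {
  a <- gs_sample_size(design_input(0.30, 0.50, power = 0.90, ratio = 1))
  b <- gs_sample_size(design_input(0.70, 0.50, power = 0.90, ratio = 1))
  expect_lte(abs(a$n1 - b$n1), 1)
  af <- fixed_sample_size(design_input(0.35, 0.55, power = 0.80, ratio = 2))
  bf <- fixed_sample_size(design_input(0.65, 0.45, power = 0.80, ratio = 2))
  expect_lte(abs(af$n1 - bf$n1), 1)
})

test_that("dropout inflation follows the 5% rule", {
  expect_equal(inflate_for_dropout(size_12, 0.05)$total, 256)
  expect_equal(inflate_for_dropout(size_12, 0)$total, 243)
  rh <- gs_sample_size(design_input(0.70, 0.55, power = 0.90, ratio = 2))
  expect_equal(inflate_for_dropout(rh, 0.05)$total, 419) # ceil(399 * 1.05)
  infl <- inflate_for_dropout(size_12, 0.05)
  expect_equal(infl$pre_inflation_total, 243)
  expect_equal(infl$n1 + infl$n2, infl$total)
})

# published two-interim tables: rows = treatment rate, one column set per
# allocation ratio and power; NA where the table prints no value
table2_expected <- data.frame(
  p1 = c(0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80),
  n1_r1_p80 = c(315, 140, 78, 49, 33, 23, 17),
  n1_r1_p90 = c(438, 194, 108, 67, 45, 32, 23),
  n1_r2_p80 = c(235, 104, 58, 37, 25, 18, 13),
  n1_r2_p90 = c(326, 145, 81, 51, 35, 25, 18)
)

table4_expected <- data.frame(
  p1 = c(0.70, 0.65, 0.60, 0.55, 0.50, 0.45, 0.40, 0.35),
  n1_p80_p0_80 = c(171, 79, 45, 30, 21, 15, 12, NA),
  n1_p80_p0_70 = c(NA, 833, 213, 96, 54, 35, 24, 17),
  n1_p90_p0_80 = c(237, 109, 63, 41, 29, 21, 16, NA),
  n1_p90_p0_70 = c(NA, 1155, 295, 133, 75, 48, 33, 24)
)

test_that("the intermediate-risk sample-size table reproduces", {
  tab <- render_sample_size_table(0.40, table2_expected$p1,
                                  power = c(0.80, 0.90), ratio = c(1, 2))
  got <- function(r, pw) {
    tab$n1[tab$ratio == r & tab$power == pw][match(table2_expected$p1,
                                                   tab$p1[tab$ratio == r & tab$power == pw])]
  }
  cells <- cbind(got(1, 0.80), got(1, 0.90), got(2, 0.80), got(2, 0.90))
  expected <- as.matrix(table2_expected[, -1])
  expect_true(all(abs(cells - expected) <= 1))
  expect_gte(sum(cells == expected), 12)
  # N2 and totals follow the allocation ratio exactly
  expect_true(all(tab$n2 == tab$ratio * tab$n1))
  expect_true(all(tab$total == tab$n1 + tab$n2))
})

test_that("the high-risk sample-size table reproduces", {
  cells <- expected <- NULL
  for (p0 in c(0.80, 0.70)) {
    tab <- render_sample_size_table(p0, setdiff(table4_expected$p1, p0),
                                    power = c(0.80, 0.90), ratio = 2,
                                    direction = "decrease")
    for (pw in c(0.80, 0.90)) {
      col <- sprintf("n1_p%d_p0_%d", round(100 * pw), round(100 * p0))
      exp_col <- table4_expected[[col]]
      got <- tab$n1[tab$power == pw][match(table4_expected$p1,
                                           tab$p1[tab$power == pw])]
      keep <- !is.na(exp_col)
      cells <- c(cells, got[keep])
      expected <- c(expected, exp_col[keep])
    }
  }
  expect_true(all(abs(cells - expected) <= 1))
  expect_gte(sum(cells == expected), 6)
})

test_that("the wide table layout carries N1/N2/Total per cell", {
  tab <- render_sample_size_table(0.40, c(0.50, 0.60), power = 0.90,
                                  ratio = c(1, 2))
  wide <- format_sample_size_table(tab)
  expect_equal(nrow(wide), 2 * 3)
  r20 <- wide[wide$effect == 0.2, ]
  expect_equal(r20$ratio_1_1_power_90, c(108L, 108L, 216L))
  expect_equal(r20$ratio_1_2_power_90, c(81L, 162L, 243L))
  expect_error(render_sample_size_table(0.4, numeric(0)), "empty")
})
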