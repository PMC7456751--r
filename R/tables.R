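# Sample-size table rendering in the layout of the published design tables:
# rows by treatment-arm rate (or effect size), columns by allocation ratio
# and power, cells N1 / N2 / Total.

#' Sample sizes over a grid of designs
#'
#' Computes group-sequential sample sizes for every combination of
#' treatment-arm rate, power and allocation ratio at a common control rate,
#' look schedule and spending exponents. Cells with `p1 == p0` (zero
#' effect) are reported as `NA`. The drift is solved once per power and
#' reused across the rate grid.
#'
#' @param p0 Control-arm event probability (scalar).
#' @param p1 Treatment-arm event probabilities (vector).
#' @param power Target powers (vector).
#' @param ratio Allocation ratios treatment:control (vector).
#' @param alpha One-sided level.
#' @param looks Information fractions.
#' @param rho_eff,rho_fut Spending exponents.
#' @param binding Binding-futility flag.
#' @param direction Passed to [design_input()].
#' @return A data.frame of class `"sample_size_table"` with one row per
#'   grid cell: `p0`, `p1`, `effect` (|p1 - p0|), `power`, `ratio`, `n1`,
#'   `n2`, `total`.
#' @examples
#' \donttest{
#' render_sample_size_table(0.40, c(0.50, 0.60), power = 0.90, ratio = c(1, 2))
#' }
#' @export
render_sample_size_table <- function(p0, p1, power = c(0.80, 0.90),
                                     ratio = c(1, 2), alpha = 0.05,
                                     looks = c(1 / 3, 2 / 3, 1),
                                     rho_eff = 3, rho_fut = 3,
                                     binding = FALSE, direction = "auto") {
  if (length(p1) == 0L || length(power) == 0L || length(ratio) == 0L) {
    stop("empty design grid", call. = FALSE)
  }
  .assert_prob(p0, "p0")
  .assert_prob(p1, "p1")
  schedule <- .as_schedule(looks)
  # one drift per power; independent of the rates
  drifts <- vapply(power, function(pw) {
    compute_boundaries(schedule, spending_spec(alpha, rho_eff),
                       spending_spec(1 - pw, rho_fut),
                       binding = binding)$drift
  }, numeric(1))
  grid <- expand.grid(p1 = p1, power = power, ratio = ratio,
                      KEEP.OUT.ATTRS = FALSE)
  n1 <- n2 <- rep(NA_integer_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (grid$p1[i] == p0) next
    delta <- drifts[match(grid$power[i], power)]
    theta <- abs(grid$p1[i] - p0)
    term <- p0 * (1 - p0) + grid$p1[i] * (1 - grid$p1[i]) / grid$ratio[i]
    n1[i] <- as.integer(ceiling((delta / theta)^2 * term - 1e-9))
    n2[i] <- as.integer(ceiling(grid$ratio[i] * n1[i] - 1e-9))
  }
  out <- data.frame(
    p0 = p0, p1 = grid$p1, effect = round(abs(grid$p1 - p0), 10),
    power = grid$power, ratio = grid$ratio,
    n1 = n1, n2 = n2, total = n1 + n2
  )
  class(out) <- c("sample_size_table", "data.frame")
  out
}

#' Pivot a sample-size table to the published wide layout
#'
#' One row per (effect, quantity in N1/N2/Total), one column per
#' ratio-by-power combination.
#'
#' @param tab A [render_sample_size_table()] result.
#' @return A wide data.frame.
#' @export
format_sample_size_table <- function(tab) {
  stopifnot(inherits(tab, "sample_size_table"))
  combos <- unique(tab[, c("ratio", "power")])
  combos <- combos[order(combos$ratio, combos$power), ]
  effects <- unique(tab$effect)
  rows <- expand.grid(quantity = c("N1", "N2", "Total"), effect = effects,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  out <- rows
  for (j in seq_len(nrow(combos))) {
    col <- sprintf("ratio_1_%g_power_%g", combos$ratio[j],
                   100 * combos$power[j])
    vals <- mapply(function(eff, q) {
      cell <- tab[tab$effect == eff & tab$ratio == combos$ratio[j] &
                    tab$power == combos$power[j], ]
      if (nrow(cell) != 1L) return(NA_integer_)
      switch(as.character(q), N1 = cell$n1, N2 = cell$n2, Total = cell$total)
    }, rows$effect, rows$quantity)
    out[[col]] <- as.integer(vals)
  }
  out
}
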