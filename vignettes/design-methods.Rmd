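---
title: "Methods: group-sequential two-arm binomial designs in gsbinom"
author: "gsbinom authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-sequential two-arm binomial designs in gsbinom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbinom)
```

## The scientific problem

`gsbinom` implements the statistical machinery for two parallel
group-sequential Phase II/III trials in hospitalized COVID-19 patients,
organized by the WHO ordinal patient-status scale:

* **Intermediate risk** (stages 3–5: hospitalized, up to non-invasive
  ventilation or high-flow oxygen). The primary endpoint is binary:
  discharge from hospital by day 15 ($Y = 1$, probability $P$); the
  composite failure ($Y = 0$) combines non-discharge, progression to a
  higher stage, and death. The design detects an *increase* in the
  discharge rate (reference scenario: 40% → 60%), with continuous
  treatment-arm toxicity monitoring.
* **High risk** (stages 6–7: invasive ventilation, possibly with
  additional organ support). The endpoint is 30-day mortality; the design
  detects a *decrease* (reference scenario: 70% → 55%), without toxicity
  monitoring.

Both trials use one-sided testing at $\alpha = 0.05$, two interim analyses
at one third and two thirds of the planned enrollment, power-family error
spending with exponent $\rho = 3$, stratified permuted-block
randomization, and 1:1 or 1:2 (control:treatment) allocation.

## Canonical sequential model

Interim inference is based on the canonical joint distribution of the
sequentially computed z-statistics. At information fractions
$t_1 < \dots < t_K = 1$ the statistics $(Z_1, \dots, Z_K)$ are
multivariate normal with

$$E[Z_k] = \delta \sqrt{t_k}, \qquad
  \mathrm{Cov}(Z_j, Z_k) = \sqrt{t_j / t_k} \quad (j \le k),$$

where the *drift* $\delta = \theta \sqrt{I_{\max}}$ is the expected
z-statistic at full information. For the difference of two proportions
with unpooled variances, $\theta = |p_1 - p_0|$ and the statistical
information at arm sizes $(n_1, n_2)$ is
$I = \left[p_0 q_0 / n_1 + p_1 q_1 / n_2\right]^{-1}$. The information
fraction is equated with the fraction of evaluated patients, which is
exact for this endpoint.

All recursions work on the score scale $S_k = Z_k \sqrt{t_k}$, whose
increments are independent $N(\delta \, \Delta t_k, \Delta t_k)$. The
sub-density of the non-stopped score is propagated across looks on a
composite-Simpson grid restricted to the continuation region (401 nodes
per look, range ±8 standard deviations), and each boundary is found by
bracketed root search on the z scale (`uniroot`, tolerance $10^{-11}$).
Halving the grid spacing changes the reported nominal p-values by less
than $10^{-6}$, far below the 3-decimal reporting precision.

## Error spending and the futility convention

Both error probabilities are spent with the power family
$f(t) = \text{total} \cdot t^\rho$: type-I error under the null for the
efficacy boundary, type-II error under the design alternative for the
futility boundary ($\beta$-spending). With $\rho = 3$ and three equally
spaced looks the cumulative $\alpha$ spend is $0.05/27 \approx 0.0019$,
$0.05 \cdot 8/27$, $0.05$ — which is why the first-look nominal level
prints as 0.002.

**The futility boundary is non-binding by default.** Efficacy boundaries
are computed from $\alpha$-spending alone (the null recursion does not
truncate at the futility bound), so the type-I error remains protected
even if a monitoring board overrides a futility stop. The drift is then
solved (by `uniroot` on the gap between the two tracks at the final look)
so that the $\beta$-spending futility bound meets the efficacy bound at
the final analysis; at that drift the attained power is exactly
$1 - \beta$. This convention — the default in standard commercial
group-sequential software — reproduces all the reference boundary values
simultaneously:

```{r boundaries}
b90 <- compute_boundaries(c(1/3, 2/3, 1),
                          spending_spec(0.05, 3), spending_spec(0.10, 3))
round(b90$efficacy_p, 3)
round(b90$futility_p, 3)
```

and, for 80% power, futility levels 0.835 / 0.312. The binding
convention (futility stops credited when spending $\alpha$) is retained
behind `binding = TRUE`; it yields a less conservative final boundary
(nominal 0.047) and roughly 2% smaller sample sizes, and its own
invariant — total efficacy crossing exactly $\alpha$ under the null with
futility honored — is covered by the test suite. Under the non-binding
default, honoring futility under the null makes the realized type-I
error slightly conservative (≈ 0.0456 instead of 0.05 for the reference
design).

### Known inconsistencies, and the choices made

* The reference description of the *one-interim* variant states
  $\rho = 2$, yet its printed first-look level 0.006 equals
  $0.05 \cdot 0.5^3$, i.e. $\rho = 3$ (with $\rho = 2$ it would be
  0.0125). The package exposes $\rho$ as a parameter and adopts
  $\rho = 3$ throughout as the value consistent with every printed
  boundary.
* The one-interim futility level "0.716" is not reproducible by
  $\beta$-spending with $\rho \in \{2, 3\}$ under either the 90%- or
  80%-power drift (the spending construction gives ≈ 0.55 and ≈ 0.44);
  the rule behind that single number is unidentified. `gsbinom` reports
  the $\beta$-spending value its own construction implies.

## Sample sizes

`gs_sample_size()` converts the solved drift to arm sizes through the
information formula: with allocation $n_2 = r \, n_1$,

$$n_1 = I_{\max}\left(p_0 q_0 + \frac{p_1 q_1}{r}\right),
  \qquad I_{\max} = (\delta / \theta)^2,$$

with the ceiling applied to $n_1$ and $n_2 = r\,n_1$ (integer $r$), and
per-look cumulative enrollments as ceilings of the schedule fractions.
No continuity correction is used, matching the unpooled-variance
convention. The attained power at the integer sizes is evaluated through
the crossing recursion at the drift implied by the integer $n$; it is at
least the target, and drops below the target at $n_1 - 1$ (minimality is
part of the test suite). The sequential inflation over the fixed-sample
size is about 4.2% for these designs, consistent with the recommended
≈ 5% dropout allowance mapping a total of 243 to 256
(`inflate_for_dropout()` ceilings the inflated total and splits it
preserving the allocation ratio).

```{r sizes}
gs_sample_size(design_input(0.40, 0.60, power = 0.90, ratio = 2))
```

`render_sample_size_table()` reproduces the full published grids
(treatment rates 50–80% against control 40% for the intermediate-risk
group; mortality 35–70% against 70% or 80% for the high-risk group);
every printed cell is matched exactly by the per-arm-ceiling convention.

## Toxicity monitoring

The intermediate-risk treatment arm is monitored continuously at a 25%
toxicity rate: after every evaluated treated patient, the trial stops
when the cumulative count of adjudicated toxicities (CTCAE grade > 2,
related/possibly/probably related) reaches a step-function boundary
$b(n)$. The published abbreviated boundary is shipped verbatim as change
points (first change point: 2 of 5) with step interpolation in between
(`covid_toxicity_boundary()`); its construction lives in external
references and is deliberately decoupled from the monitoring semantics.

`toxicity_crossing_probability()` computes, by exact dynamic programming
over (subjects, count) states that excludes already-stopped paths, the
probability that the boundary is ever crossed under i.i.d. Bernoulli
toxicity. Under a true rate of 0.25 the packaged boundary's crossing
probability is about 0.73 — the stated calibration level of 0.01 cannot
be the overall crossing probability under the monitored rate (already
$P(\ge 2 \text{ of } 5) \approx 0.37$), so the package reports the
DP-computed probability and asserts no interpretation of the 0.01.
`construct_toxicity_boundary()` offers two transparent constructions: a
pointwise exact-binomial rule, and a Pocock-type rule whose constant
nominal level is calibrated by bisection against the DP so the overall
crossing probability under the monitored rate is the largest attainable
value not exceeding the target (the crossing probability is a step
function of the level, so exact equality is generally impossible).

## Stratification and randomization

Stages 3–5 form the intermediate-risk group, 6–7 the high-risk group;
stages 1–2 (ambulatory) and 8 (death) are not randomizable.
Intermediate-risk strata cross stage group (3–4 vs 5, i.e. ward vs ICU),
age (< 60 vs ≥ 60), sex, and presence of a cardiovascular risk factor
(obesity, hypertension or diabetes) — 16 strata; high-risk strata use
age (< 65 vs ≥ 65), sex and cardiovascular risk — 8 strata, deliberately
*not* split by stage 6 vs 7 because stage-7 patients are scarce. The
canonical stratum order (stage group, then age, then sex, then
cardiovascular risk, first factor varying fastest) is fixed by
`strata_table()` for reproducibility.

`zelen_randomize()` runs an independent permuted-block stream per
stratum. The sources state both "random block size 4 or 6" and fixed
sizes per ratio; the resolution here is: 1:1 allocation draws each
block's size uniformly from {4, 6}, while 1:2 allocation uses fixed
size 6, since a 1:2 ratio cannot be balanced in a block of 4. Whether
1:2 blocks should also randomize their size is not stated anywhere; the
fixed choice is the conservative reading. Completed blocks are exactly
balanced, so the running within-stratum imbalance is bounded by half the
largest block, and assignments are bit-reproducible from the seed (the
caller's RNG state is restored).

## Stratified interim testing

The default pooled statistic is the inverse-variance weighted
combination of per-stratum risk differences,
$Z = \sum_s w_s d_s / \sqrt{\sum_s w_s}$ with $w_s = 1/\hat v_s$
(unpooled variances), which reduces exactly to the unstratified
statistic for a single stratum; a Cochran–Mantel–Haenszel count-pooling
scheme is available as an alternative. Two small-sample safeguards
matter in practice:

* Strata in which both arms are degenerate receive a continuity
  adjustment of 0.5 per cell (otherwise their weight would be infinite).
* Strata with fewer than 8 patients in either arm are merged into the
  nearest stratum in canonical order before pooling. With very small
  strata the estimated variances are unstable and often zero, which
  systematically inflates the inverse-variance statistic: at the
  reference 243-patient design with 16 uniform strata, a merge threshold
  of 2 leaves final-look decisions agreeing with the pooled test in only
  ~90% of null-effect replicates, whereas the threshold of 8 restores
  ≥ 99.5% agreement under both the null and the alternative. The
  threshold is an explicit argument (`min_per_arm`) for users who prefer
  a different rule.

`decide_at_look()` applies the nominal boundaries: stop for efficacy
when the one-sided p-value is below the efficacy level, for futility
when it exceeds the futility level (interims only), and reject at the
final look when below the final level.

## The simulator: what it emulates, and what it does not

`sim_config()` + `estimate_operating_characteristics()` execute whole
trials patient by patient: stratum membership from a prevalence mix,
arms by Zelen blocks, outcomes as independent Bernoulli draws at the
arm's (optionally stratum-specific) true rate, independent Bernoulli
toxicity flags on the treated, continuous toxicity monitoring, and
look-wise stratified decisions at the planned cumulative enrollments.
Design choices:

* Outcomes are available at evaluation time; the 15-day/30-day windows
  define the endpoint, not a timeline, since the operating
  characteristics do not depend on calendar time. No accrual or readout
  lag, no loss to follow-up.
* Toxicity and efficacy outcomes are independent; correlated models are
  out of scope.
* One master seed spawns per-replicate substreams, so results are
  reproducible and insensitive to replicate order.

Simulated trials use genuinely discrete binomial data, while the design
calculators use the normal approximation, so simulated rates carry a
small binomial-discreteness deviation on top of Monte-Carlo noise; the
acceptance checks therefore allow 3 Monte-Carlo standard errors plus a
documented 0.02 allowance. At the reference intermediate-risk design
(40% → 60%, 108 per arm, 10,000 replicates) the empirical efficacy
rejection rate is ≈ 0.90 and the empirical null rejection rate is
slightly below 0.05, as expected for a non-binding design with futility
honored. By default the operating-characteristic runs use a single
homogeneous stratum: with no stratum effects, stratification leaves the
design's behavior unchanged, and a separate property test verifies that
stratified and pooled decisions agree.

Passing these simulations shows that the calculators and the trial
engine are mutually consistent under the idealized data-generating
process; it does not validate the designs against real accrual patterns,
outcome delays, stratum-dependent treatment effects, or
toxicity-efficacy dependence.

## Problem sizes and runtime

All boundary and sample-size computations are desk-scale (well under a
second each). The test suite uses $2 \times 10^5$ Monte-Carlo paths for
the boundary-recursion cross-checks, $10^5$ Bernoulli paths for the
toxicity DP cross-check, and 10,000 replicate trials for the operating
characteristics — sizes chosen so Monte-Carlo standard errors are small
relative to the tolerances being asserted while the suite completes in a
few minutes.

## Limitations

Repeated confidence intervals, stage-wise adjusted estimates,
conditional power, covariate-adjusted interim estimation, adaptive
sample-size re-estimation, exact (non-asymptotic) binomial power,
dynamic randomization/minimization and time-to-event endpoints are out
of scope. The futility levels assume the $\beta$-spending construction;
monitors using a different futility rule should recompute boundaries
accordingly.
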