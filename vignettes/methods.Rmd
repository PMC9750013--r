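---
title: "Models and methods behind vaccshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vaccshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions they carry, the numerical choices made where the
design was genuinely open, and what the synthetic-data tests do and do
not establish. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

# The factorial experiment and its regression

Each respondent evaluates two hypothetical vaccine-sharing scenarios
drawn uniformly and independently from the 20 cells of a 2 × 2 × 5
design. The five-level deal factor deterministically encodes two numeric
scenario variables — the number of other countries contributing and
their joint total in billion € — so the analysis regressors are

* `X1` *amount*: total given by others, billion € (0, 20 or 40),
* `X2` *n_countries*: number of others giving (0, 20 or 40),
* `X3` *risk*: mutation-risk scenario indicator,
* `X4` *trade*: economic-loss scenario indicator.

`X1`/`X2` enter in natural units rather than as level dummies because
the reported quantity of interest is a single average marginal effect
per condition; scalar coding makes "per billion €" and "per country"
effects directly readable. The unit choice affects coefficient
magnitudes, never signs or t statistics.

All four columns are centered **at the realized sample mean** of the
analysis set, not the theoretical design mean: under unbalanced realized
assignment this is what makes main terms of the fully interacted model
equal average effects. Interactions are elementwise products of the
centered mains, up to three-way — the full specification has exactly 14
slope terms and deliberately no four-way term (a configuration switch on
`build_design_matrix(interaction_order =)` reduces the order; adding the
four-way term is out of scope).

Respondent fixed effects are absorbed by within-respondent demeaning,
which scales to panels of tens of thousands without forming dummy
columns; the test suite keeps the explicit `lm(y ~ X + factor(id))`
dummy regression as a Frisch–Waugh oracle and requires term-for-term
agreement to 1e-8. After demeaning, the intercept is reported as the
grand mean of the outcome, preserving its "average support level"
reading.

## Robust variance

The published description says only "robust standard errors". With two
vignettes per respondent, repeated measures make clustering by
respondent the defensible default, so `se_flavor = "cluster"` (CR1, t
reference on G − 1 degrees of freedom) is the default and an HC2-style
flavor documents the ambiguity. Two conventions matter and are easy to
get wrong:

* In the CR1 small-sample factor (N − 1)/(N − k), the absorbed
  respondent intercepts are **not** counted in k, because they are
  nested within clusters. Counting them roughly doubles the variance
  with two observations per respondent; the package's null simulations
  (500 replicates, 500 respondents) showed exactly that pathology before
  the convention was adopted, and ~5% empirical size after.
* The HC2 flavor computes leverages on the *absorbed* model: the hat
  value of observation `ij` is its within-regression leverage plus
  `1/n_i` from the respondent intercept.

# The structural public-goods model

A respondent choosing own contribution `y ≥ 0` (billion €) given others'
total `S` and others' average `ȳ` maximizes

    u(y) = M · log(S + y) − γ (y − κ ȳ)² − y²,   M = α + β·E + δ·H,

with `E`, `H` the 0/1 economic- and health-risk indicators. The model is
a standard benefit-minus-cost public-goods formulation with diminishing
returns (the log), convex own costs (the quadratic), and a peer
benchmarking term: γ weighs how much alignment with other states
matters, κ is the multiple of their average contribution the respondent
targets. Risks enter M as raw 0/1 indicators, uncentered, and all money
is in billion € throughout. In no-deal cells `ȳ = 0`, so the peer term
degenerates to `−γy²` and is simply absorbed alongside the cost term —
implemented literally, with no special-casing.

## The optimum in closed form

The first-order condition `M/(S+y) = 2γ(y − κȳ) + 2y` expands to

    2(γ+1) y² + 2[(γ+1)S − γκȳ] y − (2γκȳS + M) = 0.

With M > 0 the constant term is negative, so the quadratic has exactly
one positive root, and strict concavity of `u` on `y > 0`
(`u'' = −M/(S+y)² − 2γ − 2 < 0`) makes that root the global maximum.
Production code uses the closed form (clamped at zero); brute-force grid
maximization (step 1e-3) exists only as the independent test oracle, and
1000 random admissible draws must agree within the grid resolution.
`M ≤ 0` at any used cell is rejected at fit time rather than silently
clamped: an interior optimum is no longer guaranteed there.

## Maximum likelihood and its numerics

Reports are `y* + ε`, `ε ~ N(0, σ²)`, i.i.d. across all observations —
including the two vignettes of the same respondent, which is how the
reporting model is stated. The likelihood is maximized with BFGS over
`(α, β, δ, log γ, κ, log σ)`; the log scale keeps the optimizer in an
open box while honoring σ > 0, γ ≥ 0 (a `fix_gamma` flag removes the
peer term entirely; γ estimates near zero are otherwise reachable down
to numerical underflow of `exp`). Inadmissible regions (M ≤ 0 at a used
cell) return a large finite penalty instead of an error so line searches
can back off. Starting values: α from the heuristic
`2(γ₀+1)·mean(y)²` with γ₀ = 0.5, κ₀ = 1, σ₀ = sd(y), β₀ = δ₀ = 0, plus
seeded multiplicative jitter for the remaining starts (5 total by
default), because the likelihood is not guaranteed unimodal in (γ, κ);
the best value over starts is returned with the full start record.
Standard errors are the inverse observed information — a numeric Hessian
of the negative log-likelihood at the optimum, computed on the *natural*
parameter scale so no delta-method step is needed; if it is not positive
definite the fit is returned with SEs flagged unavailable rather than
failing. Wald intervals use the full-precision normal quantile
(1.959964…), not 1.96.

## Identification at the published noise level — why one acceptance test is red

This is the package's most important empirical finding about its own
stated world. At the published parameter values (α = 240.62, γ = 0.61,
κ = 5.22, σ = 15.98) the 20 design cells' optima `y*` span only about
3.7–9.3 billion €. A radically different sextet (e.g. α ≈ 141, γ ≈ 0.06,
κ ≈ 34) reproduces **all twenty cell optima within ≈ 0.5 bn** — the same
order as the Monte-Carlo error of a cell mean at 1 000 observations per
cell. The likelihood surface therefore has a long, nearly flat, curved
ridge in (α, γ, κ): with 20 000 observations the MLE regularly attains a
*higher* likelihood than the truth while sitting far away along the
ridge. The multi-start optimizer is verified to reach at least the
truth's likelihood at every acceptance seed, so this is geometry, not an
optimization failure. Hessian-based Wald intervals are local quadratic
approximations and understate uncertainty along a curved ridge; in the
five-seed recovery harness, 29 of 30 parameter checks land within 3
reported SEs of truth and one (γ at one seed) lands at |z| ≈ 3.2. The
criterion is asserted exactly as stated and left red rather than
widened. Two corollaries worth knowing: (i) recovery *of the cell-mean
surface* and of σ is excellent; (ii) the tight published standard errors
are much smaller than the information content of model-generated data at
this n, consistent with the real data pinning the parameters through
curvature the model itself does not generate. The estimator's
correctness is separately established in a well-identified world
(σ = 2), where all parameters recover within 3 SEs and estimation error
shrinks with n.

## Printed-rounding in the published confidence bounds

Reconstructing the published 95% bounds from the *printed* (estimate,
SE) pairs reproduces 9 of the 12 bounds at two decimals; the three lower
bounds for δ, γ and σ come out exactly one unit low in the second
decimal (13.39 vs 13.40, 0.47 vs 0.48, 15.82 vs 15.83). Interval
arithmetic over the half-ulp input ranges shows the printed bounds are
consistent with *unrounded* inputs, and no plausible normal quantile
fixes all three rows simultaneously — so the discrepancy is input
rounding, not implementation. The acceptance test asserts the criterion
as stated and is left red with this analysis.

# The synthetic cohort: a stated world

The generator emulates the statistical structure the analysis assumes,
so that every downstream stage is testable without any download:

* **Demographics.** Age group, sex and federal state are drawn
  independently from official-statistics marginals for the 18–75 German
  population (the survey quotas marginals, not joints — independence is
  therefore the faithful choice). The printed region column sums to
  1.01 from rounding; each margin table is renormalized to sum to one.
* **Assignment.** Two vignettes per respondent, uniform over the 20
  cells, seeded.
* **Contributions.** `cash = y*(cell) + u_i + ε`, with `u_i ~ N(0, 5²)`
  a respondent-level intercept shift. The reporting model itself has no
  `u_i`; it exists (default SD 5 bn, the order of the between-cell
  spread of y*) so the fixed-effects machinery has something real to
  absorb. Censoring at zero is ON by default — stated contributions
  cannot be negative — but the parameter-recovery world sets
  `censor_at_zero = FALSE` **and** `heterogeneity_sd = 0`, because the
  fitted likelihood is an uncensored i.i.d. Normal: leaving either on
  would make the recovery test measure model mismatch (σ would converge
  to the total SD √(σ² + sd_u²)), not estimator quality.
* **Doses.** A scaled-plus-noise companion of cash (12.5 million doses
  per billion €, ≈ €80bn buying ~1bn doses at €6–8 per dose), not a
  second structural fit.
* **Video experiment.** Attitude: Normal around 4 on an arbitrary 1–7
  scale (the real scale is not in the main text), shifted by 0.069 under
  treatment, clipped at the bounds (clip probability ≈ 0.3%, so the
  realized ATE is essentially undistorted). Donation: with probability
  1/3 the full 50 points (the observed point mass), otherwise
  Binomial(49, p) whose mean shifts by `ate/(1 − p_full)` under
  treatment — binomial support keeps the outcome inside [0, 49] with
  no clipping, so the marginal ATE equals the configured
  `ate_donation_points` (default 2 points = 4 pp of the endowment)
  exactly in expectation. The non-full mean 17.5 puts the overall median
  share near 40%.
* **Priorities.** Three categories with P(strictly higher) = 0.38,
  P(at least as high) = 0.57 as simulation truth.

What the generator does **not** attempt: the heavy right skew of real
stated amounts (real median ≈ €2bn vs mean ≈ €8bn implies a long tail
the Normal reporting model cannot produce), panel attrition and
refreshment, joint demographic structure, and any real response-entry
interface. A green test therefore establishes that the estimators
recover the *mechanism they assume*, on data generated by that
mechanism — not that the mechanism describes real respondents.

# Descriptive conventions and small numerical choices

* "High costs" = both scenario burdens active (trade = 1 AND risk = 1),
  "low costs" = neither; mixed cells are excluded from the cost
  grouping — the looser verbal description is resolved to this strict
  rule. "High multilateralism" = any deal (deal ≠ 0). Custom groupings
  pass a labelling function; empty groups are emitted with `n = 0` and
  `NA` shares, never dropped silently.
* Threshold grids default to the observed unique outcome values; a
  fixed grid can be supplied for cross-run comparability, and both
  vignettes per respondent are pooled (the descriptive surfaces have no
  within-respondent structure).
* Modal donation ties break toward the smallest point value; medians are
  the standard sample median (mean of middle order statistics at even
  n).
* Degenerate inference is flagged, not hidden: a two-arm comparison with
  zero pooled variance returns SE 0 with `degenerate = TRUE`; a
  zero-variance regression outcome returns exact zero slopes.
* All randomness flows from one master seed through fixed per-stage
  offsets (`seed + stage·1000003 mod 2³¹−1`), so identical configs give
  byte-identical tables while different stages stay decoupled.

# Known limitations

* The structural likelihood ignores the within-respondent correlation
  induced by `u_i`-style heterogeneity (as stated, it treats a
  respondent's two reports as independent) and offers no Tobit-style
  censored variant; both are out of scope.
* The weak-identification ridge above means structural point estimates
  at realistic noise levels should be read jointly with their likelihood
  surface, not as six separate well-measured quantities.
* The fixed-effects regression drops no-variation cases with an error by
  design; it does not implement survey weights, attrition adjustment, or
  multiple-testing corrections across the 14 terms.
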