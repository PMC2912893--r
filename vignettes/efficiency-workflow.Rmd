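---
title: "Efficiency estimation, reliability filtering and efficiency clustering for low-density qPCR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficiency estimation, reliability filtering and efficiency clustering for low-density qPCR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcreff)
```

## The measurement problem

Low-density qPCR arrays carry on the order of 96–1024 primer pairs, and the
usual ΔΔCT analysis of their threshold-cycle (CT) readouts assumes every
reaction doubles its product each cycle. Real per-cycle amplification
efficiencies `E` scatter around 2, and because the readout is exponential in
the cycle count, even modest efficiency differences translate into
multiple-fold errors in relative expression. `qpcreff` implements a complete
serial-dilution workflow that (i) estimates `E` per primer with a confidence
interval, (ii) purges primers whose estimates are unreliable, (iii) groups
the survivors into a small number of shared-efficiency clusters, and (iv)
produces efficiency-adjusted CT values that drop into any downstream
log-scale expression analysis.

## Model and estimation

For each primer, CT is regressed on the base-2 log of the relative template
concentration `d` (1, 0.1, 0.01, 0.001 in the standard design):

    CT = beta0 + beta1 * log2(d) + eps,   eps ~ N(0, sigma^2)

Base-2 logs give the slope a direct reading: one extra cycle per halving of
template, `beta1 = -1`, is perfect doubling. The efficiency transformation is

    E = 2^(-1 / beta1),   beta1 < 0,

which is strictly increasing on negative slopes and maps `beta1 = -1` to
`E = 2`. A dilution series with `d * E^CT` constant yields exactly this
relation, with `beta1 = -1/log2(E)`.

The slope's standard normality-based confidence interval
`beta1 ± t_{(1-level)/2, n-2} * se(beta1)` (1 or 2 degrees of freedom for 3
or 4 dilution points) maps through the same monotone transformation to an
efficiency interval whenever its upper slope endpoint is negative. The
*length* of this transformed interval is the workflow's reliability measure:
it grows explosively as the slope approaches zero (a slope of −0.02 implies
`E ~ 10^15`), so imprecise or non-informative dilution curves are visible at
a glance regardless of where their point estimate happens to fall.

CT values above a detectability cutoff (default 40 cycles, strictly greater)
are treated as missing; values at the cutoff are kept. Raw CT values are used
throughout — no plate normalization is assumed.

## The three-stage purge

`assess_reliability()` assigns each primer the first applicable status:

1. **Missing values** — fewer than 3 detectable points cannot support a line
   with any residual degree of freedom. (With the 4-level design this is the
   "half the curve is missing" rule; the 3-point floor generalizes it to
   other designs.)
2. **Slope significance** — the two-sided t-test of the slope must reject at
   `alpha` (default 0.05) *and* the slope must be negative. The t-statistic
   is preferred over an R² threshold because it accounts for the number of
   dilution steps. Requiring a significant negative slope at level `alpha`
   also guarantees that the `1 - alpha` slope interval stays below zero, so
   every survivor has a defined transformed interval.
3. **CI-length outliers** — survivors whose transformed-interval length
   exceeds the Tukey fence `Q3 + 1.5 * IQR` of the surviving lengths are
   removed. Quantiles use linear interpolation between order statistics
   (type 7); the convention is configurable because at a few dozen primers
   the flagged set can depend on it. If the user decouples the CI level from
   `alpha`, undefined intervals are treated as infinitely long and always
   flagged. With fewer than 4 survivors the quartiles are meaningless, so
   the stage warns and removes nothing.

The statuses are exclusive and ordered; a fully censored primer is reported
as missing even though its slope test would also fail.

## Diagnostics for pooling

Before primers can be compared through a joint model, the per-primer
residuals should be compatible with a shared error distribution.
`qpcr_diagnostics()` runs Bartlett's test of equal residual variances across
primers (before and after the purge — the purge typically restores
homoscedasticity), the Shapiro–Wilk test on the *pooled* residuals of the
kept fits (pooled rather than per-curve, since each curve contributes only
1–2 residual degrees of freedom), and the nested-model F-test of slope
heterogeneity: per-primer intercepts with one common slope against
per-primer intercepts and slopes,

    F = ((RSS_r - RSS_f) / (P - 1)) / (RSS_f / (N - 2P)).

Exact fits (zero residual variance) are excluded from Bartlett's statistic
with a warning; the case arises only in noise-free synthetic data.

## Efficiency clustering

Slope heterogeneity says individual efficiencies differ; using all of them
individually invites over-fitting, while one global mean ignores real
differences. The middle ground is a grouped-slope model: per-primer
intercepts, one slope `gamma_g` per group. For a candidate group the pooled
least-squares slope has the closed form
`sum_i Sxy_i / sum_i Sxx_i` over within-primer centered cross-products, and
the group's RSS follows directly, so any contiguous segment of slope-sorted
primers is scored in O(1) after prefix sums.

`optimal_partition()` finds, among all partitions of the kept primers into
`k` segments contiguous in individual-slope order, the one minimizing total
RSS (equivalently maximizing R²), by exact dynamic programming. Restricting
to slope-contiguous partitions is what makes exact search feasible; since
groups differ only through a scalar slope, an RSS-optimal partition is
expected to be slope-ordered anyway. Cost ties (relative tolerance 1e-9) are
broken toward more balanced group sizes, then the lexicographically smallest
boundary set, so results are reproducible under permutation of the input.

`select_clusters()` grows `k` from 1, accepting `k + 1` while the nested
F-statistic `(RSS_k - RSS_{k+1}) / (RSS_{k+1}/df)` with
`df = N - (P + k + 1)` is significant at `cluster_alpha`. Each primer then
inherits its group's pooled-slope efficiency `E_g = 2^(-1/gamma_g)` — a
variance-weighted group average rather than the arithmetic mean of member
efficiencies; for tight clusters the two are indistinguishable, and the
pooled slope is what the grouped model actually estimates. Two guards ensure
termination: a perfect-fit threshold (`RSS <= 1e-12` of the total CT sum of
squares stops the search, so noise-free data return without dividing by
zero) and a hard cap `k_max` (default 15).

**A calibration caveat, measured honestly.** The F-test at each step is
applied to the *selected* (R²-maximizing) partition, mirroring the
procedure's published definition. Selecting the best split before testing it
inflates the statistic far beyond its nominal null distribution: splitting
slope-sorted estimates optimally is one-dimensional 2-means, and the best
split of pure noise already captures several `sigma²` of apparent
improvement. Simulation with this package (2,000 replicates, 8 primers, one
common slope, `alpha = 0.05`) puts the realized probability of accepting at
least a second group at ~0.68, not 0.05, and on the package's 96-primer
reference scenario with 7 planted groups the selection typically runs to the
`k_max` cap instead of stopping near 7. The *partition* found at any given
`k` is excellent (the first split on two-group data is essentially always
correct, and agreement with planted truth measured by the Rand index stays
well above 0.8 on the reference scenario); it is the *stopping rule* that is
anti-conservative. Users
who need a calibrated group count should treat `k` as an upper bound, lower
`cluster_alpha` substantially, or fix `k` from subject-matter grounds; the
default faithfully reproduces the published procedure rather than a
statistically corrected variant.

## Adjusted CT, expression ratios, and scheme comparison

The adjustment `CT* = CT * log2(E)` converts an observed cycle count into
the cycles a perfect-doubling reaction would have needed: `2^CT*` equals the
true fold quantity `E^CT`. Data adjusted this way stay on the log2 scale and
feed unchanged into standard microarray-style downstream tools. The
accompanying fold difference `2^(CT - CT*)` quantifies the error committed
by assuming perfect efficiency. Relative expression between reactions A and
B is `E_B^{CT_B} / E_A^{CT_A} = 2^(CT*_B - CT*_A)` (amount of A relative to
B; higher CT means less template).

To compare correction schemes, the adjusted fold change of a dilution-series
well, `AFC = E^CT * d`, is constant across the series exactly when the
assumed `E` is right, so the coefficient of variation of a primer's AFC
values (sample standard deviation over mean, by default — with 3–4 wells the
n−1 choice is material and configurable) scores the assumed efficiency.
`compare_schemes()` ranks per-primer CoV curves for four schemes: fixed
`E = 2`, the global mean of individual estimates, cluster efficiencies, and
individual efficiencies. On heterogeneous arrays the expected ordering —
perfect worst, global next, cluster ≈ individual best — emerges clearly.

Two printed-form ambiguities in the source material were resolved by
requiring internal consistency: the efficiency transformation must be
increasing for negative slopes and map −1 to 2 (fixing `E = 2^(-1/beta1)`),
and the AFC must be constant at the true efficiency (fixing the direction
`E^CT * d` rather than division by `d`).

## The synthetic-data generator

Real reference datasets for this workflow are not publicly deposited, so
`simulate_dilution_table()` generates tables with known ground truth: clean
primers follow the linear model with `beta1 = -1/log2(E_true)`, uniform
intercepts (default 16–24 cycles, keeping the weakest wells below the
censoring cutoff), and Gaussian residuals (default sd 0.08 cycles, the
scale at which fitted curves show R² > 0.98 as good arrays do). Planted
defects mimic the three failure modes the purge targets: fully censored
curves, zero-slope curves, and curves with residual sd inflated 25-fold.
`simulate_qpcr_array()` fixes the reference scenario used throughout the
tests: 96 primers, 4 dilution levels, 7 efficiency groups spanning
1.72–2.14, and defect counts 3/8/7, so 78 clean primers remain.

One generator subtlety is deliberate. With only 2 residual degrees of
freedom per curve, the realized residual scale of a Gaussian draw is highly
dispersed, and the upper tail of clean transformed-CI lengths can cross the
1.5×IQR fence by chance — defeating any seed-independent statement about
what the purge should find. With `calibrate_noise = TRUE` (the reference
scenario's default) each curve's residual vector is rescaled so its realized
regression residual sd equals the nominal value exactly; clean CI lengths
then depend essentially only on the efficiency group (at most ~1.8 fence
units, against a fence near 2.3 and noise-inflated lengths above 17), and
the purge's recovery of the planted defects is guaranteed by construction.
The price is that calibrated residuals are no longer exactly Gaussian (the
pooled Shapiro–Wilk test will reject on large calibrated arrays, and slope
errors acquire t-like tails); coverage and calibration studies therefore use
the plain Gaussian mode. A zero-slope planted defect is *not* guaranteed to
fall at the slope stage — under an exact null the slope p-value is uniform,
so a few percent of flat curves show a nominally significant negative slope;
those carry astronomically long transformed intervals and are caught at the
CI stage instead. What is guaranteed is that the kept set equals the planted
clean set.

What passing on this generator does **not** show: robustness to
plate-position effects, replicate-well structure, non-Gaussian instrument
noise, censoring informatively correlated with efficiency, or curvature in
the CT–log-dilution relation. The generator matches the model the estimators
assume; it validates the machinery, not the model.

## Numerical and design choices

* Quantiles: type 7; configurable (`quantile_type`).
* Perfect fits: `se(beta1) = 0` yields a zero-length interval, not an error
  — the valid noise-free limit.
* A curve with identical CT at all levels gets `beta1 = 0`, `p = 1`,
  `R² = 0` rather than an undefined test.
* Partition ties: balance, then lexicographic boundaries (tolerance 1e-9).
* `k_max = 15` and the 1e-12 relative RSS guard exist purely for
  termination; noisy real data need neither.
* The CI level is tied to the slope-test `alpha` by default
  (`ci_level = 1 - alpha`) so the transformed interval is always defined
  for survivors.
* Long CSV (`primer, dilution, ct`) is the canonical on-disk form — it
  generalizes to replicate wells; wide tables are accepted for convenience.
* Reports are written with 17 significant digits and reread with a
  correctly-rounding parser, so round-trips are bit-exact.

Test-suite problem sizes: oracle-equivalence checks use 20–100 random small
tables; calibration and coverage checks use 2,000 replicates of 8-primer or
single-primer designs; recovery checks use the 96-primer reference scenario
and 20 seeds of it for cluster-assignment agreement. These sizes give
binomial standard errors well below the asserted margins while keeping the
full suite to a few minutes.

## Limitations

* No replicate-well averaging, weighted or robust regression.
* No multiple-testing correction across the per-primer slope tests (the
  published procedure applies none).
* The cluster-count stopping rule is anti-conservative by construction (see
  above); the package reports the trace (`$trace`) so users can apply their
  own stopping criterion.
* No significance testing of expression ratios between treatment groups;
  the adjusted CT values are meant to feed existing downstream tools.
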