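---
title: "Methods: comparing two groups of bounded count outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two groups of bounded count outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countcompare)
```

## The problem

Many clinical outcomes are *discrete numerical*: counts of events per
individual on a small bounded scale such as {0, 1, 2, 3} — emergency
department visits, repeat episodes, units transfused. Such variables sit
between ordered-categorical and continuous data. Treating them as
ordered categories discards the constant spacing between values and
loses power; treating them as continuous raises the question of which
continuous-data methods actually keep their nominal error rates on
heavily tied, bounded, often skewed samples.

Because the scale is bounded, there are no outliers in the usual sense,
and the **difference between the two group means** is a directly
interpretable effect measure (bounded by ±K on the scale {0, …, K}).
countcompare implements the standard two-sample tests and confidence
intervals for that effect measure, together with the Monte-Carlo
machinery needed to evaluate them: estimated true significance level,
power, coverage probability, interval length, and overshoot beyond the
largest possible difference.

A second effect measure, the relative effect
$p = \Pr(X < Y) + \tfrac12 \Pr(X = Y)$, is reported alongside the
rank-based tests; 0.5 means stochastic equality.

## Group-order convention

Group 1 is always the first-listed group (first factor level in the
data-frame interface; first count column in a grouped file), and every
reported difference is `mean(group1) - mean(group2)`. Swapping the
groups flips the signs of estimates and statistics, maps the relative
effect to its complement, and leaves two-sided p-values unchanged. This
single convention is applied everywhere, including the bundled clinical
examples.

## The hypothesis tests

All tests are two-sided at a nominal 5% level by default.

* **Pooled T** (`t_test_pooled`): the ordinary two-sample T statistic
  with pooled variance and $m + n - 2$ degrees of freedom.
* **Welch U** (`welch_u_test`):
  $t = (\bar x_1 - \bar x_2)/\sqrt{s_1^2/m + s_2^2/n}$ with
  Welch–Satterthwaite degrees of freedom
  $\nu = (s_1^2/m + s_2^2/n)^2 / [(s_1^2/m)^2/(m-1) + (s_2^2/n)^2/(n-1)]$.
* **Wilcoxon–Mann–Whitney** (`wmw_test`): rank sum on mid-ranks with
  the tie-corrected variance
  $\mathrm{var} = \frac{mn}{12}\bigl[(N+1) - \sum_j (t_j^3 - t_j) / (N(N-1))\bigr]$
  and a normal approximation **without** continuity correction. The
  tie-corrected variance is exactly the variance of the rank sum over
  all label assignments, which the test suite verifies by full
  enumeration. The no-continuity-correction choice is validated against
  the bundled worked example (p = 0.001 at three decimals; with the
  correction the value is indistinguishable at that precision).
* **Brunner–Munzel** (`brunner_munzel_test`): with combined-sample
  mid-ranks $R$ and within-group mid-ranks $R^{(i)}$, rank means
  $\bar R_1, \bar R_2$ and empirical rank variances
  $S_i^2 = \frac{1}{n_i - 1}\sum_k \bigl[R_k - R_k^{(i)} - \bar R_i + \frac{n_i+1}{2}\bigr]^2$,
  the statistic is
  $W = m n (\bar R_2 - \bar R_1) / (N \sqrt{m S_1^2 + n S_2^2})$
  referred to a t distribution with a Satterthwaite-type df. Unlike the
  WMW test it remains valid when the two distributions differ in shape.
* **Brunner–Munzel permutation** (`bm_permutation_test`): the p-value is
  the proportion of random relabellings — observed configuration
  included in numerator and denominator — whose $|W|$ is at least the
  observed $|W|$ (default 10 000 permutations).

**Degenerate data.** Small discrete samples are regularly constant
within both groups. Rather than abort (which would poison Monte-Carlo
loops), a zero standard error yields p = 1 when the group summaries are
equal and p = 0 with a `degenerate` flag when they differ. Inside the
permutation loop a degenerate resample contributes $|W| = 0$ when the
rank means tie and $\infty$ otherwise, so it always counts as extreme.

## The confidence intervals

Three 95% intervals for the mean difference:

* **Welch U** (`welch_interval`): $d \pm t_{\nu, 0.975}\, SE$, the
  interval consistent with the Welch U test (p < α exactly when 0 is
  outside the 1 − α interval). The ordinary T interval is deliberately
  not offered: its variance estimate is the one that breaks down under
  unequal sample sizes.
* **Percentile bootstrap** (`percentile_bootstrap_interval`): each group
  resampled independently with replacement (group sizes preserved),
  limits at the empirical 2.5% and 97.5% quantiles of the resampled mean
  differences (default B = 2000).
* **Bootstrap-t** (`bootstrap_t_interval`): studentised resampling,
  $t^* = (d^* - d)/SE^*$ with the Welch SE of each resample; the
  interval is $[d - q^*_{0.975} SE,\; d - q^*_{0.025} SE]$ with the
  observed Welch SE.

**Quantile convention.** Bootstrap limits use the order statistic with
index $\lceil qB \rceil$ and no interpolation. The convention is
deliberately simple and unambiguous at B = 2000, so the exhaustive
oracle in the test suite (all $3^3 \times 3^3 = 729$ resample pairs at
m = n = 3) can mirror it exactly.

**Degenerate resamples.** A resample with $SE^* = 0$ contributes
$t^* = 0$ if its mean difference equals the observed one, and otherwise
a sign-preserving largest-representable value. This keeps the resample
distribution complete (no redrawing, no silent dropping) and the whole
computation deterministic. The consequence is discussed under
*Known limitations*.

**Overshoot.** When the scale maximum K is known, each interval records
whether a limit lies beyond ±K — the largest difference two means on
{0, …, K} can possibly have. An overshooting interval is nonsensical to
a reader even when it covers the true value.

## The distribution families

Six pmf families on {0, …, K} serve as simulation ground truth, with
the standard expected values on the four study scales (K = 2…5):

| family       | construction                                   | means (K=2,3,4,5) |
|--------------|------------------------------------------------|-------------------|
| uniform      | all g = K+1 values equally likely              | K/2 |
| normal       | binomial(K, ½) weights                          | K/2 |
| u-shaped     | weights ∝ 1 + \|i − K/2\|                       | K/2 |
| linear trend | $p_i = a - b i$, closed-form solve              | 0.63, 1.0, 1.25, 1.625 |
| step         | two levels, high below `step_location`, closed form | 0.8 & 0.6, 0.9, 1.1, 1.6 |
| skewed       | truncated geometric $p_i \propto r^i$, r solved numerically (tol 1e-10) | —, 0.6, 0.75, 0.88 |

Linear-trend and step are uniquely pinned by normalisation and the
target mean (given `step_location`); an infeasible combination (a
negative cell) is a constraint error naming the offending cell. The
normal, u-shaped and skewed shapes are *this package's* default
reconstructions satisfying the qualitative shape and the target mean;
the original study's exact vectors for these three families are not
published in its main text, so per-cell simulation results can differ
slightly from the original report. Any pmf can be replaced verbatim via
`read_distributions()` (rows `family, K, p_0 … p_K`) and passed to the
study runners through their `dists` argument.

On {0, 1, 2} no skewed family is feasible as a strictly decreasing
geometric with the required mean, and the reference set instead carries
two step placements: `step` (step at 2, mean 0.8) and `step2` (step at
1, mean 0.6) — the only two-level placements matching the target means.
The default `step_location` is ⌈g/2⌉ (2, 2, 3, 3 for K = 2…5), which
reproduces the pinned step pmfs such as (0.4, 0.4, 0.1, 0.1) on
{0, 1, 2, 3}.

## The evaluation harness

`run_test_scenario()` draws sample pairs from two pmfs and reports the
percent of p-values below the nominal level, with the binomial
Monte-Carlo standard error $\sqrt{p(1-p)/\text{reps}}$. A scenario is
*null* when the two distribution means agree within 1e-9; then the rate
estimates the **true significance level**, otherwise **power**.
`run_ci_scenario()` reports coverage of the *analytic* mean difference
(never a sample-based stand-in), mean interval length and the overshoot
rate; the two bootstrap methods share one set of resample draws per
replication.

**Robustness bands** are nested around the nominal rate: within ±10% of
the error probability (4.5–5.5 for 5% tests, 94.5–95.5 for 95%
intervals) is 10%-robust; within ±20% (4.0–6.0 / 94.0–96.0) is
20%-robust; outside is nonrobust. The bands are implemented
symmetrically; the upper 20% limit for tests is 6.0, forced by the
nonrobust rule (p < 4.0 or p > 6.0) and by the interval analogue.

**Scenario grids.** With six distributions there are 36 ordered pairs,
12 of them null. When m = n the pair order is irrelevant and the grid
reduces to 21 unordered pairs, 9 null — the enumeration is keyed on
m = n exactly. Summary metrics follow the study design:
`mean_deviation_summary()` averages |rate − 5| over the null
combinations, and `relative_power_summary()` sums power-scenario
rejection rates and scales by the best test's sum (computed per
(scale, m, n) row, so the best test in each row scores exactly 100; the
alternative — one reference value across all rows — would mix sample
sizes and is not used).

**Reproducibility.** Every scenario derives its own seed substream by
hashing (root seed, study type, scale, pair, sizes, method) onto a
32-bit integer, so results are byte-identical across runs and
independent of enumeration order, and a single scenario rerun standalone
reproduces its row inside a study.

**Problem sizes.** The package defaults are desk-scale: 10 000
replications per test scenario and 2 000 per interval scenario
(bootstraps at B = 2 000). The original full-scale profile
(100 000 / 10 000) is a configuration choice away
(`replications = 1e5`). The bundled acceptance checks use 10 000
replications for the headline level/coverage scenarios, 4 000 for the
unequal-sample-size robustness comparison, and 100 per scenario for the
all-scales overshoot sweep.

## What the generator emulates — and what it does not

The generator reproduces the *marginal* structure the evaluation is
about: bounded supports, heavy ties, symmetric and skewed shapes, equal
and unequal means, equal and unequal sample sizes. It does not emulate
covariates, within-subject correlation, missingness, or
rounding/censoring processes in real trial data. A test passing the
simulated robustness bands is therefore evidence about tied bounded
counts as such, not about every design that produces them.

## Numerical choices

* pmf validity: probabilities ≥ 0, sum to 1 within 1e-12; factory means
  hit their targets within 1e-9 (symmetric families are exact by
  construction; the skewed ratio solve is accepted at 1e-10).
* Null labelling of scenario pairs: mean equality within 1e-9.
* Mid-ranks via `rank()` (average ties); permutation comparisons use a
  1e-12 slack so float noise never flips an inequality at the boundary.
* Bootstrap quantiles: ⌈qB⌉ order statistic, no interpolation.
* Degenerate rules as above; they are deterministic and flagged, never
  silent.

## The clinical examples

Two bundled grouped-counts fixtures reproduce published analyses
end-to-end (`reproduce_example()` pairs every computed statistic with
its published value and a match flag at printed precision):

* **ng-asthma** — emergency-department visits, intensive (n = 55) vs
  standard (n = 45) asthma education: difference 0.83, 95% CI 0.36 to
  1.30, Welch p = 0.0007 (pooled T 0.0003, WMW 0.001).
* **carter-men** — repeat deliberate self poisoning in men, postcard
  intervention (n = 145) vs control (n = 102): difference 0.0059,
  95% CI −0.14 to 0.15, Welch p = 0.94. The published postcard row sums
  to 150, not the stated 145; the fixture stores the unique reconciled
  counts (125, 13, 5, 2, 0) consistent with the arm size and the
  published mean 0.20 (sd 0.56), keeps the published row in a separate
  file, and warns on load.

## Known limitations

* **WMW at very small n.** At m = n ≤ 5 with heavy ties the normal
  approximation can sit far from the exact enumeration p (deviations up
  to ≈0.4 in extreme-tie configurations). The test suite checks the
  machinery sharply through the exact permutation moments and documents
  loose tolerances for the p comparison; exact enumeration exists in
  the suite as an oracle, deliberately not as a user-facing method.
* **Bootstrap-t limits can explode at n = 10 on zero-heavy pmfs.** When
  a pmf puts ≥ 0.5 mass on one value, more than 2.5% of resamples of a
  size-10 sample are regularly constant; the documented degenerate-
  resample rule then places the 2.5% t* quantile at the huge sentinel
  value and the interval limit far beyond ±K, i.e. an overshoot. This
  is a real property of the bootstrap-t on such data under this
  (deterministic, unbiased) handling — alternative handlings (dropping
  or redrawing degenerate resamples) would hide it at the cost of a
  biased resample distribution. The rare Welch overshoots on the
  {0, 1, 2} scale at m = n = 10 trace to the heavy-endpoint u-shaped
  reconstruction. Consequently the overshoot sweep in this package
  reports small nonzero bootstrap-t rates rather than an identically
  zero rate.
* **Reconstructed pmfs.** Normal, u-shaped and skewed are reconstructed
  from shape plus mean; per-cell rates can differ from the original
  study's detailed tables even though the qualitative findings (Welch U
  robustness, WMW/T fragility under unequal sizes, percentile-bootstrap
  undercoverage) are reproduced by the bundled checks.
* Scope: two groups, two-sided tests, scales without composite limits
  ({0, 1, 2, 3+}-style upper categories bias the mean and are not
  supported).
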