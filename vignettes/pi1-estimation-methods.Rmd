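---
title: "Estimating the proportion of differentially expressed genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the proportion of differentially expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pi1est)
```

# The estimation problem

In a two-group expression study every gene is tested for a difference in
mean expression between populations.  With G genes tested at once, error
control is phrased through the false discovery rate, and every
mixture-model FDR estimator reduces to

$$\widehat{FDR}(\alpha) = \frac{\alpha\,\hat\pi_0}{\hat F_p(\alpha)},$$

where $\hat F_p(\alpha)$ is the observed fraction of P-values below the
threshold and $\pi_0 = 1 - \pi_1$ is the proportion of non-DE genes.
$\hat F_p$ is essentially free; the entire statistical difficulty sits in
$\hat\pi_1$.  `pi1est` implements two classes of routes to $\hat\pi_1$
and a simulation benchmark that compares them.

# Test statistics

The Welch two-sample t-statistic is used throughout, exactly in its
unequal-variance form (there is deliberately no pooled-variance option:
the benchmark's variance regimes make the groups heteroscedastic).  The
SAM s-statistic adds a stabilizing constant $\delta \ge 0$ to the
denominator; `pi1est` follows the percentile convention for $\delta$: the
30th/50th/70th/90th percentile of the gene-wise t-denominators (families
`s30`, `s50`, `s70`, `s90`).  Percentiles use the linear-interpolation
convention (rank $1 + (n-1)p/100$, `stats::quantile` type 7); the
convention is isolated in `delta_from_percentile()` so an alternative is
a one-line change.  With $\delta = 0$ the s-statistic is the t-statistic
to machine precision, a reduction the test suite asserts.

**Rescaling.**  Because $\delta$ shrinks every statistic toward zero, an
s-statistic vector has smaller spread across genes than the matching
t-statistic vector.  For estimators that model the statistic scale
(the empirical-null route below), the s-statistics are multiplied by
spread(t)/spread(s), with spread either the SD or the IQR of the *signed*
statistics across genes — signed, not absolute, which is the plain
reading of a spread of statistics; the choice matters little for the
near-symmetric vectors produced here.  Rescaling is a positive scalar
multiplication, so ranks — and hence ROC behavior — are untouched.

**Degenerate genes.**  A gene whose two sample variances are both zero
has an undefined statistic.  Such genes get `NaN`, a warning counts them,
and they are excluded from percentile and spread computations and from
all downstream estimation.  Silent propagation would poison the rescaling
factor; dropping them silently would hide a data problem.

# Pooled permutation null P-values

Group labels are permuted B times (default B = 100, configurable); for
each permutation the statistic of every gene is recomputed — including
recomputing $\delta$ from the permuted denominators, so each permutation
is a self-contained replicate of the whole pipeline — and all $G \times
B$ values are pooled into a single null distribution.  Two-sided
P-values are

$$p_g = \frac{\#\{|\mathrm{null}| \ge |\mathrm{obs}_g|\} + 1}{GB + 1}.$$

Design choices here:

* **Two-sided by absolute value** — the benchmark has no directional
  hypothesis.
* **Add-one correction** in numerator and denominator guarantees
  $p_g > 0$, which the convex-NPMLE estimator requires; the distortion is
  $O(1/GB) \approx 10^{-6}$ at default sizes.
* **Ties count against significance** (the `≥`), standard conservative
  permutation practice.  Ties are detected with a relative tolerance of
  1e-9: in balanced designs the complementary label arrangement produces
  the exactly negated statistic, and exact mathematical ties must not be
  broken by floating-point noise between vectorized and scalar
  computation routes.
* **Permutation scheme**: B distinct non-identity arrangements of the
  labels, enumerated exhaustively when only B exist, otherwise sampled
  uniformly without replacement, reproducibly from a seed.  Requesting
  more arrangements than $\binom{n_1+n_2}{n_1} - 1$ is an error that
  states the maximum.

Under a complete null these P-values are approximately Uniform(0,1);
the acceptance suite checks a Kolmogorov–Smirnov statistic against the
1%-level critical value in 20 seeded replicates at G = 2000, B = 100.

# The three π₀ estimators

## Smoothing-spline mixture-model estimator (`estimate_pi0_storey`)

The plug-in $\hat\pi_0(\lambda) = \#\{p > \lambda\}/((1-\lambda)G)$ is
computed on the grid $\lambda = 0, 0.05, \dots, 0.90$ and smoothed with a
natural cubic smoothing spline with 3 degrees of freedom; $\hat\pi_0$ is
the spline value at $\lambda = 0.9$, clipped to $[0,1]$.  Grid and df are
the conventional defaults for this estimator class and are arguments.
The spline fit itself is `stats::smooth.spline`; the package adds only
the plug-in values and the evaluation point.

## Convex decreasing density NPMLE (`estimate_pi0_convest`)

The P-value density is modelled as a mixture of the uniform and the
triangular densities $f_\theta(p) = 2(\theta - p)/\theta^2$ on
$[0, \theta)$ — exactly the class of convex decreasing densities on
[0, 1].  Starting from the uniform, each iteration inserts the support
point $\theta^\*$ maximizing $\sum_i f_\theta(p_i)/\hat f(p_i)$ (the
Frank–Wolfe direction for the log-likelihood) and mixes it in with a step
size found by golden-section search (`stats::optimize`, tolerance 1e-6)
on $[0, 1)$; ties in $\theta^\*$ break toward the smaller $\theta$
(the steeper candidate).  Iteration stops after `max_iter` (default 100)
insertions or when the log-likelihood stops improving; the trace is
returned and is nondecreasing by construction.  $\hat\pi_0 = \hat f(1)$,
the residual uniform weight, since every triangle vanishes at 1.

**Support resolution.**  Candidate $\theta$ values sit on a 1% grid
(`theta_grid = seq(0.01, 1, 0.01)`).  This is a deliberate
regularization, not a shortcut: with arbitrarily fine support the exact
NPMLE absorbs part of the near-zero P-value spike into very steep
triangles whose tails leak into the interior, and the boundary value
$\hat f(1)$ — the quantity of interest — is systematically dragged down.
On a 10%-signal mixture with known $f(1)$ the gridded fit recovers the
truth while the exact NPMLE undershoots by 5–6 points.  The resolution
matches the reference implementations of this estimator class; the grid
is an argument for users who want the exact NPMLE.

## Empirical-null fit on statistics (`estimate_pi0_empirical_null`)

This is the permutation-free route.  It assumes the observed statistics
are a mixture of a scaled null — half-normal for declared z-statistics,
scaled t(df) for declared t-statistics — and a minority signal component
living mostly in the tails.  Since the per-gene Welch df varies but the
null model needs one value, df defaults to $n_1 + n_2 - 2$.

1. **Scale fit.**  $\hat\sigma$ maximizes the truncated likelihood of
   the absolute statistics below a censoring point $x_0$, i.e. of
   $f(s;\sigma)/F(x_0;\sigma)$.  The censoring point is a quantile of the
   absolute statistics, chosen adaptively from the grid
   10%, ..., 90%, 99%, searched **from the largest candidate downward**.
   The direction matters: a narrow central region carries almost no
   curvature information about $\sigma$ (the truncated likelihood is
   nearly flat and ML fits sampling noise), so the procedure starts wide
   and narrows only when the wide fit is contradicted.  A candidate fit
   is accepted when (a) the observed central fraction does not exceed
   $F(x_0;\hat\sigma)$ beyond a 95% binomial band — the null component
   of a mixture can only *lose* central mass to the alternative, so the
   reverse discrepancy signals a failed fit — and (b) the count below
   the fitted null's conditional median of the region sits inside its
   95% binomial band, a shape check that detects contamination by true
   signal (which piles up at the region's outer edge and skews the
   within-region distribution).  If no candidate passes, the fit refuses
   with diagnostics rather than returning a silently wrong scale.
2. **Null P-values.**  All statistics become two-sided P-values under
   the fitted null.
3. **Null proportion.**  The Grenander estimator (next section) is
   fitted to those P-values and $\hat\eta_0 = \min(1, \hat f(0.9))$ is
   returned as $\hat\pi_0$.  The evaluation point 0.9 reads the flat
   part of the density near 1 while avoiding the estimator's boundary
   degeneracy: the literal terminal step of a least-concave-majorant fit
   to continuous P-values is almost surely 0 (the last segment is flat),
   and the last *nonzero* step is an extreme order-statistic ratio whose
   median is far below the true density even for exactly uniform input
   — both verified numerically.  An interior tail point is the stable
   reading; it is exposed as the `tail_point` argument.

Fewer than 200 statistics are refused outright: empirical-null fitting
at that size is not meaningfully better than guessing, and a hard error
beats a quietly unstable estimate.

## Grenander density (`grenander_density`)

The nonparametric MLE of a nonincreasing density on [0, 1]: the left
derivative of the least concave majorant of the empirical CDF, computed
by a monotone-chain upper-hull pass over the ECDF knots (O(G log G) in
the sort, linear after).  The result integrates to 1 exactly because the
majorant ends at (1, 1).  The test suite verifies step-for-step
agreement (to 1e-10) with an independent pool-adjacent-violators oracle
on 200 random instances, including heavily tied inputs.

# The FDR estimate

`fdr_hat` implements the mixture identity with a strict inequality in
$\hat F_p(\alpha) = \#\{p < \alpha\}/G$ — genes *below* the threshold
are the declared list — and caps the estimate at 1.  `strict = FALSE`
switches to `≤`, which differs only for discrete pooled-null P-values
tied exactly at $\alpha$.  When nothing is below the threshold the
result is a flagged "no discoveries" record, not a division error.

# The simulation benchmark

## What the generator emulates

`synth_parameter_table` emulates the gene-level parameter source of a
real two-population study (EBV-transformed lymphoblastoid lines, 60 + 45
samples, ~47,000 transcripts) that is not redistributable: per gene a
pair of group means rounded to the nearest 0.1 — rounding makes "equal
means" an exact, unambiguous notion, so the DE indicator is
well-defined — and a pair of positive SDs.  Defaults: baseline means
$N(7, 1.5)$ on a log2-expression-like scale; SDs log-normal with
log-mean −0.7 and log-SD 0.6 (median SD ≈ 0.5, right-skewed, matching
the shape of per-gene SD distributions in log-scale expression data);
DE shifts drawn from $N(0, 0.5)$ and re-drawn until the rounded means
differ, giving a symmetric two-sided effect distribution with a minimum
visible effect of 0.1.  Exactly `round(pi1 * G)` genes are DE by
construction — enforcing the proportion exactly rather than in
expectation is the cleanest basis for parameter-recovery testing.  All
distributions are arguments, and a user with a real parameter table can
pass any data frame with the same columns to `simulate_dataset`.

Data are then independent normals per gene and sample; the variance
regimes differ only in which SD column feeds which group: EV uses the
group-A SD for both groups, UV1 each group's own, UV2 the swap.  The
scenario factorial crosses three sample sizes (60, 45), (16, 12), (8, 6)
— all 4:3 — with $\pi_1 \in \{0.01, 0.05, 0.10, 0.25\}$, the three
regimes, two rescaling factors and two input specifications (144 cells),
plus an EV-only extension at $\pi_1 \in \{0.005, 0.02, 0.03, 0.04\}$
(48 more, 192 total); the benchmark design runs 20 replicates per cell.
Replicate seeds derive deterministically from (master seed, scenario
index, replicate) so any single result row can be regenerated alone.

## What it does not emulate

Gene–gene correlation (all genes independent), non-normal noise,
platform artifacts, and any coupling between effect size and expression
level.  Passing tests therefore demonstrate correctness of the methods
under the stated sampling model, not robustness to correlated or
heavy-tailed real data.  Effect sizes are a parametric stand-in for the
empirical mean differences of the original data, calibrated only in the
sense that small-sample ROC behavior is non-degenerate (AUCs around
0.7–0.75 at (8, 6), well away from both 0.5 and 1).

## Evaluation

`roc_curve` ranks genes by $|$statistic$|$ with tie groups advancing as
one threshold step (deterministic and oracle-checkable), and reports the
trapezoidal AUC.  `run_study` executes scenario × replicate cells —
statistics, rescaling, all three estimators — recording estimator
failures as `NA`-with-reason rather than aborting a grid.
`summarize_bias` reports the median and IQR of $\hat\pi_1$ per cell, the
numerical twin of the boxplot presentation conventional for this kind of
comparison, with the bias sign labelled conservative
($\hat\pi_1 < \pi_1$) or anticonservative.

## Problem sizes in the shipped tests

The test and acceptance suites use the full design where it is cheap
(G = 10,000 for recovery, ROC and conservatism checks; 20 replicates)
and scaled-down sizes where a property does not need volume (G between
a few dozen and 2,000 for oracle, uniformity and contract checks;
replicate counts of 6 where a 20-replicate calibration is re-run at full
size in the acceptance suite anyway).  The whole suite runs in about a
minute on one core.

# Known limitations

* The empirical-null route inherits the fundamental non-identifiability
  of mixture scale fitting: with abundant weak signal the fitted
  $\hat\sigma$ absorbs part of the alternative and $\hat\pi_1$ is
  conservative — visibly so at $\pi_1 = 0.25$, which the acceptance
  suite asserts as the expected directional behavior rather than a
  defect.
* Pooled-null P-values at high $\pi_1$ are themselves contaminated (DE
  genes contribute to the permuted pool), adding a smaller conservative
  pull to the P-value-based estimators.
* `estimate_pi0_storey`'s spline extrapolation is noisy for G below a
  few hundred; the convex NPMLE is the better default there, and is the
  package default everywhere.
* No gene–gene correlation anywhere; see above.
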