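---
title: "Evaluating jingle and jangle fallacies with nomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating jingle and jangle fallacies with nomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nomnet)
```

## The problem

Psychological constructs are never observed directly, so two measures with
different names may in fact assess the same construct (a *jangle fallacy*),
and two measures sharing a name may assess different constructs (a *jingle
fallacy*). Both fallacies waste research resources and destabilise
findings. The quantitative core of an evaluation compares the *nomological
networks* of the two focal measures X and Y — their correlation profiles
across a battery of validation criteria — and asks (a) for which criteria
the two profiles differ, and (b) whether the overall profile agreement is
high enough, relative to a context-specific cutoff, to conclude redundancy.
`nomnet` implements that workflow end to end: per-criterion difference
tests, power analysis for planning, the double-entry intraclass correlation
(ICC~DE~) with bootstrap confidence intervals, threshold derivation, and
the decision rule, plus a synthetic-data generator used throughout the test
suite.

## Testing a difference between dependent correlations

When X and Y are correlated with the *same* criterion A in the *same*
sample, the two correlations $r_{XA}$ and $r_{YA}$ are dependent through
the focal intercorrelation $r_{XY}$, and a naive independent-samples
comparison is invalid. `diff_test_dep()` uses the modified Fisher-z
statistic with the pooled mean correlation
$\bar r = (r_{XA} + r_{YA})/2$:

$$Z = \left(z_{XA} - z_{YA}\right)\sqrt{\frac{n-3}{2 - 2\bar c}},
\qquad
\bar c = \frac{r_{XY}\,(1 - 2\bar r^2) - \tfrac12 \bar r^2
  \left(1 - 2\bar r^2 - r_{XY}^2\right)}{(1 - \bar r^2)^2},$$

where $z = \operatorname{artanh}(r)$. Several variants of this test
circulate (pooling on the raw versus the Fisher-transformed scale, t- vs
z-reference distributions); their p-values agree to two decimals in
ordinary ranges, and the package documents the pooled-$\bar r$ z-variant
as its choice. The test assumes bivariate-normal score pairs and
$|r| < 1$ for all three inputs; correlations of exactly $\pm 1$ are
rejected rather than clamped because the Fisher transform is unbounded
there. The implied $3 \times 3$ correlation matrix must be positive
semi-definite, checked via its smallest eigenvalue with a tolerance of
$-10^{-10}$ to absorb round-off on valid matrices.

```{r}
diff_test_dep(r_xa = .10, r_ya = .30, r_xy = .40, n = 100)
```

Two-sided testing is the default; directional alternatives are available
via `alternative = "greater"`/`"less"` because difference *hypotheses* are
usually directional even when reported p-values are two-sided.

## Planning: Monte Carlo power analysis

A study comparing correlation profiles must be powered for the *smallest
correlation difference it considers meaningful*, not for detecting a
single correlation of that size — the former needs considerably more
participants. `power_diff_dep()` estimates power by simulation: each
replicate draws an $n \times 3$ trivariate-normal sample with target
correlations $(\rho_{12}, \rho_{13}, \rho_{23})$, computes the three
sample correlations, and applies the two-sided test. With the default
`n_samples = 10000` the Monte-Carlo standard error of a power estimate
near .80 is about .004, small enough to resolve the conventional .80 bar.

```{r}
power_diff_dep(n = 250, rho12 = .10, rho13 = .30, rho23 = .40,
               alpha = .05, n_samples = 2000, seed = 42)
```

Two kinds of fidelity diagnostics accompany the estimate: `cov*` report
the share of Fisher-z confidence intervals (level $1-\alpha$) around the
simulated correlations that cover the target — close to the nominal level
when the simulation is faithful — and `bias_m*`/`bias_md*` report the
relative bias of the mean and median simulated correlation. Relative bias
is undefined for a zero target; in that case the absolute bias is
reported and flagged (`relative = FALSE`). Power estimates at a fixed
number of replicates carry Monte-Carlo noise of a few tenths of a
percentage point, so published single-run power figures should be read
with that tolerance in mind.

## Overall agreement: the double-entry intraclass correlation

Profile agreement must reflect *absolute* agreement, not rank-order
similarity: two profiles that differ by a constant offset can correlate
perfectly. The double-entry device appends each profile to the other,
`u = c(r_x, r_y)` and `v = c(r_y, r_x)`, and the ICC~DE~ is the Pearson
correlation of `u` and `v`. `icc_de()` computes the algebraically
identical closed form

$$\mathrm{ICC_{DE}} = \frac{2\sum_i (x_i - m)(y_i - m)}
  {\sum_i (x_i - m)^2 + \sum_i (y_i - m)^2},$$

with $m$ the grand mean of all $2t$ entries; the test suite verifies the
identity against a direct `cor()` on the doubled vectors to $10^{-12}$.
The coefficient is symmetric, bounded in $[-1, 1]$, equals 1 only for
identical profiles, and is exactly invariant to a common rescaling of
both profiles — a property that matters below. A profile pair whose $2t$
entries are all equal has no variance to correlate and raises a
degenerate-profile error.

`icc_de_boot()` attaches a percentile bootstrap confidence interval
computed from participant-level data, resampling *rows* so that the
dependence among the profile correlations is preserved. Defaults are
1,000 bootstrap samples and a 95% interval. Design choices, each of which
was genuinely open:

* **Percentile rather than BCa intervals** — the plain lower/upper
  percentile bounds match the simple LL/UL reporting this workflow needs,
  and no bias-correction detail is established for the ICC~DE~.
* **Point estimate = full-sample ICC~DE~** — the bootstrap-distribution
  mean is reported separately (`boot_mean`) because the two can differ
  and conflating them hides bootstrap bias.
* **Listwise deletion** with a logged count keeps every replicate's
  profiles on a common sample; pairwise-complete profiles would let each
  correlation rest on different participants.
* **Degenerate replicates** (a resampled column with zero variance) are
  redrawn, at most 100 times per replicate with a warning, because silent
  `NaN` propagation would corrupt the percentile bounds.

## Context-specific thresholds and the decision rule

A fixed cutoff for "networks agree" ignores how much difference was
actually expected and detected. The package derives the cutoff from the
data at hand: with $d$ detected correlation differences among $t$
criteria,

$$\mathrm{ICC_{DE,crit}} = 1 - d/t .$$

`count_differences()` produces $d$ in one of three modes. The standard
mode counts criteria whose `diff_test_dep()` is significant at `alpha`.
For constructs conceived as *opposites* (negative overlap), correlations
differing only in sign are functionally equivalent, so the test is
applied to $(r_X, -r_Y)$ with the focal intercorrelation flipped to
$-r_{XY}$ — the correlation of X with the reflected measure $-Y$ — which
keeps the implied correlation matrix coherent and the counting
inferential. A descriptive mode (compare $|r_X|$ and $|r_Y|$ rounded to a
configurable number of decimals) is available but not the default, since
mixing descriptive and inferential counting would make $d$ incoherent.
Differences are counted among *all* $t$ criteria, not only those where a
difference was hypothesised; the hypothesised/detected cross-tabulation
is printed so disagreements between theory and data stay visible. No
multiple-testing correction is applied by default (each per-criterion
test answers its own substantive question); Bonferroni and
Benjamini–Hochberg are available and logged when chosen. $d/t$ is formed
once from integers, so the reported fraction is exact.

`decide_fallacy()` applies the rule conservatively: evidence is
conclusive only when the *whole* bootstrap interval clears the cutoff,
i.e. `ll > icc_crit` — the only reading under which the interval's width
matters. Cutoffs at or beyond .20 and .95 (configurable) trigger an
extremity warning: a threshold that easy or that hard to exceed suggests
the criterion battery itself is uninformative. When the evidence is
inconclusive but the point estimate is numerically high (≥ .60), the
summary frames the measures as *sibling constructs* — closely related,
not twins.

```{r}
prof <- read.csv(system.file("extdata", "toy_profiles.csv",
                             package = "nomnet"))
count_differences(prof, n = 500, r_xy = .40)
```

## Measurement error and disattenuation

Observed correlations are attenuated by unreliability;
`disattenuate()` applies $r_c = r / \sqrt{\rho_1 \rho_2}$ and errors when
the corrected value leaves $[-1, 1]$. Does working with raw rather than
disattenuated profiles distort the ICC~DE~?
`attenuation_simulation()` answers by simulation: per replicate, two
length-20 profiles are drawn i.i.d. uniform on $[-.60, .60]$,
reliabilities for the 2 focal measures and 20 criteria i.i.d. uniform on
$[.70, 1.00]$, each entry is disattenuated by the square root of the
product of its two pertinent reliabilities, and both ICC~DE~s are
computed. Sampling assumptions, chosen once and documented:

* raw correlations i.i.d. **uniform** over the range — the
  minimal-assumption reading of "ranging from −.60 to .60";
* **one reliability per variable** (2 + t values per replicate), applied
  multiplicatively per correlation — the psychometrically coherent
  structure, since reliability is a property of a measure, not of a
  correlation;
* the two profiles in a pair drawn **independently** — nothing couples
  them a priori, and the headline quantity concerns the ICC~DE~ series,
  not individual pairs.

Because the ICC~DE~ is exactly invariant to a common rescaling,
disattenuation can only move it through *heterogeneous* scaling — the
criterion-to-criterion spread of reliabilities within a profile and the
focal-measure asymmetry between profiles. Under the assumptions above the
two series correlate at ≈ .995 and 95% of differences fall within about
±.04; the interval width is driven almost entirely by the per-criterion
reliability heterogeneity, and schemes that assign a single reliability
level to a whole profile produce markedly narrower intervals. The
conclusion is robust either way: raw-score ICC~DE~s track disattenuated
ones closely, so the (much simpler) raw analysis loses little.

```{r}
attenuation_simulation(n_pairs = 2000, seed = 42)
```

## Synthetic data

`generate_scores()` draws multivariate standard-normal true scores with a
target population correlation matrix (Cholesky factorisation, falling
back to an eigendecomposition with negative eigenvalues clipped at zero —
with a warning — for exactly singular matrices) and, when reliabilities
are supplied, adds congeneric measurement error so that observed
correlations equal the attenuated population values in expectation. It
emulates what the rest of the package assumes: continuous, normal,
linearly related scores. It does **not** emulate Likert discreteness,
skew, method factors, or structured missingness — so a passing test suite
shows the *statistical machinery* is correct under its own model, not
that real questionnaire data meet that model. Population ground truths
for round-trip tests come from `population_icc_de()`.

## Problem sizes and numerical choices

The test suite checks the worked p-value examples deterministically; the
power claims with 10,000 replicates per configuration; type-I calibration
of the test with 10,000 null replicates (3·SE band); bootstrap coverage
with 200 simulated studies of 300 participants and 400 bootstrap
replicates each (3·SE band); monotonicity of power on a coarse n-grid
with 2,000 replicates (2·SE band); and the attenuation simulation with
10,000 pairs. These sizes keep each check's Monte-Carlo error well below
the tolerance it asserts. All simulations take explicit seeds and are
bit-reproducible; functions restore the caller's RNG state.

## Known limitations

The dependent-correlations test assumes bivariate normality; heavy tails
or severe nonlinearity distort its calibration. The ICC~DE~ treats the
criterion battery as given — it cannot detect that the battery itself is
unrepresentative (the extremity warning is a partial guard). The
threshold formula is deliberately simple and inherits the subjectivity of
the content coding that selects criteria and expected differences;
`expected_difference` flags are inputs, never inferred. Power analysis
covers the difference test only, not the ICC~DE~ itself.
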