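# nomnet

Statistical evaluation of **jingle and jangle fallacies**. A *jangle
fallacy* is treating two measures as distinct merely because they carry
different names although they assess the same construct; a *jingle fallacy*
is treating two measures as identical merely because they share a name.
`nomnet` is for psychometricians and construct-validation researchers who
want to settle such questions with explicit, reproducible numbers instead
of fixed rules of thumb.

## What it computes

Let X and Y be the two focal measures, correlated at r_XY, each correlated
with the same battery of t validation criteria (their *nomological
networks*, the profiles r_X· and r_Y·).

* **Dependent-correlations difference test** (`diff_test_dep`): for a
  shared criterion A, tests H0: ρ_XA = ρ_YA with the modified Fisher-z
  statistic using the pooled mean correlation r̄ = (r_XA + r_YA)/2,

      Z = (z_XA − z_YA) · sqrt( (n − 3) / (2 − 2c̄) ),
      c̄ = [ r_XY(1 − 2r̄²) − ½ r̄²(1 − 2r̄² − r_XY²) ] / (1 − r̄²)²

* **Monte Carlo power analysis** (`power_diff_dep`): power of that test at
  a planned n, with coverage and bias diagnostics of the simulation.
* **Double-entry intraclass correlation** (`icc_de`, `icc_de_boot`):
  profile agreement as the Pearson correlation of the doubly entered
  vectors u = (r_X·, r_Y·), v = (r_Y·, r_X·), with percentile bootstrap
  confidence intervals from participant-level data (default: 1,000
  resamples, 95%).
* **Context-specific threshold and decision** (`count_differences`,
  `icc_de_crit`, `decide_fallacy`): the redundancy cutoff
  ICC_DE,crit = 1 − d/t from the count d of detected correlation
  differences among t criteria, and the rule that calls a strong fallacy
  only when the whole bootstrap interval clears the cutoff.
* **Attenuation utilities** (`disattenuate`, `attenuation_simulation`):
  classical correction r/√(ρ₁ρ₂) and a simulation showing how little the
  ICC_DE moves when profiles are disattenuated.
* **Synthetic data** (`generate_scores`): participant tables from a known
  population correlation matrix with an optional congeneric error model.

A command-line interface (`exec/nomnet`, installed with the package) wraps
the same functions: subcommands `power`, `iccde`, `evaluate`,
`simulate-attenuation`, `generate`, each writing a JSON report that embeds
its full resolved configuration and seed.

## Worked example

Two measures X and Y correlate at about .70 and share six validation
criteria. Is "Y" just "X" under another name?

```r
library(nomnet)

# participant scores: here simulated from a near-redundant population
k <- 6
nm <- c("X", "Y", paste0("C", 1:k))
R <- diag(2 + k); dimnames(R) <- list(nm, nm)
R["X", "Y"] <- R["Y", "X"] <- .70
rx <- c(.45, .35, .30, .20, .10, -.25)   # population profile of X
ry <- c(.40, .38, .28, .22, .12, -.22)   # population profile of Y
for (i in 1:k) { R["X", nm[2+i]] <- R[nm[2+i], "X"] <- rx[i]
                 R["Y", nm[2+i]] <- R[nm[2+i], "Y"] <- ry[i] }
d <- generate_scores(800, R, seed = 2024)

prof <- profiles_from_data(d, "X", "Y")
thr  <- count_differences(prof, n = attr(prof, "n"), r_xy = attr(prof, "r_xy"))
icc  <- icc_de_boot(d, "X", "Y", seed = 99)
decide_fallacy(icc, thr, direction = "jangle_test")
```

```
Context-specific redundancy threshold
  mode = standard, alpha = 0.05, correction = none
  detected differences d = 1 of t = 6 criteria
  ICC_DE,crit = 1 - 1/6 = 0.833
Double-entry intraclass correlation (bootstrap)
  focal: X vs Y; criteria: C1, C2, C3, C4, C5, C6
  n = 800 participants, 1000 bootstrap samples, 95% CI, seed = 99
  ICC_DE = 0.976  (bootstrap mean 0.968)
  LL = 0.934, UL = 0.989
Jingle/jangle evaluation (jangle_test)
  ICC_DE = 0.976, 95% CI [0.934, 0.989]; threshold = 0.833 (d = 1, t = 6)
  decision: strong jangle fallacy indicated
```

Reading: only 1 of the 6 per-criterion difference tests was significant,
so the cutoff is 1 − 1/6 ≈ .833. The observed profile agreement (ICC_DE =
.976) has a 95% bootstrap interval whose lower bound (.934) clears that
cutoff, so the networks overlap more strongly than the detected
differences allow — evidence that the differently named measures assess
the same construct. Had the interval straddled the cutoff, the high point
estimate would instead have been framed as *sibling constructs*.

Planning the next study instead:

```r
power_diff_dep(n = 950, rho12 = .10, rho13 = .20, rho23 = .40, seed = 1)
#> power = 0.817 ...   # a .10 correlation difference needs ~950 participants
```

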