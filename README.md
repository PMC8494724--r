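# visref — reference intervals for clinical visual electrophysiology

`visref` establishes, transfers, verifies and monitors reference intervals
for quantitative clinical physiological measurements — ERG, VEP and EOG
parameters such as amplitudes (µV) and peak times (ms) — for clinical
scientists and physicists who maintain normative data for these tests.  It
implements the full reference-interval workflow with explicit support for
the two features that make visual electrophysiology awkward for standard
laboratory-medicine recipes: correlated bilateral (two-eye) measurements and
one-tailed reference limits.

## What it computes

* **Nonparametric limits** (gold standard): the p-quantile at rank
  `0.5 + p·n`, with the exact 90% CI of each limit from order statistics —
  ranks `(l, u)` such that `P(l ≤ K ≤ u−1) ≥ 0.90`, `K ~ Bin(n, p)`.  At
  n = 120 the 2.5th-percentile CI spans ranks (1, 7); the package also
  computes the smallest n at which an exact equal-tailed CI exists (119,
  conventionally rounded to the 120-subject recommendation).
* **Parametric limits** `x̄ ± 1.96 s` after a normalising transform (log,
  √, Box–Cox), gated by an Anderson–Darling normality test; each limit's CI
  both by the analytic approximation `±2.81 s/√n` and by the exact
  non-central-t tolerance interval, whose endpoint error the approximation
  tracks to O(1/n).
* **Subject-level bootstrap limits** for n ≥ 40, resampling subjects (never
  eyes) so correlated or duplicated fellow-eye values do not shrink the CI.
* **Bilateral strategies**: one eye per subject, all eyes, or duplication of
  singletons so every subject contributes a pair — plus a Monte-Carlo
  engine comparing their CI/RI performance across inter-eye correlations.
* **Curation**: Tukey fences (remove only beyond `Q3 + 3·IQR`), Grubbs and
  Dixon tests, Tukey-biweight robust location with IQR-based scale,
  robust continuous age compensation, and partitioning rules (25%/15%
  mean-gap, per-tail 4%, SD-ratio ≥ 1.5).
* **Transference** of an interval to a new method via Deming regression
  with the r² ≥ 0.7 and n ≥ 40 gates; **verification** of an external
  interval by the exact two-stage 20-subject outside-count rule, or by
  Mann–Whitney / Siegel–Tukey / Kolmogorov–Smirnov when the full primary
  dataset is available.
* **Serial change**: repeatability coefficient `RC = z√2 × SD` (or CV),
  df-weighted pooling of replicate dispersions over subject–eye units, delta
  checks, and bootstrap RC uncertainty.
* **Classification** against estimated limits with an indeterminate zone
  (inside a limit's 90% CI) and the familywise risk `1 − 0.95ⁿ` of
  reporting n parameters.

## Worked example

Simulate a 150-subject bilateral cohort (75% of subjects contribute both
eyes, inter-eye correlation 0.7, gamma-distributed amplitudes), establish
two-tailed limits, and run a delta check:

```r
library(visref)

spec <- bilateral_cohort_spec(150, r = 0.7, fraction_bilateral = 0.75,
                              distribution = distribution_spec("gamma"),
                              seed = 20)
sample <- generate_bilateral_cohort(spec)
sample
#> Reference sample: sim
#>   262 measurements from 150 subjects
#>   reporting tier: full (n = 150)

establish_limits(sample, method = "nonparametric")
#> Reference limits (nonparametric, two_tailed, 95% interval)
#>   lower: 154.57  [90% CI 138.985, 172.132]  CI/RI = 0.100
#>   upper: 486.539  [90% CI 457.963, 487.5]  CI/RI = 0.089
#>   n = 300 values from 150 subjects; quality (all CI/RI < 0.2): pass
```

The 262 measured eyes become 300 analysis values because the default
bilateral strategy duplicates the single available eye of the 38 one-eyed
subjects, so every subject contributes a pair.  Both limits' 90% CIs are
narrower than 0.2 of the reference interval, so the estimate passes the
reliability criterion.  For serial monitoring:

```r
delta_check(310, 200, rc)   # rc: CV-basis repeatability estimate, RC = 15.7%
#> Delta check: 310 -> 200 (change -35.48% vs RC 15.72%): changed_down

familywise_risk(5)
#> [1] 0.2262191
```

A 35% amplitude drop exceeds the repeatability coefficient, so it is a real
change; and reporting five independent parameters already carries a 23%
chance of at least one false abnormal call.

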