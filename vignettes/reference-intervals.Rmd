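---
title: "Reference intervals for clinical visual electrophysiology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference intervals for clinical visual electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visref)
```

## The problem

Clinical visual electrophysiology tests — the electroretinogram (ERG),
visual evoked potential (VEP) and electrooculogram (EOG) — produce
quantitative parameters (amplitudes in µV, peak times in ms) that are judged
against *reference intervals*: the central 95% span of values observed in
disease-free subjects.  Each reference limit (e.g. the 2.5th percentile) is
itself estimated from a finite sample and therefore carries a 90% confidence
interval; a limit is considered adequately reliable when the width of that
CI is below 0.2 of the whole reference interval (the CI/RI ratio).

Two features distinguish these data from ordinary laboratory analytes and
drive most of the package's design: measurements come in correlated pairs
(two eyes per subject, sometimes only one), and many parameters are
one-tailed — only a too-small amplitude or a too-late peak is pathological.

## Data model

Everything is long format: one row per measured value with
`subject_id`, `side` (R/L/NA), `parameter`, `value`, plus optional `units`,
`age`, `sex`, `session_id`, `replicate_index`.  A `reference_sample` holds
the rows of one parameter within one partition.  The single schema serves
limit estimation, verification and replicate-based repeatability alike, and
round-trips exactly through `read_reference_table()` /
`write_reference_table()`.

Reporting policy is a pure function of the subject count
(`reporting_tier()`): below 10 subjects nothing is reported; 10–19 support a
ranked table with the median only; 20–39 robust or parametric limits with
illustrative CIs; 40–119 add subject-level bootstrap limits; from 120 the
gold-standard nonparametric limits with exact order-statistic CIs apply.

## Nonparametric limits

Quantiles use the rank convention `index = 0.5 + p·n`.  Two resolutions of a
fractional rank are provided, and the choice is a genuine convention rather
than mathematics:

* `"interpolate"` (default): linear interpolation between adjacent order
  statistics — identical to `stats::quantile(type = 5)`, continuous in `p`,
  and the convention under which duplicating every value leaves limits
  unchanged whenever the rank lands on a half-integer;
* `"round"`: the order statistic at the half-up-rounded rank.  This is the
  convention under which the 10th percentile of the digits 0–9 is 1 no
  matter how many copies of the digit set are pooled, which matters when
  reasoning about perfectly correlated duplicated eyes.

Ranks outside `[1, n]` clamp to the extremes: at the bare minimum of
`min_n_for_separation(2.5) = 39` points the extreme values *are* the
estimated limits.

The exact CI of a quantile uses the binomial law: the order-statistic
interval `[x(l), x(u)]` covers the p-quantile with probability
`P(l ≤ K ≤ u−1)`, `K ~ Bin(n, p)`.  `order_statistic_ci()` returns the
smallest-width pair reaching 90%, ties broken by symmetry about the rank
index.  Two notions of "smallest n with an exact CI" coexist and
`min_n_exact_ci()` computes both: pure coverage is attainable from n = 91
(for p = 0.025), while the classical recommendation of ~120 subjects
corresponds to the equal-tailed convention — each tail risk ≤ 5%, which
first holds at n = 119 (`0.975^119 ≤ 0.05`); 120 is the conventional round
figure.  At n = 120 both conventions give ranks (1, 7).

## Parametric limits

If the values (possibly after a log, square-root or Box–Cox transform) pass
a normality test, the 95% limits are `mean ± 1.96 s` on the working scale,
back-transformed.  Anderson–Darling is the default gate at α = 0.05, with a
Lilliefors-corrected Kolmogorov–Smirnov option (parameters are estimated, so
the plain KS null is wrong).  The Box–Cox exponent is fitted by profile
likelihood and rounded to {−1, −½, 0, ½, 1}: small samples do not support
finer power resolution, and the rounded family keeps the transform
interpretable.

Each limit's 90% CI is computed two ways:

* the analytic z-approximation, half-width
  `z₀.₉₅ √(1 + z₀.₉₇₅²/2) · s/√n ≈ 2.81 s/√n`;
* the exact non-central-t (tolerance-limit) interval: the one-sided factor
  at confidence γ is `qt(γ, df = n−1, ncp = z√n)/√n`.

The exact interval is authoritative for reported CIs and the quality flag.
`eq2_error_curve()` measures the approximation error as the relative error
of the CI *endpoint factor* (`z ± 2.81/√n` against the exact factor); under
this definition the error falls as 1/n (measured log–log slope ≈ −1.0),
whereas the relative error of the half-width itself decays only as 1/√n.
By Gaussian symmetry the lower limit's two endpoint errors mirror the upper
limit's exactly.

Forcing a Gaussian fit onto skewed data is refused by default: even when
`mean ± 1.96 s` encloses 95% of the distribution it is not the *central*
95%, so low amplitudes are systematically misclassified as normal and high
ones as supranormal.  `allow_nonnormal = TRUE` computes the limits anyway
for diagnostic demonstrations, with the failed verdict recorded.

## Correlated bilateral data

Three strategies resolve two-eye correlation before estimation
(`apply_eye_strategy()`): one eye per subject (right preferred, or a seeded
random side); all eyes as independent values; or duplicating the single
value of one-eyed subjects so every subject contributes a pair.  Averaging
fellow eyes is deliberately absent — it shrinks recording variability that
will be present in patient testing.

CI estimation must respect the subject level: `bootstrap_limits()` resamples
subjects, never eyes, which removes the artificially narrow CIs that
eye-level resampling produces when eyes are nearly duplicated, while leaving
low-correlation cases unaffected.

`strategy_ci_experiment()` reproduces the strategy-comparison study on
simulated correlated Gaussian cohorts.  The limit's "90% CI" in each cell
is, by default, the 5th–95th percentile span of the estimated limit across
the Monte-Carlo replications — the true sampling uncertainty of the
estimator.  The per-replicate order-statistic CI is available as
`ci_method = "order_statistic"` but is *not* the default, for two reasons
found during implementation: it treats duplicated eyes as independent
observations, recreating exactly the overly-narrow-CI artifact described
above (and so fails the expected equality of strategies at r = 1), and at 60
one-eye values no interior rank pair attains 90% coverage at all.  Under
the sampling definition the three qualitative results hold: duplication is
never worse than one eye; at r = 1 all strategies coincide; at r = 0 using
both eyes equals doubling the subjects.

One-tailed limits (the 5th or 95th percentile) always express their CI/RI
ratio against the two-tailed 2.5th–97.5th interval width: one-tailed
interval widths depend on the most extreme observation and do not converge
with n.

## Curation

The enforced order is: transform / age-adjust first, then outlier
detection, then estimation.  With a real age trend, outlier screening before
adjustment preferentially flags the oldest and youngest subjects; the
package's `age_adjust()` warns if outlier removal is already in the curation
log.

Tukey's fences are the default outlier method because they assume no
distributional shape: values beyond `Q3 + k·IQR` / `Q1 − k·IQR` are flagged
at k = 1.5 (inner) and k = 3 (far).  Only far-fence violators are removed by
default — the emphasis is on retaining data.  In closed form the far fence
rejects ≈ 2.3 per million from a Gaussian, but orders of magnitude more from
skewed distributions, which is why fences are applied after any normalising
transform or age adjustment.  Grubbs (iterative) and Dixon's Q (single
extreme, n ≤ 30, α = 0.05 table) are provided for near-Gaussian data and
warn when normality looks doubtful.  Robust estimation uses the one-sample
Tukey biweight (tuning constant 6 MADs, ≤ 50 iterations, tolerance 1e−8,
median fallback) and IQR/1.349 as the Gaussian-consistent scale.

Age compensation fits `value ~ age` or `value ~ log(age)` by Tukey-bisquare
M-estimation (`MASS::rlm`) so the fit itself resists outliers; residual
spread above and below the trend can be fitted separately so the interval
width may change with age.  Modelling refuses when the observed age span is
under 5 years (configurable) — a slope from a 2-year window is noise.

Partitioning (e.g. by sex) evaluates: the 25% mean-gap rule (gap > 25% of
the combined 95% RI; the stricter 15% variant is reported but not
decisive), the SD-ratio ≥ 1.5 rule, and the 4% rule.  The 4% rule is
implemented per tail — a subgroup fires it if more than 4% of its points lie
beyond one combined limit, against the 2.5% each tail should hold.  The
naive total-fraction reading fires for identical subgroups (about 5% of any
subgroup is outside its own 95% limits by construction), so it cannot be
what the rule intends.  Combined limits are computed nonparametrically on
the pooled data.

## Transference and verification

Transference (`transference_assess()`) maps an established interval to a new
method from ≥ 40 paired measurements.  Deming regression is the default —
both methods carry measurement error, so OLS attenuates the slope; OLS
remains available for compatibility.  Gates: below 40 pairs or r² < 0.7 the
interval cannot be transferred; with high correlation the limits are reused
unchanged when |slope − 1| ≤ 0.05 and |intercept| ≤ 5% of the old RI width
(both configurable — the literature says "clinically significant" without
numbers), otherwise mapped through `new = slope·old + intercept`.

Verification (`verify_reference_interval()`) is the count-exact two-stage
rule on 20 local reference subjects: ≤ 2 outside accepts; 3–4 trigger a
second 20-subject stage (≤ 2 outside accepts); 5+ at stage 1, or a failed
stage 2, send the user back to protocol review.  No third stage exists: the
two enumerated branches are exhaustive by design.  Under the null the
stage-1 acceptance probability is exactly `P(X ≤ 2)`, `X ~ Bin(20, 0.05)` ≈
0.924, which the test suite confirms by simulation against an independent
binomial oracle.  When the full primary dataset is available,
`verify_full_dataset()` applies Mann–Whitney U (location), Siegel–Tukey
(dispersion; alternating-extreme ranks, warning on heavy ties) and
Kolmogorov–Smirnov (shape) instead — more sensitive and specific than the
count rule.

## Serial measurements

The repeatability coefficient is `RC = z√2 × dispersion` (2.77 × SD or CV at
z = 1.96).  Replicate dispersions are pooled with degrees-of-freedom
weights: `√(Σ(kᵢ−1)sᵢ² / Σ(kᵢ−1))`.  Units are subject–eye composites,
never eye-averaged: combining fellow eyes into one set inflates the SD
whenever their expected values differ (unilateral disease), which the test
suite demonstrates by simulation.  Conventions fixed here and overridable:
SD basis for times (ms), CV basis for amplitudes (percent), selected from
parameter metadata; the CV denominator of a delta check is the *previous*
value; a change must strictly exceed the RC — equality is no change.  RC
uncertainty is a percentile bootstrap over subjects (eye-units travel
together); eight subjects is the working minimum, smaller cohorts are
flagged rather than refused.

## Classification and multiplicity

`classify()` partitions the line into normal / abnormal-low / abnormal-high,
with values inside a limit's 90% CI band flagged indeterminate; one-tailed
estimates never emit the unmonitored tail's verdict and annotate normal
results accordingly.  `familywise_risk(n) = 1 − 0.95ⁿ` reports the
false-positive risk of reporting n independent parameters; it is reported,
not corrected for, because a principled correction needs the inter-parameter
correlations, which are rarely known — the practical advice is to limit
testing to clinically indicated, discriminating parameters.

## The simulation engine and what the tests show

`generate_bilateral_cohort()` draws correlated pairs through a Gaussian
copula (for Gaussian marginals this is exact correlated sampling; for gamma
or log-normal marginals `r` is the copula correlation and results are
labelled extensions, since only Gaussian cohorts back the published
comparisons).  Singleton subjects alternate sides.  Generators are pure
functions of their spec and seed.

Default study conditions, fixed once: the skewed amplitude distribution is
gamma(shape 12, scale 25) — mean 300 µV, CV 29%, right-skewed — matching the
coefficient of variation typical of ERG b-wave amplitude reference data.
Strategy experiments in the test suite run 10 000 replications per cell at
n ∈ {60, 120} subjects, r ∈ {0, 0.5, 0.9, 1}, with Monte-Carlo standard
errors per cell and 2-SE tolerances on every ordering; the verification
null uses 100 000 trials; quantile-recovery checks use n = 10 000 samples.
The full-scale 10⁶-replication grids remain available through the `reps`
argument.

What passing tests do *not* show about real data: simulated cohorts have
exactly exchangeable subjects, exact marginals and a single correlation
parameter; real reference data add session effects, operator and electrode
variability, age structure and imperfect inclusion screening.  The
simulations validate the estimators' statistical behaviour, not any claim
about a particular instrument or population.

## Numerical choices and degenerate inputs

Zero IQR disables fences with a warning; degenerate reference intervals
make the CI/RI ratio 0 (zero-width CI) or undefined (NaN) rather than
silently passing; bootstrap CIs warn below 100 resamples and below 40
subjects; `qt(..., ncp)` warnings about final-digit precision are
suppressed (the affected digits are far below every tolerance used).  All
randomised routines take an explicit seed, record it in their output, and
restore the caller's RNG state.

## Limitations

Indirect sampling from patient databases, multidimensional reference
regions, GEE-based CIs and clinical decision limits are out of scope.  Age
models are linear / log-linear only — full centile modelling (GAMLSS-style)
for paediatric data needs designs of ~500 subjects and different machinery.
Dixon's Q is tabulated for α = 0.05 and n ≤ 30 only.  The CLI covers the
package's main flows but is a thin wrapper; the functions are the interface.
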