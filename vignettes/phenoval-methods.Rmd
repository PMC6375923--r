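---
title: "Methods: extraction optimization and HPLC method validation with phenoval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction optimization and HPLC method validation with phenoval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoval)
```

`phenoval` implements a complete computational workflow for optimizing
ultrasound-assisted extraction of leaf polyphenols and for validating and
applying an external-standard HPLC-DAD quantification method. This
vignette records the statistical models behind each stage, the tunable
parameters and their defaults, the numerical conventions, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where more than one reasonable convention exists.

## Screening: factorial effects and Dong's critical effect

The screening stage assumes an unreplicated regular two-level design. The
default geometry is the 7-factor, 16-run quarter-replicate
(a 2^(7−3) design) with duplicate center points, matching a screening
study of methanol fraction, extraction time, number of methanol
extractions, temperature, mass/solvent ratio, number of acetone
extractions and particle size. The generating relations are not uniquely
determined by such a study's published effect table, so the package
defaults to E = ABC, F = BCD, G = ACD — a resolution-IV choice under which
no main effect is aliased with another main effect and the seven
two-factor-interaction alias representatives A:B, A:C, A:D, A:E, A:F, A:G
and B:D are estimable alongside the seven main effects, exactly the 14
contrasts such a screening table reports. The generators are configurable
for laboratories that used a different fraction.

An effect is the difference of mean responses at the high and low coded
levels of its contrast; center replicates carry no contrast information
and are excluded. With no replication the error is estimated from the
effects themselves. Dong's approach treats the small effects as
pseudo-noise: the effect standard error `(SE)_e` is the root mean square
of a retained subset, and the significance threshold is

```
E_critical = t(1 - alpha, dof) * (SE)_e .
```

Two retention rules are implemented because published screening tables are
not always consistent with a single one:

* `lowest75` (default): retain the `floor(0.75 m)` smallest absolute
  effects of the `m` estimated effects.
* `dong_classic`: start from `s0 = 1.5 * median|E|`, retain effects with
  `|E| <= 2.5 * s0`.

Two conventions deserve emphasis. First, the t quantile is **one-sided**
at level `1 − alpha` with `dof = m` (the total number of effects, 14 in
the default geometry). This is the convention that reproduces published
critical effects of this family to two decimals; plausible alternatives
(two-sided quantile, dof equal to the retained count) give visibly
different thresholds. Second, the one-sided choice makes the rule mildly
anti-conservative as a pure significance test: on pure-noise effects the
per-effect flag rate sits near `2·alpha` rather than `alpha` (the
test-suite demonstrates both this and the fact that halving `alpha`
restores nominal control). We regard `E_critical` as what it is in
practice — a screening threshold for ranking candidate factors ahead of an
optimization stage, not a confirmatory test — and keep the
published-table-compatible convention as the default. Both `alpha` and
`dof` are arguments.

## Response-surface optimization

The optimization stage assumes a two-factor rotatable central composite
design: a 2² factorial at ±1, four axial points at ±α with α = 1.414
(= √2, giving rotatability for k = 2), and center replicates (default 3).
The full quadratic model

```
y = b0 + Σ bi Xi + Σ bii Xi² + Σ bij Xi Xj
```

is fit by ordinary least squares in coded units, with per-coefficient
standard errors and two-sided t-tests against zero. Lack-of-fit ANOVA is
deliberately omitted: the workflow this package mirrors reports
coefficient t-tests only, and with 11 runs and 6 parameters the pure-error
split adds little. All model arithmetic is done in coded units; the
coded↔natural affine map (`coded = (natural − center)/half-range`) is
carried by `factor_spec` objects and applied only at the reporting edge,
so optimization results do not depend on the laboratory's particular
center choice. Defaults for the worked examples place the center at 70%
methanol and 60 °C.

Maximization uses a grid of coded step ≤ 0.01 over the search region,
followed by local refinement (box-constrained quasi-Newton ascent on a
square region; a 20-fold finer local grid clipped to the disk when the
region is circular, because a box optimizer cannot respect the circular
constraint). The default region is the square [−1.414, 1.414]²; the
circumscribed-disk option restricts to the region actually spanned by a
rotatable design. Ties among near-maximal grid points break toward the
lower second coordinate (temperature) and then the lower first (methanol),
preferring gentler conditions at equal predicted yield. Multi-response
optimization scalarizes by a Derringer-type desirability: each response is
linearly rescaled to [0, 1] using its own min/max over the region grid
(making the optimum invariant to positive affine rescaling of any single
response) and the geometric mean is maximized. Degenerate inputs —
all-constant surfaces — return the origin with a warning.

Verification of a predicted optimum uses Welch's two-sample t-test
assembled from summary statistics (mean, sd, n per side; the predicted
side defaults to n = 3), since verification experiments are typically
summarized, not raw. The percent difference is `|pred − exp|/pred × 100`;
published tables of this kind sometimes print a "% difference (CV)"
column computed by an unstated formula, which we do not attempt to
reproduce. Note that the prediction's standard deviation is a model
quantity; treating it as if it came from three independent runs is a
pragmatic convention, and the resulting p-values should be read as
agreement indicators rather than strict error rates.

## Validation statistics

**Linearity.** Calibration curves (≥ 5 levels recommended; a warning below
that) are fit by OLS. We report r², 95% confidence intervals and t-tests
(N − 2 dof) for slope and intercept — a method passes when the slope is
significantly nonzero and the intercept CI includes zero, which also
licenses single-point external-standard quantification — plus per-level
replicate %RSD screened at 5%. Mandel's fitting test compares first- and
second-order fits through

```
DS² = (N−2)·s_lin² − (N−3)·s_quad²,   F = DS²/s_quad²  vs  F(1−alpha; 1, N−3)
```

at α = 0.01 by default. A numerically perfect linear fit is declared
linear with F = 0 by convention; a perfect quadratic fit with remaining
first-order misfit is declared quadratic with an infinite-F flag.

**Precision.** Determinations are grouped into day × level cells (six
replicates per cell in the default geometry, four days, three levels).
Repeatability is the pooled within-cell %RSD on the grand mean.
Intermediate precision treats the day-level cells as a single random
grouping factor in a one-way variance decomposition,
`s_R² = s_r² + max(0, (MS_between − MS_within)/n)`; the one-way pooling
(rather than a two-way day × level model) matches the common practice of
reporting one intermediate-precision figure across days *and* levels.
RSD_R ≥ RSD_r holds by construction. Cochran's C (`max s²/Σ s²`) checks
variance homogeneity across the cells before pooling; its critical value
uses the exact closed form `[1 + (k−1)/F(1−α/k; ν, (k−1)ν)]⁻¹`, ν = n−1,
verified against Monte Carlo in the test-suite. All-zero variances are
homogeneous by convention.

**Horwitz limits.** Acceptability ceilings depend only on the analyte
mass fraction C (dimensionless, m/m): `RSD_R = 2^(1 − 0.5·log10 C)` and
`RSD_r = (2/3)·RSD_R`. The logarithm is base 10, as required for the
equation's standard form. Because the C values behind published limit
columns are often unprinted, the helper `rsd_r_from_rsd_R()` recovers the
repeatability limit from an intermediate-precision limit directly.

**Accuracy.** Recovery at spike levels 75/100/125% in triplicate. The
mean is the unweighted mean of level means when only level means are
available (this reproduces published level-mean tables exactly), or of
all raw replicates when provided — the %RSD of a recovery table is only
meaningful on raw replicates. Three flags: 95% CI contains 100%, mean in
[98, 102]%, %RSD at or below a repeatability reference.

**LoD/LoQ.** Calibration route: 3.3σ/slope and 10σ/slope with σ the
standard deviation of the intercept (the ICH multipliers; published
limit tables whose LoQ/LoD ratio differs from 10/3.3 evidently used
another convention and are treated as data, not as targets). Empirical
route: the lowest dilution-series concentration with S/N above threshold
(default 3, within the conventional 2–3.5 band) for LoD, and with
replicate %RSD ≤ 5 for LoQ.

## Quantification and censoring

Single-point external-standard quantification converts a peak area to
µg/mL via `conc = area/area_std × conc_std`, with chlorogenic acid
(20.12 µg/mL), vitexin (20.32 µg/mL, read at 340 nm for flavone
C-glycosides and at 390 nm for flavonolignans) and rutin (18.69 µg/mL,
for quercetin O-glycosides) as the reference standards; curve mode inverts
a fitted calibration instead. Mass fractions follow from
`conc × volume × dilution / mass` (the reference workflow: 50 mL flask,
1:2 dilution). Values below LoQ are censored and contribute **zero** to
class totals and category sums — the convention that makes published
totals equal the sum of their quantified member rows; an LOQ/2 imputation
is available but non-default, and a class whose members are all censored
reports a censored total rather than zero. The packaged 19-sample
composition table carries known quirks of its source faithfully: one
flavonolignan total is a misprint of its neighbour (the package recomputes
totals from members), one replicate SD is unrecoverable and stored as NA,
and two samples' totals differ from their member sums by ~0.2 µg/g from
member rounding, so exact-equality checks are confined to the three
internally consistent cells.

The reference peak areas shipped by `default_standards()` are synthetic:
they equal concentration × calibration slope and exist to give the
simulators and round-trip tests a self-consistent area scale. Real
analyses should supply measured standard areas.

## Multivariate stage

The 8-category roll-up (chlorogenic acid; luteolin, apigenin and
diosmetin C/C,O-glycosides; luteolin and apigenin malonyl-glycosides;
quercetin O-glycosides; flavonolignans) produces a samples × 8 matrix on
which Pearson correlations and PCA operate. Default PCA preprocessing is
column centering plus unit-variance scaling — the standard choice for
concentration variables spanning two orders of magnitude, and without it
the high-abundance categories dominate the decomposition. Published
cumulative-variance figures for this kind of matrix (e.g. ~79% for three
components) depend on preprocessing choices that are rarely stated, so the
package treats them as soft plausibility bands (the packaged table gives
76.5% under autoscaling), not reproduction targets. Loadings are oriented
so each component's largest-magnitude entry is positive, making signs
reproducible across linear-algebra backends.

## Synthetic data: what it does and does not emulate

All generators are seed-deterministic and Gaussian: additive noise for
design responses and calibration areas, multiplicative noise for peak
areas, and additive day and residual components for precision studies.
Gaussian errors are the minimal assumption consistent with the t- and
F-based statistics the pipeline computes. Default sample sizes mirror the
reference workflow: duplicate center points in screening, 3 center points
in the CCD, six precision replicates over four days and three levels,
triplicate recoveries and triplicate sample preparations. With zero noise
every downstream stage is exact — effects, refitted surface coefficients
and quantified mass fractions reproduce their truths to machine precision
— which anchors the test-suite.

What passing these tests shows is that the *statistics* are computed
correctly under their own assumptions. The generators do not emulate
chromatographic reality: no retention-time drift, no peak overlap or
integration error, no heteroscedasticity across the calibration range, no
non-Gaussian outliers, and no day × level interaction structure beyond a
single random day shift. Agreement on synthetic data therefore says
nothing about, e.g., whether a real calibration is homoscedastic — that
must be checked on the real residuals.

## Numerical conventions and problem sizes

Reported statistics follow the printed precision of the tables they
correspond to (two decimals for validation statistics, one for µg/g) while
machine outputs keep full precision. Optimizer grids use coded step 0.01;
stationary points are cross-checked analytically where interior. The
simulation-based checks in the test-suite use 200–1000 seeds per property
(type-I rates for Mandel and Cochran at 1000 seeds with 99% binomial
acceptance bands, CI coverage at 300–400 seeds), sizes chosen so the full
suite runs in well under a minute while keeping the bands tight enough to
catch implementation errors of practical magnitude.

## Known limitations

* Raw design-response tables of the reference workflow are not published,
  so end-to-end reproduction of its screening/optimization fits is out of
  reach; the package instead proves the machinery on its own simulators
  and reproduces every derived statistic that *is* printed.
* The desirability criterion is the linear all-maximized Derringer form;
  target-value and weighted variants are not implemented.
* `estimate_effects` handles regular two-level fractions only; Plackett-
  Burman and mixed-level screening are out of scope, as are blocking and
  D-optimal designs.
* The intermediate-precision model is one-way; a laboratory wanting
  separate day and level components should fit a two-way mixed model
  directly.
* Censored values enter totals as zero (or LOQ/2 on request); no
  distributional left-censoring model is attempted.
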