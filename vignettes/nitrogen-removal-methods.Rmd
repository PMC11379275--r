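---
title: "Methods: harvest-based nitrogen removal by farmed eastern oysters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harvest-based nitrogen removal by farmed eastern oysters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anrc)
```

## The computation and its assumptions

The calculator estimates the nitrogen leaving a waterbody when a crop of
farmed eastern oysters is harvested. For a harvest of `n` oysters at mean
shell height `H` (mm), it evaluates

* the 50th-quantile allometric prediction of tissue dry weight,
  `W_t(H) = a_t H^{b_t}` (g), and likewise shell dry weight `W_s(H)`;
* tissue and shell nitrogen as those weights times the regional mean
  nitrogen concentrations (percent of dry weight), summed to whole-animal
  nitrogen `N(H)`;
* the farm total `n · N(H)` in grams, converted exactly to kg
  (÷1000) or avoirdupois lb (÷453.59237) only at output.

Three modelling assumptions matter. First, a **single regional model set**:
one tissue regression, one shell regression and one pair of nutrient means
are applied regardless of farm location, ploidy or gear. The group
differences that exist in regional data (detectable by the robust tests in
this package) are small at market sizes (63.5–88.9 mm, i.e. 2.5–3.5 in),
which is what justifies a simple tool; subgroup coefficients are retained in
the registry strictly as a sensitivity switch (`model_group`), never as the
default path. Second, the **median oyster stands for the crop**: using the
τ = 0.5 quantile curve at the mean harvest height estimates the typical
animal; the interquartile band (τ = 0.25/0.75 fits) expresses the spread of
weight-at-height, not parameter uncertainty. Third, **harvest only**: the
calculation excludes denitrification enhancement and biodeposit burial, so
it is a conservative lower bound on the farm's total nitrogen effect.

The reverse calculator returns `ceiling(load / N(H))` — it never
under-mitigates a stated load, a deliberately conservative, permit-facing
rounding. A guard corrects the rare floating-point case where the quotient
lands a hair above an integer, so the forward/reverse round trip is exact.

## Parameters and their defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| tissue model `a`, `b` | 1.42e-5, 2.607 | g·mm⁻ᵇ, – | regional τ=0.5 fit (registry `paper-2024`) |
| shell model `a`, `b` | 0.00039, 2.58 | g·mm⁻ᵇ, – | regional τ=0.5 fit |
| tissue N mean | 7.70 (sd 1.34, n 1339) | % dry wt | regional mean |
| shell N mean | 0.19 (sd 0.10, n 494) | % dry wt | regional mean |
| trim fraction | 0.2 | – | standard robust-ANOVA choice: efficiency under normality, bounded outlier influence |
| bootstrap B | 599 (tests), ≥200 (regression comparison) | – | odd B aligns percentile indices; p floored at 1/(B+1) |
| height sanity window | 20–200 mm | mm | outside it predictions extrapolate beyond data; warn, don't refuse |

The registry's published coefficients are printed, **rounded** values; the
original online tool evaluated unrounded fits. Direct evaluation of the
printed coefficients reproduces the published removal grid to within about
3% (best near 89 mm), which is why the package's own checks on those
quantities use a 5% relative tolerance rather than printed-digit equality.
No coefficients were published for the τ = 0.25/0.75 band, so the shipped
band is fitted from the synthetic generator's default conditions and its
registry provenance labels it `synthetic`/non-canonical.

## Fitting machinery

**Theil-Sen on the ln–ln scale.** `W = aH^b` is linear after ln-transform;
the slope is the median of all pairwise slopes (tied-x pairs skipped; an
even count of slopes takes the midpoint of the two central order
statistics), the intercept the median of `y - slope·x`. The estimator is
checked in the test suite against an exhaustive pairwise-enumeration oracle
on all instances with n ≤ 7.

**Nonlinear quantile power fit.** The pinball loss
`Σ ρ_τ(W_i − aH_i^b)`, `ρ_τ(u) = u(τ − 1[u<0])`, is non-smooth, so the
optimiser is a derivative-free Nelder-Mead simplex on `(ln a, b)` — the log
parameterisation keeps `a > 0` without constraints. It starts from the
ln–ln Theil-Sen fit with the intercept shifted by the τ-quantile of the
ln-scale residuals (so band fits start near their own level), plus three
jittered restarts (relative sd 0.05, seeded); each run is polished by
restarting the simplex at its own optimum, and the best start wins. The fit
must never be worse than its initializer; tolerance is 1e-10 on the loss
(`reltol`), with up to 5000 iterations per run. Records with zero dry
weight are excluded (undefined for the ln-scale initializer). Quantiles are
fitted independently — no monotone rearrangement — so curves can cross far
from the data; crossing inside the market span only raises a warning.

**Robust one-way test.** The statistic is the trimmed-mean analog of the
heteroscedastic one-way F statistic, weighting groups by inverse squared
standard errors built from winsorized variances and post-trim sample sizes.
The null distribution is a percentile bootstrap: each group is centred at
its own trimmed mean and resampled within-group B times; p is the fraction
of bootstrap statistics ≥ the observed one. A constant group has zero
winsorized variance; its squared standard error is floored at a tiny
positive value so separated point masses yield a huge finite statistic
rather than 0/0.

**Effect size.** The published tables report a bare "effect size" without
naming the statistic. This package implements an explanatory measure:
`sqrt(B / (B + W))` with `B` the (population-style) variance of the group
trimmed means and `W` the mean winsorized within-group variance rescaled by
the normal consistency constant for the trim fraction. It is zero iff all
trimmed means coincide, increases as any group separates, and is
Monte-Carlo stable; it is *an* interpretation, and reproducing the printed
effect-size values is deliberately not asserted anywhere.

**Comparing two groups' regressions.** Pairs are resampled jointly within
each group, Theil-Sen refitted, and the slope and intercept differences
each get a two-sided percentile p-value `2·min(P*(d≤0), P*(d≥0))`, clipped
to [0,1] and floored at 1/(B+1). Slope and intercept are bootstrapped from
the same replicates (jointly), a documented choice where the construction
was open.

**Reproducibility.** Every stochastic routine takes an explicit seed and
scopes it locally (saving and restoring the caller's RNG state), so a fixed
seed reproduces results byte-for-byte without side effects. R's default
generator is platform-stable, which meets the goal a counter-based
generator would otherwise serve.

## The synthetic generator

`generate_records()` emulates the structure the analysis assumes: factor
labels (state, ploidy, practice) drawn from sampling weights; shell heights
uniform on 30–150 mm by default; dry weights from the component power law
with **multiplicative lognormal noise** (additive on the ln scale — this
matches the ln-transform linearisation and guarantees positive weights);
nitrogen percents from normals truncated to (0, 100) **by resampling**, not
clipping, so no mass piles at the bounds; and independent per-column
missingness, mimicking datasets that mix length:weight-only rows with fully
paired rows. `generate_group_shifted()` adds per-level mean shifts to a
nutrient column for power and type-I-error studies; zero shifts reproduce
the base draw exactly at the same seed.

Defaults are the regional study conditions: the published allometric
coefficients, nutrient means/sds, and ln-scale weight noise sd 0.3 — the
noise scale is not a published number; it was chosen once as a realistic
match to the scatter seen in regional height–weight data and is not tuned.
What passing tests on synthetic data show is that the estimators recover
the generating structure under these conditions; they cannot show
robustness to features the generator omits — spatial autocorrelation among
farms, seasonality, measurement error in shell height, or non-lognormal
weight scatter.

## Numerical and design choices

* Units on disk are fixed (mm/g/%); conversions (25.4 mm/in,
  453.59237 g/lb, both exact) happen only at the interface, so stored data
  round-trip bit-exactly. CSV writing formats numerics to 12 significant
  digits.
* Farm totals are computed in grams in double precision with no
  intermediate rounding; display rounding (1 decimal lb/kg, 3 significant
  figures per-oyster) applies to printed reports only, and the JSON report
  retains full precision.
* A 3-inch input converts to exactly 76.2 mm; the published reference grid
  lists that column as 77 mm. The package always uses the exact conversion.
* Validation is per-row and order-independent; in non-strict mode violating
  rows are dropped and itemised by rule, in strict mode the first violation
  aborts.
* Test problem sizes were chosen to make the distributional checks sharp
  but cheap: 1000 random small instances for the Theil-Sen oracle, 500 null
  datasets × 599 bootstraps for type-I error (half normal, half lognormal
  populations), 20 seeds × n = 2000 for quantile-fit recovery and coverage.

## Known limitations

* The printed registry coefficients are rounded; exact reproduction of the
  published removal grid is bounded near 3% at 77 mm. Refitting from data
  (`anrc fit`) gives a registry free of that artefact.
* The shipped interquartile band is synthetic-fit and non-canonical; users
  with real regional records should refit it.
* The calculator extrapolates outside 20–200 mm only under a warning, and
  subgroup models are back-transformed medians of ln-scale fits — a median
  on the ln scale, not a mean on the raw scale.
* Nitrogen means and allometry are treated as independent, fixed constants;
  the band does not propagate uncertainty in the nutrient means.
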