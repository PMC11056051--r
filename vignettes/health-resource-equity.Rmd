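---
title: "Measuring decadal equity in county health-resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring decadal equity in county health-resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equipanel)
```

`equipanel` analyses the equity of hospital beds, doctors and nurses
across the counties of a province over a decade. This vignette is the
package's own account of the methods: the indicators and the inequality
model, the assumptions behind the regressions, what the synthetic-panel
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## The data model

The unit of observation is a county-year. A panel is a long-format tibble
with one row per county and year carrying resident population, counts of
beds, licensed doctors (physicians and physician assistants, excluding
village doctors), registered nurses, and all health practitioners, plus
three covariates: average annual practitioner income, GDP per capita, and
county mean altitude (metres above sea level). Counties carry one of five
fixed category labels — Yi, Zang, other ethnic minority (OMC),
poverty-stricken (PSC) and non-minority (NMC) — that is constant over the
study window: the categories come from a single government classification
applied to the whole decade, and counties qualifying as both
ethnic-minority and poverty-stricken are classified under their minority
category, keeping the partition mutually exclusive and exhaustive.

`validate_panel()` checks, and `as_panel()` enforces, the structural
invariants: a balanced panel (every county in every year), positive
populations, finite non-negative counts, and practitioner consistency
`health_practitioners >= doctors + nurses` — the remainder of the health
workforce (roughly 16–31% in the motivating province) being pharmacists
and clinical laboratory technicians. Missing covariates are allowed as
explicit `NA`s and are excluded from regression fits only; density and
Theil series always use every row, so an income gap in the yearbook never
punches a hole in the equity series.

## Indicators and growth

Densities are per-1000 quantities, `1000 * count / population`. Decade
growth of a density `H` is the relative change
`(H_end − H_start) / H_start`; a zero starting density has no defined
growth and is an error, never a silent infinity. Two staffing ratios
summarise the mix: doctors-plus-nurses per bed (`DNpB`) and
doctors-plus-nurses as a fraction of all practitioners (`DN/HP`, at most
1 on any panel passing practitioner consistency).

Two category-level estimands are deliberately kept apart:

* **aggregate** (the default): 1000 × (summed counts over the category's
  counties) / (summed population) — the population-weighted level a
  planner would quote, and the scale on which headline decade growth is
  computed;
* **mean of counties**: the unweighted mean of county densities — the
  estimand behind distributional statements such as "half of this
  category's counties lost doctors per capita".

Both are exposed and labelled in every output, because the two answer
different questions and mixing them silently is a classic source of
irreproducible percentages. Growth summaries report both, plus the share
of a category's counties with negative growth and the share growing
strictly more slowly than the province aggregate. "Strictly below" is
implemented with a 1e-9 relative guard so that counties growing at
exactly the province rate (a tie that arises naturally in constructed
data) never flip on floating-point noise; ties count as not-lower.
Percentages for comparison with published tables are rounded to the
nearest integer; machine outputs keep the raw fractions.

## The inequality model

The package measures inequality with the population-weighted Theil index
across counties,

$$TI = \sum_{i=1}^{n} p_i \ln\!\frac{p_i}{y_i},$$

where $p_i$ is the county's share of total population and $y_i$ its share
of the resource. This is the population-share-weighted mean log deviation:
zero exactly when every county holds resources in proportion to its
population, positive otherwise, symmetric in county order, invariant to
replication of the county list and to rescaling all resources by a
constant, and never increased by a progressive transfer. It is implemented
exactly in this form (natural logarithm throughout) rather than as the
resource-weighted Theil-T variant; the two differ, and the
population-weighted form is the one this pipeline is built around.

The county partition splits the index additively:

$$TI = TI_{intra} + TI_{inter},\qquad
TI_{intra} = \sum_j p_j\, TI_j,\qquad
TI_{inter} = \sum_j p_j \ln\!\frac{p_j}{y_j},$$

with $TI_j$ the same index computed within category $j$ on within-category
shares. The between-group term is the mean log deviation on category-level
shares — the only reading under which the additive identity holds, and the
implementation asserts that identity to 1e-12 relative tolerance on every
call. Contribution shares `intra_share`/`inter_share` are reported as
fractions of `TI`; when `TI = 0` they are undefined and reported as `NA`,
never as 0/0.

A county with positive population and zero resources makes the index
diverge. The package refuses to compute in that case, naming the county,
rather than regularising silently — an epsilon floor on resource shares
would bend an equity series without the analyst noticing. An explicit
`epsilon` argument (default off) is available for exploratory use and is
documented as a distortion.

## Regressions and diagnostics

The association module fits bivariate OLS of a density on one covariate:
pooled over all county-years for income and GDP per capita (the decade
scatter, n = counties × years), and single-year cross-sections for
altitude (n = counties). The slope test is the regression F-test of zero
slope at α = 0.05 — for a simple regression this is the identical object
to a one-way ANOVA on the slope, and equals the squared slope t-statistic;
the implementation asserts `F = (n−2) R² / (1−R²)`.

Three assumption checks accompany every fit, advisory only (they never
block a fit, matching how such checks are used in applied reporting):
normality of residuals by Shapiro–Wilk for n ≤ 5000 and Anderson–Darling
beyond, homoscedasticity by Breusch–Pagan, and independence by
Durbin–Watson. The choice of these particular tests is this package's
decision; the assumptions themselves are the standard linear-model trio.
On perfectly linear data (zero residual variance) all three are reported
as not applicable rather than spuriously computed.

Two pooling caveats are deliberate, documented behaviour rather than
oversights: county-years are treated as independent observations (no
clustering by county, no panel correction), and incomes are nominal across
the decade (no deflation). Both match the design of the decade-scatter
analyses this package reproduces; slopes and p-values should be read
accordingly.

## The synthetic-panel generator

`synthetic_config()` describes, and `generate_panel()` draws, a
Sichuan-shaped panel: 12 Yi, 32 Zang, 23 OMC, 32 PSC and 82 NMC counties
(181 in all) over 2009–2019. The generator is first-class, tested code —
it is how the pipeline is validated end to end without the source
yearbook — and its defaults are the study conditions, not tuning knobs.

Each county's density for a resource follows

$$d_{c,t} = b_{g(c)} \,(1+G_c)^{(t-t_0)/T}\; f_c \; \eta_{c,t},$$

a category baseline $b_g$ per 1000, a geometric decade-growth trajectory,
a time-constant log-normal county frailty $f_c$ (within-category
heterogeneity), and i.i.d. mean-one log-normal year noise $\eta$ with
configurable coefficient of variation. Counts are the density times the
county population, rounded to integers (yearbook counts are integers; the
rounding bounds every exactness tolerance in the tests) with a floor of 1
for beds, doctors and nurses so the Theil index stays finite by default —
a `count_floor = 0` switch exposes the divergence path deliberately.
Practitioner totals inflate doctors-plus-nurses by a per-county overhead
share drawn uniformly from [0.16, 0.31], the pharmacist/technician band.

Default parameter choices, made once and documented here:

* **Category baselines and decade growths.** The published decade growth
  percentages are used where they exist (beds: Yi 140%, OMC 127%, NMC
  121%; doctors: Yi 20%, Zang 11%, NMC 61%; nurses: Yi 240%, OMC 316%,
  NMC 198%). The six unpublished cells (beds Zang 95%/PSC 130%; doctors
  OMC 75%/PSC 70%; nurses Zang 120%/PSC 260%) are set to match the
  decade's qualitative record — Zang lowest in all three indicators, OMC
  and PSC above the province average. Baseline 2009 densities rank the
  categories as the decade's level trends do (Yi lowest, NMC highest).
* **Populations** are log-normal with `meanlog 12.4`, `sdlog 0.5`
  (median ≈ 240 000 residents, a realistic county scale) and a common
  0.5%/year growth; the common growth rate makes category aggregate
  density growth exactly the count-weighted mean of county growths, which
  the negative-growth compensation (below) relies on. The dispersion is a
  calibration choice — real within-category dispersion is not published —
  set so that category aggregates average over enough effective counties
  for growth recovery at the tested noise level.
* **County frailty** `sdlog 0.25` gives within-category density spreads
  of roughly ±25%, enough to make the within-category Theil component
  non-trivial. The resulting intra/inter split is *not* calibrated to the
  published contribution shares; only the growth percentages and
  negative-growth shares are.
* **Covariates.** Income and GDP levels per category with geometric
  trends and county jitter; altitudes at the published category means
  (Yi 2139 m, Zang 3656 m, OMC 1592 m; 900/600 m for PSC/NMC) with
  log-normal jitter, constant over years.
* **Optional effects.** A linear altitude→density effect ramps from zero
  in the first year to full strength in the last (altitude gradients in
  the motivating decade emerged over time, significant at the end but not
  the start); a linear income→density effect applies uniformly on
  within-year-centred income. Both default to zero: in the paperlike
  configuration the altitude and income associations emerge from the
  category structure itself (high-altitude categories have the low
  baselines and growths), not from injected slopes.

`paperlike_config()` adds the negative-growth injection: doctor growth of
−10% is forced on a flagged 1/3 of Yi and 1/2 of Zang counties, and the
remaining counties' growth is raised to exactly compensate, so the
category aggregate still meets its configured growth while the flagged
shares are recovered by `share_of_counties()`. The flags are recorded in
the ground truth, so share recovery is exact bookkeeping, not estimation.

The randomness contract: one root seed; each county draws from a
substream seeded by its category and within-category index, so enlarging
one category never perturbs another county's draws; the caller's RNG
state is restored on exit.

**What the generator does not emulate** — and therefore what passing
tests do and do not show about real data: no spatial autocorrelation
between neighbouring counties, no migration or county reclassification,
no correlated measurement error in the yearbook counts, no within-decade
policy shocks (trajectories are smooth geometric curves), and a
within-category dispersion that is a calibration choice rather than an
estimate. Tests on generator output therefore validate the *pipeline
arithmetic and inference machinery* under known truth; they do not
validate substantive conclusions about any real province.

## Numerical choices and degenerate inputs

* Theil additivity is asserted at 1e-12 relative tolerance; the oracle
  tests require equality with a brute-force evaluation of the defining
  sum at the same tolerance.
* Zero-resource counties: divergence error naming the county (default),
  explicit epsilon floor otherwise.
* Zero starting density: growth undefined, typed error.
* Constant predictor or constant response in OLS: typed errors
  (`degenerate predictor` / undefined R² on zero total sum of squares);
  fewer than 3 complete observations: insufficient-data error.
* Ties against the province growth: not-lower, with a 1e-9 relative
  guard.
* Contribution shares at `TI = 0`: `NA`.
* Count rounding: nearest integer with floor 1; exactness tests carry a
  one-count tolerance per county.

## Problem sizes used in the test-suite

The suite validates the Theil machinery on 200 random small instances
(n ≤ 8 counties, ≤ 3 categories) against a brute-force oracle; growth
recovery on 20 full-size replicate panels (181 × 11) at count noise
CV 0.05, comparing the growth of seed-averaged aggregate densities —
the unbiased point estimate over replicates — to the configured values
within ±0.03 absolute; the slope test's type-I rate on 500 null
cross-sections of 181 counties (three-sigma binomial band around 5%);
and 90% detection power on 100 generator replicates with an injected
altitude slope of two residual standard deviations per altitude range.
These sizes are the package's validation design: large enough for the
binomial and recovery bounds to be meaningful, small enough to run
routinely.

## Known limitations

Inference treats county-years as independent; there are no clustered
standard errors, no deflation of nominal incomes, no confidence intervals
on the Theil series (point series only, matching the reporting style of
the analyses this reproduces), and no alternative inequality measures
(Gini, Atkinson, concentration index) — the Theil index was chosen for
its exact additive group decomposition, which is the analytical point.
The five-category scheme is fixed; the pipeline does not re-derive it
from attributes. The comparator checks printed values under stated
rounding; it cannot detect compensating errors that survive rounding.
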