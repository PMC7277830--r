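---
title: "From registry tables to exposure-classified birth cohorts: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From registry tables to exposure-classified birth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cohortair` assembles analysis-ready birth cohorts from administrative
registry tables and assigns each pregnancy a residential air-pollution
exposure and a neighbourhood deprivation level. This vignette documents the
underlying models, the conventions the package fixes where registry practice
is ambiguous, the design of the synthetic-data generator, and the limits of
what the test suite can show about real data.

## 1. The pipeline and its assumptions

The pipeline links five tables by the mother's id — delivery certificates,
residence episodes, census blocks, address-level modelled annual
concentrations, daily background-monitor series — plus hospital discharges
and a birthweight reference chart. Ids are exact keys: no probabilistic
record linkage is attempted, matching the deterministic individual codes of
municipal registries.

The pregnancy is anchored at the date of the last menstrual period (LMP):
day 0 is the LMP and the pregnancy interval is the half-open, day-resolution
window `[LMP, delivery)`. Certificates carry gestational age in completed
weeks, so `delivery = LMP + 7 × weeks` holds exactly in generated data and
is the consistency expected of real inputs. We deliberately do not shift the
anchor by the ~14 days between LMP and conception; every downstream window
is defined relative to the LMP because that is the date the registries
record.

Selection proceeds in two steps. `select_initial()` applies the demographic
filters (singleton, livebirth, maternal age 15–49 inclusive, delivery year
in range); records with missing singleton/livebirth flags are routed to a
reject log rather than dropped, because silent attrition is the failure mode
audits exist to prevent. `apply_cascade()` then applies the exclusion
sequence — missing geocoding, missing exposure, malformation, missing
outcome fields — in that fixed order, counting each record once at its first
failing step. The order is a convention (a record can fail several filters);
fixing it makes the audit counts telescope, which is the accounting identity
the tests assert per city and overall.

Two percentage conventions are worth stating explicitly, since both are
implemented:

* printed percentages are rounded half-up to one decimal
  (`round_half_up()`), not half-to-even;
* the audit's linkage-success row is reported two ways: `pct_linkage_exact`
  = `100 (n − geocoding − exposure) / n` rounded, and `pct_linkage` = `100 −
  rounded geocoding% − rounded exposure%`. Registry reports typically print
  the latter (the complement of the already-rounded exclusion rows), and the
  two can differ by 0.1 when a component sits near a rounding boundary. The
  reference audit shipped in `inst/extdata/` reproduces cell-for-cell only
  under the complement convention, which is why the renderer uses it.

## 2. Deprivation index

The block-level index is the unweighted sum of five z-standardized component
percentages: low education, unemployment, home tenancy (renting counts as
deprivation), lone-parent families, overcrowding. Standardization uses the
pooled block set across all cities — the index is constructed on a common
national-style reference — with the sample standard deviation (n−1).
Whether such indices weight blocks by population during standardization
varies between implementations; we standardize unweighted and flag this as
a choice, since only the within-city *ranking* feeds the quintiles and the
ranking is unaffected by any per-component affine rescaling.

Quintiles are population-weighted within city: blocks sorted by ascending
score (ties broken deterministically by block id), cumulative resident
population cut at 20/40/60/80% of the city total, and a block straddling a
cut goes entirely to the lower quintile. Each quintile's population share
therefore deviates from 20% by at most one maximal block share — the bound
the property tests assert against a cumulative-walk oracle. Births link to
the block of the residence at delivery (the address occupied on the day
before delivery, falling back to the last pregnancy address under tolerated
gaps); with residential mobility this is a convention, recorded so a
sensitivity analysis can switch to, e.g., the longest-occupied address. The
2011 census index is the default; 2001-vintage blocks pass through the same
code.

## 3. Exposure assessment

**Standard model.** Each address carries a modelled (land-use-regression)
annual concentration in µg/m³, treated as a time-constant spatial surface.
The mother's standard exposure is the weighted mean of her addresses'
concentrations, weights proportional to days of residence within the
window; with a covering residence history the weights sum to 1, and under a
tolerated gap (`tolerance_days`, default 0) they are renormalised over the
covered days. The exposure is therefore always inside the range of the
mother's own address concentrations.

**Back-extrapolation.** The spatial surface is assumed stable over time;
temporal variation enters through the city's background monitor. With
`M_LUR` the monitor mean over the LUR campaign period (default the 2010
calendar year, configurable per city and pollutant) and `DC(d)` the daily
concentration, each day is rescaled by `Ratio(d) = DC(d)/M_LUR` and the
window exposure is the mean of `C_address(d) × Ratio(d)` over window days.
Two readings of "the concentration attributed to the subject" are
implemented: the default resolves the address day by day (so a move
interacts correctly with the temporal signal); `constant_weights` instead
uses the pregnancy-constant weighted concentration on every day. The two
coincide for non-movers and whenever the monitor series is flat — the
degenerate-limit identities the tests pin at 10⁻¹².

**Windows.** Trimesters cut at days 90 and 180 (≈13/26 weeks), the first
five months are days 0–149, the last week is the final 7 calendar days
before delivery. Gestations under 180 days yield an empty third trimester,
flagged rather than errored; gestations outside 154–315 days (22–45 weeks)
are marked invalid for the reject log. Season of conception follows the LMP
month (Dec–Feb winter, etc.). "Last week" could alternatively mean
gestational week ≥37; the final-7-days reading is used because it is
defined for every birth.

**Numerical conventions.** Monitor gaps are filled by linear interpolation
between the nearest observed flanking days up to `max_gap_days` (default 7);
longer gaps fail loudly, identifying the date range — silent imputation of
long outages would bias winters, where outages and peaks coincide. Up to 10%
of campaign-period days may be missing when computing `M_LUR` (mean over
available days, with a message); more is an error.
Back-extrapolation is attributed only to deliveries in 2008–2013, so that
the monitor record (available from 2007) covers every pregnancy day; other
births carry `NA` with an availability flag.

## 4. Outcomes

Boundary conventions are strict, matching the definitions' printed
inequalities: preterm `< 37` completed weeks; term low birthweight `< 2500`
g among term births (preterm births are excluded from the denominator, and
carry `NA`); small for gestational age strictly below the 10th percentile of
the sex × gestational-week × parity reference chart. The reference defines
only the "small" tail; we classify "large" symmetrically as strictly above
the 90th percentile, so weight-for-GA is a three-class partition. Apgar is
banded 7–10 / 4–6 / 1–3, with 0 routed to an explicit unclassified bucket.

Hypertensive-complication flags scan discharges admitted within the closed
interval `[LMP, delivery]` for ICD-9 codes stored undotted and matched by
string prefix: `642` sets the family flag, fourth digit 4–7 sets the
preeclampsia/eclampsia flags. A bare three-digit `642` therefore sets only
the family flag — prefix semantics, asserted against an enumeration oracle.
Malformed code strings are skipped with a warning, never fatal.

## 5. Descriptives

Categorical summaries use non-missing denominators (missing counts are
reported alongside). The high-exposure flag is exposure strictly above the
75th percentile of the whole-pregnancy standard exposure, computed with the
type-7 (linear-interpolation) quantile — the most common default, stated so
the above-threshold count is reproducible: with n tie-free values it is
`floor(n/4)` up to ±1 depending on `n mod 4`. The percentile scope is
within-city by default, so the socioeconomic gradients are interpretable per
city; a pooled scope sits behind a flag, since between-city level
differences would otherwise dominate the contrast. Prevalences carry Wilson
95% intervals, chosen over the normal approximation for its behaviour at
small counts; the outcome summary tables use the normal approximation, and
neither interval style is treated as a validated quantity by the tests.

## 6. The synthetic-data generator

The generator emits every input table with the statistical structure the
pipeline assumes, under a single seed (identical seed and configuration
reproduce the bundle bit-for-bit; per-table sub-seeds are derived
deterministically so a monitor series is identical standalone or inside the
bundle).

Study conditions baked into the defaults: deliveries 2007–2013; maternal age
truncated normal around 32.5 (15–49); ~6% of gestations below 37 weeks, with
a term distribution peaking at 39–40 weeks (pooled mean ≈ 39 weeks, sd ≈
1.8); birthweights drawn from the same reference chart the classifier uses
(normal within stratum, sd 13% of the stratum mean, ≈490 g pooled, boys ~3%
heavier, parous mothers slightly heavier), which makes the ~10%
small-for-GA recovery a closed-loop check of the classifier rather than a
claim about any real reference; socio-demographic covariates at realistic
marginal frequencies with sub-2% missingness (one city may be configured
higher for education, mirroring the uneven completeness of real
certificate fields); 15% of mothers move once during pregnancy; daily
monitor series `baseline × (1 + amplitude·cos) × (1 − decline)^years +
noise`, peaking in early January with a slow multi-year decline, which is
the winter-peaking shape of urban Italian PM and NO₂ series and yields the
closed-form identities the tests check (flat-series constancy, the
`(1−decline)⁶` annual-mean ratio between the two non-leap endpoint years).

Linkage failures are *planted*, mutually exclusively, at configurable rates
(no linkable address; an out-of-city residence gap; a missing concentration;
a malformation; a missing outcome field), and the ground-truth labels ship
in the bundle — so the selection audit is checked against known truth
rather than against itself.

Geography is abstract: addresses are ids carrying a census block and
per-pollutant concentrations; there is no coordinate math and no spatial
surface. The deprivation–pollution association is induced per city and
pollutant through a Gaussian copula on the block's realized deprivation
signal: address concentration couples to the standardized component sum
with correlation ρ ∈ [−1, 1], so at |ρ| = 1 concentration is a
deterministic monotone function of the very score the index ranks on, and
the crosstab gradient across quintiles is generator ground truth. Two
consequences are worth knowing when designing checks: at |ρ| = 1 all
addresses of a block share one concentration, which creates ties in the
exposure distribution (the tie-free 25%-above-threshold identity should be
checked at |ρ| < 1); and residential movers are binned by delivery address
while their exposure mixes two blocks, so strict tail monotonicity is only
guaranteed with mobility switched off.

What the generator does **not** emulate — and hence what green tests do not
show about real data: spatially correlated LUR surfaces and their error;
monitor outages and instrument drift; heaping of registry dates and
birthweights; correlated missingness (real missing education is not
independent of citizenship); multiple gestations, terminations and
transcription errors; and any real city's deprivation geography. The
pipeline's accounting, window arithmetic and classification logic transfer;
calibration of levels to a specific city does not.

## 7. Problem sizes and runtime choices

The shipped analysis uses a five-city study scaled to ~11,000 births over
seven years (≈1/20 of a realistic network), which keeps a full run in tens
of seconds while leaving every per-city table non-trivially populated. The
validation suite uses 50,000 births for the small-for-GA recovery (3-σ
binomial tolerance ≈ ±0.4 percentage points), 10,000 for the seasonal
orderings, 1,000 random fixtures for the day-by-day exposure oracles at
10⁻¹², and 500 for the quintile walk. These sizes were chosen so each check
has clear statistical headroom at its tolerance.

## 8. Known limitations

* Exposure attribution needs a covering residence history; the default
  zero-tolerance coverage mirrors strict cohort definitions, and any
  tolerated gap renormalises weights over covered days rather than imputing.
* The back-extrapolation inherits the stable-spatial-surface assumption of
  LUR; nothing in the package can detect a surface that changed over time.
* `M_LUR` uses a single pre-averaged background series per city and
  pollutant; multi-monitor averaging must happen upstream.
* The growth reference is synthetic and clearly labelled as such; analyses
  of real cohorts must substitute the national reference chart, which the
  table-driven classifier accepts unchanged.
* Confidence intervals in summary tables are descriptive conveniences, not
  calibrated inferential output.
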