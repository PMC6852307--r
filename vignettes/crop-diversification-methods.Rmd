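---
title: "Methods: pollinator dependence and crop diversification from area panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollinator dependence and crop diversification from area panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropdivr)
library(dplyr)
```

## The scientific question

Global agriculture has been shifting toward crops whose fruit or seed
yield depends on animal pollination — most oilseed, fruit and nut crops —
while staple cereals, which need no pollinators, expand more slowly. A
diversified agriculture supports richer pollinator assemblages; a
landscape dominated by one or two pollinator-dependent monocultures
simultaneously raises the demand for pollination services and degrades
the conditions that sustain them. The quantities this package computes
from country × crop × year harvested-area panels are designed to measure
exactly that tension:

* the **pollinator-dependence share** of agriculture — the proportion of
  harvested area under pollinator-dependent crops;
* **crop diversity** as the effective number of crops $e^{H'}$, with
  $H' = -\sum_i p_i \ln p_i$ the Shannon–Wiener index over area shares
  $p_i$, plus its components, richness $S$ and Pielou evenness
  $J = H'/\ln S$;
* per-country **compound annual growth rates** of area, dependence,
  diversity, richness and evenness between two endpoint years,
  $\Delta_x = 100\,\bigl(e^{(\ln x_{t_1}-\ln x_{t_0})/(t_1-t_0)}-1\bigr)$ %/yr;
* two **vulnerability indices**, $\Delta_\text{area}-\Delta_\text{diversity}$
  and $\Delta_\text{dependence}-\Delta_\text{diversity}$, positive when
  expansion or dependence growth outpaces diversification;
* **regional comparisons** of those rates through linear models that allow
  a separate residual variance per region, with least-squares means and
  Tukey-adjusted pairwise contrasts.

## Input model and preprocessing

The universal input is a tidy panel of (entity, crop, year, harvested
area in hectares), the long layout used by the FAO's bulk crop data.
Three preprocessing rules matter and each is a deliberate choice:

**Successor-state harmonization.** Entities that subdivided after the
start of the analysis window report later years under successor names.
`harmonize_entities()` re-aggregates successor areas under the historical
reporting entity for *every* year present, not only the final one; for a
panel where predecessors reported the early years this is equivalent and
yields a continuous series either way. The bundled rule set covers the
six standard merges (Czechoslovakia, Ethiopia PDR, Sudan (former), the
USSR's fourteen republics, the Yugoslav SFR, Belgium–Luxembourg). A
successor record that would collide with an existing record of its
target is a hard merge-conflict error rather than a silent double count.
Because the modern FAO name "Sudan" is itself a successor of the
pre-partition entity, the bundled target is named "Sudan (former)";
a rule whose target equalled one of its sources would always
self-collide.

**Minimum-area exclusion.** Countries with less than 1,000 km²
(100,000 ha) of total harvested area at the baseline year are removed for
all years, with a report of who was excluded and why. Tiny baselines
produce wildly unstable growth rates — a few km² of 1961 agriculture can
compound into three-digit annual percentages. The boundary is strict
(`< threshold`): an entity at exactly 100,000 ha is retained. Internally
everything stays in hectares; the km² threshold is converted once at the
API boundary so no silent unit drift is possible.

**Zero handling.** Missing (entity, crop, year) combinations count as
zero area in aggregates but are never materialised as records, and
zero-area crops do not count toward richness: presence means positive
harvested area. This mirrors how the source data omit non-cultivated
crops, and it is an assumption — a reported zero row and an absent row
are treated identically.

## Dependence classification

Crops are classified by the percent reduction in fruit or seed
production observed when pollinators are experimentally excluded:
`none` (exactly 0), `little` (0–10%], `modest` (10–40%], `high`
(40–90%], `essential` (>90%]. The brackets are upper-inclusive, so a
crop at exactly 10% is `little`. "moderate" is accepted as an alias of
"modest" since both names circulate for the same class. The
dependence share for an entity-year divides dependent area by the total
*classified* area: crops missing from the dependence table are excluded
from both numerator and denominator (with a warning) rather than assumed
nondependent, because a classified-crop subset that covers ~95% of area
is a better denominator than one silently contaminated by unknowns. The
bundled table (`load_dependence_table()`) covers ~50 major crops with
categories consistent with the published literature; it is explicitly a
synthetic stand-in (see its filename) for the full published
classification, and any user-supplied CSV overrides it. Rows carrying a
percent reduction are cross-checked against their own category's bracket
at load time.

## Growth rates and their degeneracies

Rates use only the two endpoint years, exactly as the compound-growth
formula dictates; intermediate years inform the global percent-change
series but not $\Delta$s. The formula is undefined when either endpoint
is non-positive. We return `NA` with a machine-readable reason code
(`nonpositive_start`, `nonpositive_end`, `missing`) and *never*
epsilon-adjust: a country whose dependence share was 0 in the base year
has no defined dependence growth rate, and inventing one by adding a
small constant would fabricate the quantity being studied. Evenness is
undefined for single-crop endpoints ($\ln 1 = 0$); the same reasoning
applies — any convention (0 or 1) would be invented, so the value is
flagged and excluded downstream. Undefined rates propagate as `NA` into
vulnerability indices and are dropped listwise, with counts, by the
regional models.

The crop-expansion ranking excludes crops with zero global area at
either endpoint from the rate ranking (reporting them separately as
novel or discontinued) and breaks rate ties by larger absolute area
change, then alphabetically, so output order is deterministic.

## The G-test

The 2×2 cross of top-$k$/bottom-$k$ expansion membership against
dependence is tested with the likelihood-ratio (G) statistic,
$G = 2\sum O \ln(O/E)$, on 1 df. Three variants are implemented: no
correction (default), the Williams correction
($G/q$ with $q = 1 + (N/r_1 + N/r_2 - 1)(N/c_1 + N/c_2 - 1)/(6N)$), and
the Yates continuity correction (each count shifted 0.5 toward its
expectation). For the reference 20-fastest/20-slowest table with 16 and
6 dependent crops respectively, these give 10.600, 10.212 and 8.501. All
three are printed rather than a single "right" one, because the choice
of correction materially changes the statistic at these sample sizes and
published G values for this kind of table are not always reproducible
from the printed counts under any one variant. p-values are reported
throughout but drive no automated decision.

## Heteroscedastic regional models

Growth rates are modelled with main-effects linear models: region alone
for $\Delta$area; region plus $\Delta$area for $\Delta$dependence;
region, $\Delta$area and $\Delta$dependence (entered simultaneously) for
each of the three diversity responses. Regional variances plainly differ
in this kind of data — Oceania's three eligible countries cannot have
the same residual spread as fifty African ones — so each model is fitted
both with a single residual variance and with one variance per region,
and the two are compared by REML AIC and a likelihood-ratio test on
$G-1$ df (identical fixed effects make REML likelihoods comparable).

Estimation is iterative feasible GLS written for this package: weighted
least squares for the coefficients alternating with per-group variance
updates $\hat\sigma^2_g = \mathrm{RSS}_g/(n_g - h_g)$, where $h_g$ is
the within-group trace of the weighted hat matrix. This
leverage-corrected denominator is the REML-style correction: for the
pure group-means model it gives exactly $\mathrm{RSS}_g/(n_g-1)$, and
with covariates it is the standard refinement. Iteration stops when the
relative change in the REML log-likelihood drops below 1e-8 (at most 100
iterations; non-convergence is an error carrying the likelihood trace,
not a silent result). In testing, coefficients, REML log-likelihoods and
AICs agree with the reference `varIdent`-style implementation to
numerical precision, which serves as an independent cross-check, never
as the implementation.

Least-squares means hold covariates at their grand means. Pairwise
contrasts use the Tukey–Kramer adjustment through the studentized-range
distribution with per-contrast Satterthwaite degrees of freedom obtained
from the per-group decomposition of each contrast's variance (for the
group-means model this reduces exactly to Welch's two-sample df). With
two levels the adjusted p equals the Welch t-test p. The compact letter
display uses the insert-and-absorb construction: start from one
all-level group, split every group containing a significantly different
pair, drop subsets, and assign letters ordered by group mean — so
sharing a letter is equivalent to "not significantly different at
$\alpha$". Tukey–Kramer rather than an exact multivariate-t adjustment
is deliberate: it is deterministic, standard, and accurate at five
groups.

## The synthetic world

`generate_panel()` builds FAOSTAT-like panels in which every country
draws a baseline area per crop from a configured log-normal and each
crop's area then compounds at its true rate with optional multiplicative
log-normal noise, $x(t) = x(t_0)\,(1+r/100)^{t-t_0} e^{\varepsilon_t}$.
Noise is multiplicative because areas are positive and the rate formula
lives on the log scale. The base year carries no noise, so configured
baselines are exact. Ground truth is computed analytically from the
drawn baselines and configured rates — never by running the pipeline —
which keeps the oracle independent of the system under test: a
noise-free run must recover every configured rate to at least 1e-8
relative error (observed: ~1e-14).

The presets encode qualitative regimes seen in real panels: a 5-region ×
25-country × 30-crop × 56-year mixed world for end-to-end runs; uniform
expansion (area grows, diversity exactly flat); European-style
substitution (total area contracts while dependent crops replace
nondependent ones); Pacific-rim-style diversification (minor dependent
crops outgrow the staple); and a soy-style takeover in which one
modest-dependence oilseed at +8 %/yr against static staples collapses
evenness while driving the dependence vulnerability index positive.
Noise defaults to zero because the presets' first job is exactness
checking; tests that need stochasticity pass `noise_sd` explicitly.
Baseline spread (`sdlog = 0.5`) gives realistic order-of-magnitude
variation between countries without degenerate tiny baselines.

What the presets deliberately do **not** emulate: revisions of
historical values, reporting gaps, crops entering or leaving cultivation
mid-series, correlated shocks across crops (weather, policy), or any
attempt to match real global area marginals. Passing tests therefore
demonstrate that the *computations* are exact and the estimators behave
as designed — not that real panels satisfy the generator's assumptions.
Reproducing published headline figures additionally requires the actual
area download and the complete published crop classification, supplied
by the user through the same file-based interface.

## Problem sizes and numerical choices

Test and validation runs use the scales the methods were designed
around: 1,000-vector property sweeps for the diversity identities and
the G-test oracle; 5 regions × 200 countries for variance-ratio
recovery; 200 replicates at 25 countries per region for interval
coverage (observed ≈ 95–96%, within the designed [90%, 98%] band); and
the full 5 × 25 × 30 × 56 preset for end-to-end runs, which completes in
seconds on a single CPU. Share vectors are validated to sum to 1 within
1e-9 and renormalized, covering floating-point accumulation without
masking genuine errors. All randomness flows from a single explicit
seed; reruns with the same configuration are byte-identical.

## Known limitations

* Entity names match as exact trimmed strings; no fuzzy matching. This
  is reproducibility over convenience — a fuzzy match that guesses
  wrong corrupts a merge invisibly.
* The dependence table is crop-name-keyed; item-code keying would be
  more robust for real FAO extracts but names are what the bundled
  stand-in and synthetic worlds share.
* Only harvested-area elements are handled; production and yield are out
  of scope.
* The regional models are unweighted: a small country counts as much as
  a large one, which is the standard reading when no weighting scheme is
  stated, but it is a choice.
* No changepoint analysis of the global series; inflections are left to
  visual inspection of the percent-change plot.

## A worked example

```{r example}
presets <- preset_scenarios(seed = 11)
gen <- generate_panel(presets$soy_takeover)
growth <- country_growth_table(gen$panel, gen$dependence,
                               regions = gen$regions)
vulnerability_indices(growth) |> head(3)
```

Every country in this scenario shows negative evenness growth with a
positive dependence-vulnerability index: expansion of one
pollinator-dependent crop is simultaneously raising reliance on
pollinators and eroding the diversification that would support them.
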