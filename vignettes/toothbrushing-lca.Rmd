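---
title: "Methods: life cycle assessment of community toothbrushing programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life cycle assessment of community toothbrushing programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushLCA)
```

## The question and the functional unit

Caries prevention at community scale is delivered in the UK through two
kinds of toothbrushing programme: *supervised toothbrushing in schools*
(school staff supervise one brushing per school day, with materials provided
by the dental service) and *targeted provision of toothbrushes and
toothpaste* (quarterly packs delivered via schools so a child can brush
twice daily at home). This package quantifies the environmental footprint of
those programmes with life cycle assessment (LCA). All results are expressed
per **functional unit**: one five-year-old child receiving the programme for
one year.

## Foreground inventory model

The foreground — the part of the product system modelled explicitly — has
five components per programme: toothbrush supply, toothpaste supply,
tap-water use, staff delivery travel, and the storage/packaging item (a
"toothbrush bus" holder for the supervised programme, a zip-lock bag for
provision). The per-child-year demands follow from a small set of
parameters, all exposed in `programme_parameters()`:

| parameter | supervised | provision | unit |
|---|---|---|---|
| brushes per year | 5 | 4 | item |
| toothpaste tubes per year | 0.65 | 4 (100 ml each) | item |
| brushing episodes per year | 195 (school days) | 730 (2 × 365) | episode |
| tap water per episode | 2 | 2 | L |
| bus holders (177 g ABS, 10 children) | 3/year | — | item |
| zip-lock bag (1.5 g) | — | 4/year | item |
| delivery round trip | 13 km / 180 children, quarterly | same | km |

The 2 L per episode derives from a 6 L/min tap running for 20 s
(`tap_run_litres(6, 20)`), giving annual water budgets of 390 L and
1,460 L (`annual_water_litres()`). Toothpaste is a generic 100 ml fluoride
formulation split across seven ingredients by mass fraction
(`toothpaste_recipe()`; sorbitol 53.66%, silica 25%, water 17.5%, SLS
1.75%, xanthan gum 1.5%, sodium fluoride 0.315%, sodium benzoate 0.275% —
exactly 100%). Mixing electricity is allocated to a tube by volume share of
a 68 kW, 500 L, 2.4 h batch (`mixing_energy_per_tube()`, 0.03264 kWh per
100 ml).

Several bill-of-materials values are *not* study-reported quantities: the
toothbrush component masses (15 g polypropylene handle + 0.5 g nylon
bristles; 10 g bamboo handle with brass staples), packaging masses, and the
non-mixer machine energies come from a separately published toothbrush
teardown and are shipped as documented placeholders in
`component_defaults()`. They are configuration, not findings; replace them
for substantive work on toothbrush design.

Deliberate modelling choices where the design was open:

* **Quarterly deliveries (`trips_per_year = 4`)** — quarterly delivery is
  the only stated frequency for both programmes.
* **Zero default commute (`commute_km = 0`)** — staff commuting is
  acknowledged but no distance is stated; a configurable parameter with a
  zero default avoids inventing one, at the cost of understating the
  travel component relative to assessments that include commuting.
* **Tube content 100 g per 100 ml** — the tube is specified by volume
  only; density 1.0 g/ml is assumed and the recipe fractions are applied
  to that mass.
* **Supervised paste dose** — 0.65 tubes/year is the authoritative demand
  quantity (0.25 g per episode is derived metadata); the doubled-dose
  sensitivity scenario sets 1.3 tubes/year.
* **Disposal as named elementary flows** — end-of-life routes are stated
  (brush and empty tube binned, packaging recycled, excess paste and water
  to the drain) but no treatment inventories are; disposal is therefore
  carried as named flows (`waste_residual`, `waste_recycled`,
  `wastewater`, `paste_to_drain`) that characterization factors can act
  on, rather than as modelled treatment chains.
* **No co-product allocation** — the foreground has no co-products, so
  every amount is attributed fully to the functional unit.

## Matrix-based impact assessment

The computation is the standard linear LCA model. With technology matrix
$A$ (product flows × processes; reference products positive, consumed
product inputs negative), intervention matrix $B$ (elementary flows ×
processes) and functional-unit demand $f$:

$$ A s = f, \qquad g = B s, \qquad h_c = \sum_{\text{flows } f} Q_{c,f}\, g_f $$

where $s$ is the scaling vector, $g$ the life cycle inventory and $Q$ the
characterization table mapping elementary flows into the 16 midpoint
impact categories of the EU Product Environmental Footprint (PEF) scheme
(`default_impact_categories()`; climate change in kg CO₂ eq through
dissipated water in m³ deprivation).

Numerical choices: the systems here are tiny (≲ 50 processes), so
`solve_scaling()` uses a direct dense solve; a reciprocal condition number
below `1e3 * .Machine$double.eps` is rejected as singular. Because the
supply chains are acyclic, the solve must agree with plain iterative demand
expansion; `expansion_oracle()` implements that expansion with no matrix
algebra and the test suite requires agreement within 1e-9 relative on 100
seeded random systems of depth ≤ 3. Characterization is strict by default —
a nonzero inventory flow with no factor row is an error, since completeness
of user-supplied factor tables cannot be assumed — with an explicit lenient
mode that treats such flows as zero and warns.

**Normalization** divides each category score by a per-person-per-year
reference value. The three toxicity-related categories (freshwater
ecotoxicity, cancer and non-cancer effects) are excluded per PEF practice
and are reported as explicitly excluded, never as zero. Real per-capita
reference sets are external data; the shipped default of 1.0 per category
is a synthetic placeholder that keeps the step testable.

**Contribution analysis** (`contribution_by_group()`) attributes impacts
cradle-to-grave: each labelled foreground component (toothbrush,
toothpaste, water, travel, bus/bag) gets the full supply-chain impact of
its share of the functional-unit demand. By linearity the group scores sum
exactly to the total (tested at 1e-9 relative), and removing a component's
demand — e.g. the exclude-water scenario — removes exactly its
contribution. Percent shares are computed on nonnegative scores; if credits
make a group score negative the share is reported as `NA` with a warning
and the absolute scores remain valid.

## Endpoint DALYs

Human-health midpoint scores on eight pathways (global warming,
stratospheric ozone depletion, ionising radiation, particulate matter,
photochemical ozone formation, cancer and non-cancer effects, water
consumption) are converted to disability-adjusted life years by endpoint
damage factors (`endpoint_convert()`), summed (`total_dalys()`), and
scaled to DALY-seconds with a 365-day year (31,536,000 s,
`seconds_per_year()`) — the only year-length constant consistent with both
bundled total↔seconds pairs, which the tests verify. Hierarchist endpoint
factor sets are licensed method data; `default_endpoint_factors()` ships
synthetic order-of-magnitude stand-ins, and the bundled reference breakdown
(`reference_daly_table()`) is consumed as input data. On that breakdown,
global warming plus water consumption carry 99.81% (supervised) and 99.89%
(provision) of the total burden.

## Sensitivity scenarios

`run_scenarios()` re-runs a programme under named parameter overrides
against the same characterization table and background. The shipped sets
mirror the published analysis: supervised — bamboo brushes, doubled paste;
provision — bamboo brushes, paper bags, both, and excluding water use.
Percent changes are always taken **relative to the baseline column**; this
convention reproduces every checkable published integer percentage (15, 68,
28, 23 and 5 for the supervised bamboo swap; 36, 81 and 49 for excluding
water; 6 for the provision bamboo swap). Narrative rounding uses
half-away-from-zero integers (`report_percent()`); unrounded signed values
are always retained. The published 0.47% paper-bag figure is not
reproducible from the rounded table values (it evidently derives from
unrounded internals) and is deliberately not asserted. Likewise the
published contribution averages (e.g. staff travel 28.39%) depend on the
proprietary background database and an unstated travel allocation, and are
treated as context, not targets.

## The synthetic background: what it does and does not show

Real background databases (the upstream inventories of polymer,
electricity, transport, water supply, and the toothpaste ingredients) are
proprietary. `generate_cf_table()` and `generate_background_processes()`
produce structurally faithful stand-ins as pure functions of a seed:
nonnegative characterization factors drawn log-uniform (spanning orders of
magnitude, as real factor tables do, which stresses numerical robustness),
optional sparsity, and acyclic background supply chains of configurable
depth behind each product the foreground consumes. A fixed small elementary
flow vocabulary maps one signature flow to each impact category, keeping
per-category contributions interpretable.

What passing tests on synthetic data show: the algebra (solve, aggregate,
characterize, decompose) is correct, linear, conservative and
deterministic, end to end. What they do not show: real-world score
magnitudes or rankings. In particular, under the default synthetic
background the water component dominates most categories simply because
390–1,460 L of supplied water dwarfs the kilogram-scale material flows —
the published assessment, with real background data, found water
contributing 26% (supervised) to 49% (provision) on average. Absolute
published scores (e.g. 1.95 vs 2.89 kg CO₂ eq for the two programmes) are
bundled as reference input tables for percent-change arithmetic, never
recomputed.

Problem sizes used by the test suite: foreground systems of 5 processes
plus synthetic backgrounds of up to 13 products × depth 3 (≈ 22 processes);
the oracle-equivalence property runs 100 seeded systems; the full pipeline
runs in seconds.

## Known limitations

* Background data are synthetic; any numeric resemblance to real databases
  is coincidental and unintended.
* The toothbrush bill of materials is a placeholder teardown; endpoint
  factors are synthetic defaults.
* At-home brushing resources under the supervised programme are excluded
  (as in the underlying service models), and compliance with twice-daily
  brushing under the provision programme is assumed perfect; both choices
  bound rather than estimate the true footprint.
* No uncertainty propagation over characterization factors and no
  regionalized characterization.
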