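---
title: "The costing model behind seqcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The costing model behind seqcost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcost)
```

## The problem

Broad next-generation-sequencing gene panels for tumor profiling are
expensive to run, and the cost per patient sample depends strongly on how
the laboratory is organized: how many samples share a weekly sequencing
run, which tasks are manual, how instrument capital is spread over
throughput, and how much interpretation and tumor-board time each case
absorbs. seqcost implements a bottom-up (microcosting) model of such a
service: every resource is identified as a line item, measured in natural
units, and valued with a unit cost, then aggregated into a per-sample
step-by-category cost decomposition that can be re-evaluated under
alternative batch sizes and costing assumptions.

## Model structure and assumptions

The workflow is fixed at nine ordered steps (`workflow_steps()`), a
synthesis that spans request handling through data storage and is broad
enough to accommodate related assays. Direct costs fall into four
categories; overhead is never stored but always derived as a flat markup
(default 20%) on each step's direct costs, representing administrative
departments, office supplies and non-laboratory space. Applying the
markup uniformly — including to storage-only steps — is an assumption of
the model, not a computed quantity.

Cost behavior is the model's central mechanism for batch-size effects:

- **variable** items scale proportionally with the batch size $n$;
- **step-fixed** items are consumed in blocks of capacity $c$:
  $\lceil n/c \rceil$ blocks per batch, so their per-sample cost traces a
  sawtooth in $n$: it is guaranteed non-increasing only along batch sizes
  that are common multiples of all block capacities. A per-run resource
  (block capacity equal to the largest supported run, e.g. 24) halves per
  sample when the batch doubles from 12 to 24, while a capacity between
  13 and 23 leaves the per-sample cost unchanged over that move;
- **fixed** items accrue per year and are divided by the yearly
  throughput $N = n \times \text{runs/year}$.

Valuation routes and their formulas, per sample at batch size $n$:

| route | formula | notes |
|---|---|---|
| unit price | $q \cdot u(n) \cdot p \,/\, n$ | $u(n)$ units per batch by behavior; for fixed behavior $q\,p$ is an annual fee (license) |
| personnel | $t \cdot w \cdot u(n) \,/\, n$ | $w$ = salary $\times 1.13 \times 1.25$ / annual hours |
| equipment | $\alpha \, \mathrm{EAC} / N$ | $\mathrm{EAC} = P r / (1 - (1+r)^{-L}) + M$ |
| space | $\alpha \cdot \text{area} \cdot \text{rate} / N$ | internal per-m² rate |
| storage | $g \cdot p_{GB\text{-}yr} \cdot Y$ | full horizon charged to the generating sample |

Two loading conventions deserve comment. The two statutory wage loadings
(13% employer contributions, 25% social security) compound
multiplicatively, $1.13 \times 1.25 = 1.4125$, following Norwegian
unit-cost practice; both rates are per-row fields, so an additive
convention can be emulated by editing them. Equipment maintenance $M$ is
added undiscounted per year rather than annuitized together with the
purchase — maintenance is a recurring operating payment, not capital.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `batch_size` | 12 | samples/run | one weekly run at current capacity |
| `runs_per_year` | 52 | runs/year | weekly operation; the model treats it as configurable rather than hard-coding one year of weeks |
| `overhead_rate` | 0.20 | fraction | hospital internal guideline for non-attributable costs |
| `interest_rate` | 0.04 | fraction/year | capital cost of equipment purchases |
| `nok_per_usd`, `nok_per_eur` | 10.7433, 11.6276 | NOK | fixed 2024 exchange rates; conversion happens only at reporting |
| `estimate` | base | — | deterministic low/base/high switch |
| storage horizon | 10 | years | per-item field `storage_years` |

The `estimate` switch selects the low, base or high **field value** of
every three-point input (working times, equipment lifetimes, data
volumes). Note the semantics for lifetimes: a *low* lifetime value means
faster amortization and therefore a *higher* equipment cost. The switch
is deliberately a plain field selector, not a "pessimistic/optimistic"
relabeling; the bounds express measurement uncertainty, not a worst-case
ordering of costs.

## Numerical choices

All internal arithmetic is unrounded double precision; rounding happens
exactly once, at render time, half-away-from-zero to integer dollars and
percents (`round_half_out()`, deliberately not base R's half-to-even).
A rendered step row is recomputed from unrounded values and then rounded,
so it may differ by ±1 from the sum of its rendered cells — published
costing tables show the same property, and the renderer documents rather
than hides it. The annuity uses the closed-form capital-recovery factor
with an explicit $r = 0$ straight-line branch; the test suite checks the
$r \to 0$ limit at $r = 10^{-8}$ to $10^{-6}$ relative tolerance.
Percent changes between scenarios are computed on unrounded totals.
Scenario step weights multiply the affected steps' **direct** costs, with
overhead following proportionally; under a flat markup this is
numerically identical to weighting overhead-inclusive step totals and is
simpler to audit. Degenerate inputs are defined, not errors: an empty
inventory yields an all-zero matrix with zero shares, and a percent
comparison against a zero base total raises an explicit error rather than
returning infinities.

## The calibrated inventory

`calibrated_inventory()` ships a complete inventory whose computed matrix
at batch size 12 with base estimates reproduces, cell by cell after
rounding, a published step-by-category cost decomposition for a
broad-gene-panel profiling service (grand total $2944 per sample, 20%
overhead, consumables and personnel at 34%/35%). Because printed tables
round internally, the printed cells of such a table need not sum to its
printed totals; the fixture is therefore a *feasibility solution*: each
unrounded cell is placed inside its ±0.5 rounding band such that the
grand total, the overhead total, selected step totals, the category
shares, a step-8 exclusion total and a halved-consumables percent change
all round to their published values simultaneously. Working times,
purchase prices, areas and storage prices are then back-solved from those
cell targets at full precision (`data-raw/build_fixtures.R`, which also
re-verifies every constraint before writing the CSV). The line-item
granularity — how a cell splits into named kits and tasks — is
illustrative; only cell-level sums are calibrated. The calibration is
committed data and is never re-fit at test time.

The step-fixed structure is part of the calibration: the sequencing
reagent kit and the per-run setup and data-analysis tasks use a block
capacity of 24 samples, so they halve per sample when the weekly batch
doubles from 12 to 24, reproducing the published doubled-batch scenario
row (equipment $187 per sample, total change −11%).

An `automated_inventory()` variant (robot as amortized equipment, reduced
engineer hands-on time, block capacity 16) is bundled for demonstrating
workflow-variant scenarios. It is synthetic and deliberately *not*
calibrated: the capital inputs of such a robot are not public, so the
variant shows the mechanics (equipment up, personnel down at equal batch
size) without claiming its totals.

## The synthetic generator and what tests show

`synthetic_inventory(seed, n_items, mix)` draws random inventories from
documented positive ranges with controllable category/behavior mixes. It
emulates the *structure* of real inventories — mixed currencies, shared
allocation weights, three-point bounds, all five valuation routes — but
not their empirical scale relationships (a generated "sequencer" can cost
less than a generated reagent kit). Property tests on it therefore
establish the engine's arithmetic invariants — oracle equivalence against
an independently coded line-by-line summation (500 seeded inventories at
$10^{-9}$ relative), price homogeneity, batch-size invariance of variable
costs, exact halving of fixed costs on doubling, additivity and share
normalization of every matrix — and say nothing about the realism of any
particular cost estimate. Realism claims rest solely on the calibrated
fixture.

Problem sizes used by the default suite: 500 synthetic inventories of 12
items for oracle equivalence, 25 of 18 items for matrix invariants,
sweeps over batch sizes 1–96; the whole suite and the acceptance script
each run in well under a minute on one CPU.

## Open design decisions taken

- **Runs per year = 52.** Annual costs are spread over
  $N = n \times 52$ by default; `runs_per_year` is an explicit parameter
  because real services lose weeks to maintenance and holidays.
- **Storage price is per gigabyte-year.** A price quoted "per gigabyte"
  with a multi-year horizon is ambiguous; the per-GB-year reading makes
  the horizon a real parameter (`storage_years`, default 10) instead of a
  label.
- **Investments amortize over one year of samples** at the effective
  batch size by default (`amortization_samples` overrides). A
  development investment (e.g. months of bioinformatician time spent
  building a pipeline) is a sunk cost; the model includes it as a fixed
  software/storage item contributing exactly
  `total_cost / amortization_samples` per sample before overhead.
- **Scenario composition is sequential and multiplicative.** A −p%
  followed by a +p% adjustment of the same target does not return to
  base; it scales it by $(1-p/100)(1+p/100)$. This keeps scenario
  application associative and order-insensitive within a single spec.
- **Price adjustments scale every monetary field** of the targeted items
  (unit costs, salaries, purchase prices, maintenance, space rates,
  storage prices), so a category-level discount means "this category's
  resources get cheaper", not merely "its consumable unit prices do".

## Known limitations

- Sensitivity is deterministic (low/base/high switches); there is no
  probabilistic sensitivity analysis and no distributional uncertainty.
- Overhead as a flat 20% markup cannot represent overhead that scales
  differently from direct costs (e.g. office space for interpretation
  staff).
- Personnel capacity flags compare weekly hours against configured
  capacities; there is no queueing, scheduling or staffing optimization,
  and extrapolating the cost curves to very large batch sizes ignores the
  reorganization, training and space such scale would require.
- Currency rates are fixed (2024); the model intentionally performs no
  live lookups.
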