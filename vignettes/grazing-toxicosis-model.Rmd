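---
title: "An agent-based model of cattle grazing a larkspur-infested pasture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of cattle grazing a larkspur-infested pasture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Geyer's larkspur (*Delphinium geyeri*) and its relatives contain
norditerpenoid (MSAL-type) alkaloids that are potent neuromuscular toxins in
cattle. Losses of 2–5% per year are reported for herds grazing larkspur
habitat, and producers often abandon or delay grazing of infested pastures.
Field experiments on management strategies are effectively impossible — the
cost of a failed treatment is dead animals — so `graztox` implements a
spatially explicit, behavior-based, individual-level simulation in which
management strategies can be compared without risk. The two management levers
under study are **stocking density** (SD, animal-units per hectare) and
**herd cohesion** (HCF, a 1–10 factor describing how tightly the herd keeps
together), and the outcome of interest is the count of *lethal acute
toxicosis* events: moments at which an individual's alkaloid body burden
exceeds its tolerance.

## Entities, scales and state

The pasture is a grid of 1 m² cells ("feeding stations"), each carrying
current forage mass (g), MSAL alkaloid content (mg), a times-grazed counter,
an accessibility flag (cells beyond the fence line are inaccessible), and
optionally a water flag. A derived layer holds the 3 m disc mean of initial
forage, used when scoring candidate feeding sites.

Cows are 500 kg adults (1.1 animal-units) with a role — **leader** (5%),
**follower** (85%) or **independent** (10%) — a continuous position and
heading, a hydration ledger, and two individual sensitivities drawn once at
creation:

* `msal_tolerance` ~ Normal(4000, 333.33) mg truncated to [3000, 5000]: the
  body burden at which the cow is recorded as a death. The truncation makes
  the stated "virtually all values within 25% of the mean" exact (an
  untruncated normal puts only 99.73% within 3 sigma).
* `larkspur_attraction` ~ Normal(1, 0.083) truncated to [0.75, 1.25]: a
  multiplier on alkaloid intake relative to forage intake, standing in for
  individual preference or avoidance.

A tick is **one patch interaction per cow**, not a unit of time. Time is
counted in grazing-days: a grazing-day passes when herd-mean consumption for
the day reaches 12.5 kg (2.5% of body weight). Run length is measured in
animal-unit-months (AUMs): `aums = grazing_days * n_cows * 1.1 / 30.44`, and
a run stops once the target AUMs are consumed.

## Scheduling (one tick)

Each tick is exactly one of:

1. **Watering trip.** Any leader whose hydration has depleted to zero (tied
   to consumption so it happens twice per grazing-day) sends the whole herd
   to water; each cow takes the nearest water cell with at most two cows
   already on it, hydration refills, and leaders' site patience is set one
   increment below the threshold so a site change follows soon after
   drinking. Nothing is grazed on a watering tick.
2. **Site change.** Each leader compares the mean times-grazed within 10 m
   against the pasture-wide mean: if the local neighborhood is relatively
   overgrazed (`local > 0.5 * global + 1.2`) its `ready_to_go` counter
   increments; at the site-tolerance threshold the leader (the first one in
   that tick's shuffled order) selects a new site — unless its hydration is
   below 20% of capacity, in which case the herd waters instead. Candidate
   sites are scored on a 25 m lattice by summed ranks of low grazing
   pressure, high forage and high neighborhood forage; the nearest of the
   best five becomes the site centre, with radius
   `sqrt(n_cows * space_per_cow / pi)`. Cows relocate in role order
   (leaders, then followers, then independents), each taking the best free
   cell with no cow on it or its four direct neighbors.
3. **Movement and grazing.** Every cow, in freshly shuffled order, either
   *herds up* — if its mean distance to its 20 nearest herdmates exceeds the
   herd distance, it moves to the max-forage cell 10–25 m toward the
   herdmate centroid within a ±45° cone — or makes an *environmental* move:
   to the max-forage cell within 2 m (ahead, ±45° of heading) while the
   10 m neighborhood is relatively ungrazed (mean times-grazed < 0.5), or
   within 10 m once it is. Independents only herd up beyond 2.5x the herd
   distance and are repelled inside 0.5x. The cow then eats its destination
   cell: 40% of available forage on the cell's first grazing, 50% of the
   remainder on the second, 60% thereafter, with alkaloid removed at the
   same fraction times the cow's attraction (capped at the cell content).

At the end of each grazing-day every cow's burden is compared with its
tolerance — an exceedance is recorded as a death, the burden reset to zero,
and the cow continues (removing it would alter herd function; the count is a
risk measure, not a population model) — and all burdens are halved: alkaloid
is eliminated with a half-life of one grazing-day, so under zero intake a
burden follows `L * 0.5^d` exactly.

## The herd-cohesion factor

HCF is mapped geometrically onto the two stated behavioral ranges, pinned at
the published endpoints:

* desired herdmate distance: `100 * 10^-((hcf - 1) / 9)` m (100 m at HCF 1,
  10 m at HCF 10);
* space per cow at a new site: `1000 * 100^-((hcf - 1) / 9)` m² (1000 down
  to 10 m²).

A geometric interpolation is the only monotone two-point fit that keeps the
relative step constant across the 1–10 scale; the source material states
only the endpoints. Herd size is `round(sd * accessible_ha / 1.1)` — the
divisor makes a 258.82 ha pasture at SD 0.5 carry 118 cows, consistent with
the published cross-check that 2.8 mean deaths is 2.4% of the herd.

## The synthetic landscape generator

The study pasture's remotely sensed layers are not distributable, so the
package generates landscapes that emulate their statistics:

* **Productivity index**: Gaussian white noise smoothed to a correlation
  length (default 16 m) and min-max normalized. The index drives both
  forage and larkspur mass, which is what couples foraging desirability to
  toxin exposure — larkspur grows most densely in productive ground, which
  is exactly where cattle want to graze.
* **Forage**: `m * 3^(2u - 1)` for index `u`, rescaled so accessible cells
  average `kgs_per_hectare / 10` g; where the index attains 0 and 1 the
  poorest cells hold one third of the mean and the richest three times it.
* **Larkspur**: a Poisson-cluster (Neyman–Scott style) process. Patch
  centres (default 0.5 ha⁻¹, sampled with probability proportional to the
  index) seed discs of radius 18 m in which cells draw
  Poisson(4) plants·m⁻²; background cells draw Poisson(0.02). Per-plant
  mass is `median_mass * (0.5 + u)` — 50% above the median in the most
  productive ground, 50% below in the least — and cell MSAL content is
  `count * mass * concentration` (defaults 3.5 g and 3.0 mg/g, an excellent
  growing year at bud stage, the most dangerous realistic conditions).
* **Water**: a lateral random-walk stream, broken into intermittent
  segments (the stream the pasture is modeled on runs partly below ground);
  at least one water cell is always retained.

Patch geometry was calibrated, once, against the published output
statistics rather than chosen from first principles: patch area coverage of
roughly 5% of the pasture reproduces a mean individual daily alkaloid intake
near 530–550 mg under the default inputs, and 18 m patches are comparable in
area to a cow's daily feeding footprint (~600 cells), which is the scale
required for the rare single-day intake excursions that drive lethal acute
toxicosis. Smaller patches at higher intensity match the mean intake but
make lethal days impossible, which contradicts the observed mortality. A
16 ha desk-scale landscape carries a Poisson(8) number of patches, so
individual landscape draws vary considerably in total alkaloid; analyses in
the package's tests and acceptance script therefore fix one typical-draw
landscape (seed 12, whose realized patch coverage is closest to the process
expectation) as "the study pasture", mirroring the fixed real pasture it
stands in for.

What the generator does **not** emulate: real topography and slope response,
distance-to-water gradients in forage quality, plant phenology and regrowth
(clipped larkspur at bud stage regrows negligibly; forage regrowth within a
single semi-arid grazing period is small), multiple or developed water
sources, and the mapped spatial layout of any actual pasture. Passing tests
on synthetic landscapes show the behavioral and toxicokinetic machinery is
correct and that the management gradients are directionally right at desk
scale; they do not reproduce pasture-specific absolute death counts.

## Calibrated behavioral bounds

Two quantities the source description leaves open are set by calibration to
published output verification statistics and then frozen:

* **Site tolerance** (leader patience): `max(2, ceiling(n_cows / 25))`.
  Together with the 16 m index correlation length this puts mean site
  changes per day in the observed 2.3–6.0 band, increasing from the loose,
  sparse corner to the cohesive, dense corner.
* **Satiation**: a cow that has eaten 102.5% of the 12.5 kg daily
  requirement stops grazing (it keeps moving with the herd) until the next
  grazing-day. Voluntary dry-matter intake in cattle is bounded near 2.5–3%
  of body weight, and without some bound individual daily totals range far
  outside the tight observed band (2.34–2.66% of body weight): the
  grazing-day is defined by the *herd mean*, so without satiation a cow
  camped on rich, fresh cells can bank 3–4% while a laggard in ground-down
  terrain records under 2%. The 2.5% level of the cap follows from a
  worst-case bound: when the day closes at herd mean 12.5 kg, the laggard
  holds at least `n * 12.5 - (n - 1) * cap` kg, which stays above 2% of body
  weight for the herd sizes of interest only when the cap is within ~2.6% of
  the requirement.

## Numerical choices

* Distances are Euclidean between cell centres (cells indexed half-open from
  0, centres at half-integers); neighborhood "discs" are the integer-offset
  cells whose centre distance is within the radius (5 cells at radius 1 m,
  29 at 3 m), truncated at the grid edge.
* Movement tie-breaks are deterministic: max forage, then nearest, then
  lowest cell index. On continuous synthetic forage fields exact ties are
  measure-zero; determinism keeps every trajectory reproducible and
  oracle-checkable.
* Empty movement cones widen from ±45° to ±90° and then to the full circle
  before any fallback, so cows cannot stall against fences.
* Candidate-site neighborhoods are square windows (side twice the site
  radius) evaluated with summed-area tables, O(1) per candidate; the
  enumeration of "available sites" is otherwise unspecified and a 25 m
  lattice keeps the search linear in pasture area.
* All randomness (herd draws, initial placement, per-tick update order,
  stream layout, plant counts) flows from R's RNG, so `set.seed`-derived
  seeds make whole experiments bit-reproducible; factorial designs derive a
  per-run seed by hashing the base seed with the factor levels and
  replicate index, so any single run can be reproduced in isolation.
* Mass balance is maintained exactly by construction (grazing is the only
  mutation of the grids); `audit_every` recomputes the forage and alkaloid
  ledgers against the grids on demand and reports the worst relative error
  (observed ~1e-14, i.e. floating-point accumulation only).
* A run on a pasture that cannot feed the herd ends with status
  `forage_exhausted` after a sustained stretch (5000 consecutive ticks) of
  near-zero herd intake; a single near-zero tick is normal late in a day
  when only sated cows remain near the laggard.

## The analysis layer

Death counts across a factorial experiment are overdispersed, so the
reference model is a negative-binomial GLM with log link (`fit_count_glm`),
compared against a Poisson GLM by corrected AIC. Conventions that matter for
cross-package comparison:

* the NB dispersion parameter is counted as an estimated parameter in `k`,
  so AIC/AICc match the convention of the standard NB fitting routine and
  differ by 2 from software that omits it;
* `AICc = AIC + 2k(k + 1) / (n - k - 1)`;
* `percent_change(b) = 100 * (1 - exp(b))` reports a log-link coefficient as
  the percent *decrease* in expected deaths per unit predictor;
* standardized betas z-score the predictors (population SD) and refit the
  main-effects model, per the source tables' footnotes; their ratios give
  relative influence;
* `single_factor_scan` fits one NB model per candidate mechanism and
  reports AICc, the coefficient, type-7 (linear interpolation) quartiles,
  and the observed percent change in mean deaths between the bottom
  (mechanism ≤ Q1) and top (mechanism ≥ Q3) quartile groups — the grouping
  rule behind the published quartile contrast is not stated, and this
  reconstruction is the natural reading;
* mechanism regressions (`fit_mechanism_ols`) are ordinary least squares
  with optional interaction, adjusted R², and betas from the
  no-interaction refit.

## Problem sizes used in tests

The full published experiment is 480 runs on a 262 ha landscape. The
package's test suite and acceptance script run the same machinery at desk
scale, chosen so the whole suite completes in minutes: a 400 x 400 cell
(16 ha) pasture, the four corners of the factorial
(HCF {1, 10} x SD {0.25, 2}) with 10 replicate seeds, and an area-scaled
stopping target of 9.3 AUMs (the equivalent of the published ~150 AUM
seasonal use, removing ~41% of forage). Full-size landscapes
(1663 x 1580 cells) are supported by the same code paths.

## Known limitations

* Daily alkaloid elimination as a single half-life is a deliberate
  simplification; continuous toxicokinetic models exist only for controlled
  dosing on stored feeds and would add parameters without adding realism
  here.
* Deaths do not remove cows, so death counts are exposure-risk counts, not
  demographic projections.
* Desk-scale landscapes make rare-event counts (deaths per run) more
  variable and, cell-for-cell, more dangerous than the full-size pasture;
  corner contrasts and mechanism directions are the meaningful desk-scale
  outputs, absolute death rates are not.
* Slope, resting, dominance interactions and regrowth are intentionally out
  of scope (parsimony: they contribute little to larkspur intake in the
  modeled setting).
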