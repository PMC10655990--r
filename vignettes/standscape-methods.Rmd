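---
title: "Methods: stand-resolution simulation of clear-cut forest landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stand-resolution simulation of clear-cut forest landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standscape)
```

## The model

`standscape` simulates a forest landscape at the resolution of individual
stands — relatively homogeneous forest units subject to a single
management decision — with one calendar year per iteration. The only
disturbance modelled is clear-cut harvesting with retention trees; growth
is represented as deterministic aging of the layered species composition.
This design targets intensively managed, even-aged (clear-cutting based)
silvicultural systems, where harvest entries dominate mid-term landscape
change and much of the apparent stochasticity is constrained by the
patchwork of previous cuts.

Each clear-cut is the conjunction of two questions:

1. **Willingness** — does the owner want to harvest this year? Private
   decisions are made per cadastral unit (an ownership parcel of one or
   more stands). Every stand gets an age-adjusted yearly cutting
   probability

   $$p_i = \begin{cases} 0 & t_i < 0 \\
   \min\!\big(1,\; b_i\,(1 + t_i/h)\big) & t_i \ge 0,\end{cases}$$

   where $b_i$ is the base probability from the unit's management
   intensity (and the capped class A/B overrides), $t_i$ the years past
   the stand's minimum felling age, and $h = 20$ years the doubling
   horizon. The unit applies for a permit with probability equal to the
   equal-weight mean of the nonzero $p_i$ (immature, unregistered and
   strictly protected stands are omitted); a successful draw applies for
   *all* eligible stands of the unit.

2. **Allowance** — is the cut legal? Stands carry one of six management
   types derived from restriction zone and site type in a fixed priority
   order (strict protection → alvar sites → limited-management classes
   A/B → waterbody restriction → bog sites → general). General and bog
   management compare the *total connected cutover* — the candidate plus
   every connected stand younger than 6 years, found by flood-fill over
   the fixed adjacency graph — against an area limit (7 ha and 5 ha),
   with an exemption for single stands larger than the limit on their
   own. Alvar and riparian management use a 2 ha limit and cut larger
   stands in two steps. Limited management permits a cut only when no
   neighbouring stand was clear-cut within the preceding five years.

Because one executed cut changes the allowance of its neighbours (and of
their neighbours, through connected young stands), permitting is strictly
sequential within a year: alvar, riparian, limited, bog, then general
stands; applying units in seeded random order within each pass; the
largest stand first within a unit. State forests are handled separately:
eligible state stands (10 years past maturity, or 20 for stands within
1 km of settlements, where public interest is heightened) are grouped
into 1-km-radius clusters, the largest cluster harvested first, through
the same per-stand permits, until a yearly area quota is met.

After a cut the stand age is reset to 0 and the composition is retained,
except that with probability 0.05 the regeneration mode flips between
planted and natural and the composition is copied from a stored similar
stand of the target mode. A stand counts as a clear-cut while younger
than 6 years.

## Parameters

All tunables live in `default_harvest_params()` and the scenario presets
of `build_scenario()`. The yearly base cutting probabilities (intensive
0.385, non-intensive 0.055, state 1, class A 0.2 / B 0.1 capped by the
unit base, state A/B 0.05) are calibrated such that, without harvest
constraints, about 80% of intensively managed stands are cut within 3
years of maturation and about 95% within 6, while non-intensively managed
stands reach the same coverage in 18 and 30 years. `time_to_cut_cdf()`
gives the closed form behind this calibration,
$1 - \prod_{t=0}^{n-1}\big(1 - \min(1, b(1+t/20))\big)$, and
`simulate_time_to_cut()` the Monte-Carlo counterpart:

```{r calibration}
round(100 * c(int_3y = time_to_cut_cdf(0.385, 3),
              int_6y = time_to_cut_cdf(0.385, 6),
              nonint_18y = time_to_cut_cdf(0.055, 18),
              nonint_30y = time_to_cut_cdf(0.055, 30)), 1)
```

Six scenario presets span the policy space: `DEFa`/`DEFb` (status quo,
differing only in whether clear-cuts missed by outdated canopy scans are
simulated into the starting state; the `a` variants also use the
uncorrected probabilities 0.35/0.05), `MODa`/`MODb` (adding a yearly 2.8%
conversion of eligible non-intensive units to intensive management),
`GOV` (all area limits enlarged by exactly 20%), and `REAL` (conversion
plus a linear market-pressure ramp of the non-intensive base probability
to 0.13 by 2050). All scenarios complete the land reform: the initially
unregistered stands become harvestable linearly so that everything is
registered by the final year.

### The worked example

`worked_example_landscape()` ships a four-stand unit for tracing the
arithmetic by hand: a strictly protected stand (probability 0), a
limited-management class A stand 30 years past maturity, an immature
stand (probability 0), and an unrestricted stand 20 years past maturity
(0.385 doubled to 0.77). Under the default rule the class A stand
adjusts 0.2 → 0.5; the example as published alongside this model family
instead shows 0.3, which corresponds to a gentler adjustment (a 60-year
doubling horizon) for limited-management stands. The adjustment rule as
stated is the default; `limited_doubling_horizon = 60` reproduces the
example:

```{r worked}
W <- worked_example_landscape()
unit_application_probability(W, 1)  # stated rule
unit_application_probability(W, 1, build_scenario("REAL", limited_doubling_horizon = 60))
```

## The synthetic generator

`generate_landscape()` emulates the statistical structure of the
hemiboreal Estonian forest estate at desk scale: mean stand area 1.15 ha,
12.9% strictly protected and 12.3% restricted-management area (split
between waterbody restriction and classes A/B in their observed 5.1:6.8
proportion), alvar and bog site prevalences of 2.0% and 13.6%, and 10%
unregistered land. Values the source system does not pin down were chosen
once as field-realistic and are documented here: half of the cadastral
units state-owned, 30% of private units company-owned, intensity priors
0.95 (juridical) and 0.35 (physical), a piecewise-uniform age
distribution mixing a recent clear-cut cohort with mid-aged and old
forest, and sparse settlements (0.05 per km²).

The tessellation is a perturbed rectangular grid rather than a Voronoi
diagram: it is trivially planar, areas are controlled exactly (stand
areas sum to the extent), and the rectangle geometry gives closed-form
edge and grid-overlap computations for the metrics. Cadastral units are
grown by contiguous breadth-first search; zones, site types and
unregistered land are spatially clustered blobs hitting their target
fractions; each stand stores its nearest natural and planted same-site
stand as regeneration-transition references.

What the generator does **not** emulate: real geography and soils,
species spatial autocorrelation beyond blob clustering, diameter-based
felling allowances, growth and yield volumes, or mortality (hooks exist
but default to zero). Tests passing on synthetic landscapes therefore
demonstrate the decision, permitting and metric machinery — not
predictive skill on any real registry.

## Registry refresh

Real stand registries lag reality because owners delay re-inventory
until the next cutting plan. The package mirrors a two-part refresh:
`detect_clearcut()` flags stands whose canopy-height percentiles
contradict their recorded state — the median below half of both the 90th
percentile and the expected height, or a very uneven height distribution
(relative spread above 0.7; this second threshold is a package choice and
deliberately excluded from any reference check) — and
`simulate_missing_clearcuts()` extrapolates the linear trend of
additional clear-cut rates by scan year (8.4% / 7.6% / 6.8% for scans
one, two and three years old) to the target date, flagging the implied
number of eligible stands per scan region as cut before the first
simulated year. These pre-simulation cuts are initial conditions: they
are logged to the preceding calendar year and bypass permitting, exactly
as cuts that already happened on the ground do.
`impute_missing_composition()` fills composition-less stands from the
nearest same-site donor, drawing artificial regeneration with
probability 0.2; donor component ages are copied with the composition.

## Output metrics

Four indicator families: age-class area composition (optionally by
pooled zone, management type or ownership); patches — connected
components of the adjacency graph restricted to an age predicate
(younger than 20; 80 or older; 100 or older) — with their size
distributions; edge area, the part of a patch within 30 m of open land
or stands up to 20 years old, computed exactly by rectangle erosion; and
incidence-function (Hanski) connectivity
$\sum_{j \ne i} e^{-a d_{ij}} S_j^{b}$ with $a = b = 0.5$, distances in
km edge-to-edge under a circular-patch approximation, neighbours within
10 km, aggregated on a 10 × 10 km grid. Both a "weighted mean" and a
"weighted sum" cell aggregation are exposed; the area-weighted mean is
the default, since the two phrasings coexist in the literature this
model family reports against and the mean is the one attached to the
mapped index.

## Numerical and design choices

* **Ages.** Component ages are integers; the stand age is the
  share-weighted mean, so mixed stands age fractionally. Share sums
  carry floating-point drift of order $10^{-16}$, which would let a
  stand exactly 6 years after a cut fall on either side of the
  clear-cut threshold; weighted ages within $10^{-9}$ of an integer are
  therefore snapped to it.
* **Quiet period.** "No neighbouring stand clear-cut in the last 5
  years" blocks a limited-management cut when any neighbour was cut 0-4
  years ago; a cut exactly five years back no longer blocks. Note the
  neighbour may then still count as a clear-cut (threshold 6) for the
  area rules of other management types.
* **Two-step cuts.** An over-limit alvar/riparian stand is split into a
  harvested child of `min(limit, area/2)` and a residual child;
  children inherit the parent's neighbours, are adjacent to each other,
  and the parent rectangle is split along its longer side so geometry
  stays exact. The residual is eligible only once the harvested child
  no longer counts as a clear-cut and its own permit passes.
* **Mixed-composition maturity.** The statutory minimum felling age is a
  species × productivity matrix; for mixed stands the package uses the
  share-weighted mean of the per-species entries. The shipped
  `default_maturity_table()` is explicitly non-normative (pine
  90/100/110, spruce 80/90/100, birch 60/70/80, aspen 40/50/60 by
  descending productivity); statutory values can be supplied as CSV.
* **State clusters.** Cluster membership uses centroid-to-centroid
  1,000 m distance and requires willingness and eligibility; state cuts
  pass through the same per-stand permits as private ones (a uniform
  reading of "is it allowed?"), and the quota stop may overshoot by at
  most one stand. At desk scale the yearly state quota
  (120,000,000 m²) is far larger than any synthetic landscape, so it is
  effectively non-binding in the examples and tests.
* **Adjacency guarantee.** The sequential permit guarantees that
  *immediately after* each executed general/bog cut, the connected
  cutover containing it respects that cut's own type limit (or is that
  single oversized stand). A cluster may later grow past a *smaller*
  member's limit through cuts permitted under a larger limit — mixed
  management types share clusters — so the invariant is checked per
  executed cut in cut order, not against year-end clusters.
* **Intensity assignment.** Redrawing the unit intensities per replicate
  seed is a dominant source of between-run variation and is on by
  default in `run_scenario()`.
* **Problem sizes.** The shipped test-suite exercises the full pipeline
  on landscapes of 100 to 10,000 stands, 29-year horizons and up to 50
  replicate landscapes for the adjacency guarantee, with Monte-Carlo
  checks at $10^4$–$10^5$ draws; these sizes keep every stochastic
  tolerance at three-or-more standard errors.

## Limitations

Volume, revenue and salvage logging are out of scope; species dynamics
beyond the 1%-per-year second-layer transfer are not modelled; protection
zoning is static; and the state-forest policy is a single rule set. The
REAL scenario's conversion and market-pressure assumptions are linear
stylisations. All reported numbers in the package documentation are
computed by the package itself (see `scripts/acceptance.R` and the test
suite); none are transcribed claims about any real landscape.
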