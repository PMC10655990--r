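# standscape

Stand-resolution simulation of clear-cut forest landscapes.

`standscape` is an R package for projecting how an intensively managed,
even-aged forest landscape develops over decades when the dominant
disturbance is clear-cut harvesting under legal and ownership
constraints. It is aimed at landscape ecologists and forest-policy
analysts who need whole-landscape, stand-level projections — age
structure, clear-cut placement, old-forest connectivity — under
alternative socioeconomic scenarios, and at modellers who want a fully
testable, synthetic-data-driven harness for adjacency-constrained
harvest scheduling.

## The model in brief

One iteration is one year. A clear-cut happens in a stand when two
questions are answered positively:

* **Does the owner want to harvest?** Every stand carries an
  age-adjusted yearly cutting probability
  `p = min(1, b (1 + t/20))` for `t ≥ 0` years past its minimum felling
  age (`p = 0` before), with the base `b` set by the cadastral unit's
  management intensity (0.385 intensive, 0.055 non-intensive) or the
  capped restriction-class overrides. A private unit applies for a
  permit with probability equal to the mean of its stands' nonzero
  `p`; on success it applies for all eligible stands.
* **Is it allowed?** Management types (general, bog, alvar, riparian,
  limited, no-management) are derived from protection zoning and site
  type in priority order. General/bog cuts must keep the connected
  cutover — candidate plus all adjacent stands younger than 6 years,
  transitively — within 7/5 ha (single oversized stands exempt);
  alvar/riparian cuts are limited to 2 ha with larger stands cut in two
  steps; limited management requires no neighbour cut in the last five
  years. Permitting is sequential: each executed cut constrains the
  next. State forests are harvested by largest-first 1-km clusters of
  stands well past maturity, under a yearly quota, through the same
  permits.

Landscape outputs are the standard indicator families: age-class
composition, patch size distributions, 30-m edge proportions, and the
incidence-function (Hanski) connectivity `Σ exp(-a d) S^b`
(`a = b = 0.5`, edge-to-edge km, circular-patch approximation) on a
10-km grid.

No real forest registry ships with the package; `generate_landscape()`
builds seeded synthetic landscapes with the statistical structure of the
target system (zoning fractions, site prevalences, ownership mix,
multi-stand cadastral units, rectangle geometry), so everything is
reproducible and testable at desk scale.

## Worked example

```r
library(standscape)

# a 1,000-stand synthetic landscape, fixed seed
L <- generate_landscape(synth_params(n_stands = 1000, seed = 7))
L
#> <landscape> year 2022 - 1000 stands, 395 cadastral units
#>   total area: 1,150 ha
#>   zones: classA=40 classB=42 strict=129 unrestricted=748 waterbody=41

# the four-stand permit-application example, traceable by hand:
# adjusted stand probabilities 0.5, 0, 0.77, 0 under the default rule
unit_application_probability(worked_example_landscape(), 1)
#> [1] 0.635
age_adjusted_probability(0.385, 20)   # base doubled at the horizon
#> [1] 0.77

# three replicate 29-year runs of the REAL scenario
r <- run_scenario(L, build_scenario("REAL"), seeds = 1:3)
glance(r)
#> # A tibble: 5 × 5
#>   metric        median      min      max    range
#> ...  (final-year across-seed summaries: cut area, n cuts,
#>       share_young, share_old80, share_old100)
autoplot(r)   # median + min-max ribbon per metric

# landscape metrics at the end state
rf <- run_scenario(L, build_scenario("REAL"), seeds = 1, keep_final = TRUE)
end <- rf$final_states[["1"]]
old <- patch_connectivity(build_patches(end, c(80, Inf)))
head(grid_connectivity(end, old, cell_size = 2000))
```

`unit_application_probability()` returns 0.635 here because the stated
doubling rule adjusts the class A stand's base 0.2 to 0.5; with the
gentler limited-management adjustment
(`build_scenario("REAL", limited_doubling_horizon = 60)`) the same unit
gives 0.535 — see the methods vignette for why both are exposed. The
`glance()` ranges are characteristically narrow: most run-to-run
variation comes from the random assignment of management intensity to
private units.

A thin command-line front end is included:

```sh
Rscript inst/cli/standscape.R generate --seed 3 --out lnd
Rscript inst/cli/standscape.R simulate --landscape lnd --scenario REAL \
    --years 29 --seeds 1,2,3 --out run1
Rscript inst/cli/standscape.R report --run run1
```

## Package layout

* `R/landscape.R` — the landscape container, validation, management-type
  assignment, CSV I/O
* `R/synthgen.R` — seeded synthetic landscapes and canopy-height fixtures
* `R/succession.R` — aging, second-layer dynamics, maturity ages
* `R/harvest.R` — willingness, permits, two-step cuts, state harvest,
  the annual iteration and multi-seed scenario driver
* `R/scenario.R` — scenario presets and socioeconomic drivers
* `R/registry.R` — clear-cut detection, missed-cut extrapolation,
  composition imputation
* `R/metrics.R` — age classes, patches, edges, connectivity
* `vignettes/standscape-methods.Rmd` — the full model description,
  assumptions and design choices
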