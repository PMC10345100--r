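# fairphen

FAIRification and integration of multi-environment plant phenotyping
data, for data stewards and quantitative breeders who need to make
legacy field-trial data reusable — and to re-enact the reuse itself.

Multi-environment trials (the same genotypes grown across locations and
years) only become analyzable after a chain of integration steps:
discover the relevant dataset, read its study metadata, verify the
trials share genotypes, find weather data matching each site and
season, aggregate a trait per genotype per environment, and put trait
performance on a common environmental axis. `fairphen` implements that
chain end to end around three pieces of machinery:

* **A MIAPPE 1.1 model with validation.** Investigations, studies,
  persons, data-file links, biological materials, observed variables,
  environment parameters, events (dates mandatory — an undated
  occurrence belongs in the experimental factors), and observation
  units at the `block` / `plot` / `plant` / `genotype` levels.
  `validate_investigation()` reports every structural defect
  deterministically: unresolved references, duplicate ids, date-less
  events, out-of-range coordinates, tokens outside a declared
  categorical scale, and more.
* **Lossless RDF and a FAIR Data Point.** PPEO-style graphs for
  phenotyping (meta)data, AEMET-style graphs for daily weather, a
  deterministic Turtle writer/parser, and a four-level FDP hierarchy
  (root → catalog → dataset → distribution) whose dataset documents
  embed a MIAPPE summary — enough content metadata to pick the right
  dataset without opening any distribution.
* **The integration milestones.** Study summaries; genotype overlap
  (set intersection after synonym resolution); nearest-weather-station
  matching by squared coordinate differences,
  `(Δlat)² + (Δlon)²`; per-genotype trait means, "averaged by plant",
  with union and complete-case restrictions; cumulative photo-beta
  thermal time, the daily product `f_photo(P) · f_beta(T)` of a clipped
  photoperiod multiplier and the beta temperature response
  (0 at `t_base` = 5.5 °C and `t_ceil` = 34.6 °C, maximal at
  `t_opt` = 23.4 °C) summed over each study window; and per-genotype
  stability lines from worst to best environment on the PBTT axis,
  classified rising / falling / flat.

Every milestone runs identically over three source kinds — in-memory
model objects, serialized Turtle graphs, or a SPARQL engine loaded with
those graphs — and the test suite holds the three routes to identical
results on 100 seeded fixtures.

Because the original five-trial potato archive cannot be bundled, a
seeded generator produces a deposit-shaped synthetic emulation (5
studies, one recorded only as per-genotype averages, 292 genotypes with
101 common to all trials, one weather station per site) together with a
ground-truth ledger computed by independent plain loops, so the whole
pipeline is testable offline.

## Worked example

```r
library(fairphen)

# a deposit-shaped synthetic scenario, written in the interchange formats
fx <- generate_fixture(fixture_spec(seed = 1), dir = "deposit")
fx$investigation
#> MIAPPE 1.1 investigation 'CxE_potato_trials': Multi-environment potato trials of the CxE population
#>   5 studies, 2 persons, 292 materials, 3 variables, 5 data files
#>   study 1999NL (NL): 2125 observation units
#>   study 2003VE (VE): 189 observation units
#>   study 2004Fin (FI): 2070 observation units
#>   study 2005Fin (FI): 2180 observation units
#>   study 2010ET (ET): 2147 observation units

res <- run_milestones(source_model(fx$investigation, fx$records),
                      source_weather_model(fx$stations, fx$weather),
                      "tubweight", out_dir = "reports")
res$counts
#>     datasets_discovered                 studies        common_genotypes
#>                       0                       5                     101
#>                stations   union_trait_genotypes complete_case_genotypes
#>                       5                     292                      80
#>        stability_rising       stability_falling          stability_flat
#>                      45                     188                      59

res$pbtt
#>   study_id  pbtt
#> 1   1999NL 71.15
#> 2   2003VE 53.31
#> 3  2004Fin 50.09
#> 4  2005Fin 46.69
#> 5   2010ET 65.33

head(res$stability[, c("genotype_id", "study_low", "study_high", "spread", "direction")], 3)
#>   genotype_id study_low study_high spread direction
#> 1       CE001   2004Fin     2010ET 324.21    rising
#> 2       CE002    1999NL     2010ET 377.12   falling
#> 3       CE003    1999NL     2010ET 407.50   falling
```

Reading the numbers: the five trials share 101 genotypes; 292 distinct
genotypes carry at least one tuber-weight value somewhere and 80 carry
one in *every* trial, so a complete-cases multi-environment comparison
is possible for those 80. Each trial's cumulative PBTT (unitless index
per day, summed over the trial window) places it on the long-day/warm
versus short-day/cool axis; `CE001`'s line rises (it performed worst in
the lowest-PBTT environment it appeared in), and the `spread` column
(grams per plant) is the stability indicator — larger spread, less
stable.

The same milestones run over serialized graphs
(`source_graph(...)` after `investigation_to_graph()` /
`observations_to_graph()` / `weather_to_graph()`) or over Turtle files
through a SPARQL engine (`source_sparql(...)`), and
`cmd_fdp()` / `cmd_fdp_crawl()` / `discover_datasets()` re-enact
discovery from the FDP documents alone. A thin command-line wrapper with
`simulate`, `validate`, `convert`, `fdp` and `milestones` subcommands is
installed at `inst/cli/fairphen.R`.

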