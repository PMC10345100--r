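---
title: "FAIRifying multi-environment phenotyping data: models and methods"
author: "fairphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAIRifying multi-environment phenotyping data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairphen)
```

## The problem

Multi-environment plant trials — the same genotypes grown at several
locations and years — are the raw material for genotype-by-environment
analysis, but the data usually arrives as heterogeneous spreadsheets
assembled by different hands over a decade. Reusing it means answering a
fixed sequence of questions: which datasets exist and are relevant? What
were the studies (where, when)? Do the trials share genotypes? Is there
weather data matching each site and season? What did each genotype do in
each environment? And how does performance relate to an environmental
axis combining temperature and day length?

`fairphen` makes that workflow executable end to end. It models trial
metadata on the MIAPPE 1.1 checklist, holds measurements as sparse
observation records, serializes everything to RDF (a PPEO-style
vocabulary for phenotyping, an AEMET-style vocabulary for weather),
publishes metadata as a FAIR Data Point (FDP) hierarchy with MIAPPE
summaries embedded at the dataset level, and implements the six reuse
milestones so they can be run over in-memory objects, serialized graphs,
or a SPARQL engine — with identical results.

The worked scenario is a five-trial diploid potato dataset: partially
overlapping subsets of a backcross mapping population (the CxE cross)
phenotyped in the Netherlands, Venezuela, Finland (twice) and Ethiopia,
with daily temperature and photoperiod per site.

## The metadata model and its validation rules

An investigation owns studies, persons, data-file links, biological
materials (genotypes) and observed variables; each study owns
environment parameters, experimental factors, events, and observation
units. Two modelling rules deserve comment because they come straight
from the pain points of harmonizing legacy trial data:

* **Events must be dated.** An occurrence without a date (a fertilizer
  amount with no application date, say) is real information but not an
  event; it belongs in the experimental-factor section. Constructing a
  date-less event is a validation *error*, not a warning, because a
  date-less "event" silently poisons any later temporal join.
* **Categorical scales are closed.** A variable whose scale declares
  categories (a 0–7 flowering score) rejects tokens outside that set —
  undocumented dots and asterisks are the classic corruption in scored
  traits. A `permissive_tokens` flag downgrades this to a warning for
  exploratory loading.

All other rules are structural: unique identifiers, resolvable
references (record → unit → material, data file → study), coordinate
ranges, date ordering, and coarser-to-finer unit nesting
(block → plot → plant). `validate_investigation()` reports every
violation deterministically, ordered by `(code, object_id)`; nothing is
raised, so one pass yields the complete defect list.

Dates are ISO 8601 strings throughout. Year-only partial dates are
accepted in metadata with a warning, since under-documented older trials
often know only the year. A missing study end date is allowed and
interpreted as "still open": thermal-time windows then run to the last
day the matched station reports.

Genotype identity is the biological-material id *after synonym
resolution*: trials relayed through several groups carry name-translation
lists, which the model stores as synonyms mapping onto one canonical id.
The pre-averaged trial (deposited only as per-genotype means) uses
observation units of level `"genotype"`; those records pass through
trait aggregation as cell values with an unknown contributing count,
treated as weight-1 means — the deposit does not say how many plants
were averaged, and the model deliberately stores no invented weight.

## Interchange formats

The MIAPPE workbook is read and written as a directory of per-section
TSV files, one file per checklist tab (all eleven sections, including an
empty Sample placeholder). This is the plain-text form of the
spreadsheet layout: it round-trips exactly, diffs cleanly, and needs no
binary format support. Observation tables follow the sparse convention:
`observation_unit_id`, `date`, then one column per observed-variable id;
every non-empty cell is one record and empty cells produce nothing, so a
time series measured on few plants stays small. Parsers are
locale-independent (tab separator, decimal point, UTF-8), the
missing-value token list is configurable (`""`, `"NA"`, `"-"` by
default), and a duplicate measurement of the same (unit, date, variable)
with a different value is an error by default — ambiguity of exactly
this kind is what makes legacy files unreusable — with explicit
`"last"`/`"first"` overrides.

## RDF serialization

Both metadata and data are serialized losslessly to subject–predicate–
object statements. The shapes are fixed; the term IRIs are configuration
(`ppeo_vocabulary()`, `aemet_vocabulary()`), defaulting to a PPEO-style
namespace covering exactly the MIAPPE subset modelled here and an
AEMET-style station/property/timestamped-value shape for weather. Every
node receives a minted URI (`base/{type-tag}/{percent-encoded id}`;
injective by construction, verified by property test) — no blank nodes,
because harvesting and cross-document references need stable names.

Turtle output is restricted to one statement per line with sorted order,
so serialization is deterministic and byte-stable; the parser accepts
the usual conveniences (`@prefix`, prefixed names, `a`, `;`/`,`
continuations, language tags). The test suite additionally feeds emitted
files to an independent RDF engine (python's rdflib) and compares
statement counts, so "valid Turtle" is not self-certified.

## The FAIR Data Point layer

The FDP tree has four levels — root, catalog, dataset, distribution —
each emitted as an independent Turtle document linking both its parent
and its children, so agents can navigate in either direction without any
index. Generic per-level metadata uses DCAT2-compatible predicates
(title, description, theme, license, dataset/distribution links, access
URL, media type), chosen so that harvesters unaware of MIAPPE degrade
gracefully.

The package's central extension is dataset-level embedding of a MIAPPE
*summary*: investigation id/title/description, per-study id, title,
country and dates, the observed-variable list, and the material count.
That is deliberately a summary, not the full metadata — observation-unit
detail contributes nothing to findability, while the embedded block is
exactly enough to decide whether a dataset is relevant *without opening
any distribution*. The only cross-link between the generic and MIAPPE
parts is Dataset ↔ Investigation; alignments such as distribution-to-
study have no meaning and are never emitted. The crawler asserts this
discoverability property: dataset selection in the tests and the
discovery milestone uses embedded descriptors only.

Documents are defined at the file level; serving them over HTTP is a
trivial wrapper and intentionally out of the core, so the whole layer is
testable without a network.

## The six milestones and the three execution routes

1. **Discovery** — crawl the FDP breadth-first, select datasets by a
   predicate over embedded summaries.
2. **Study summaries** — id, country, location, dates, coordinates,
   altitude per study, exactly equal to the model fields.
3. **Genotype overlap** — intersection over studies of the genotype sets
   attached to observation units, after synonym resolution.
4. **Station matching** — per study, the station minimizing
   $(\Delta\mathrm{lat})^2 + (\Delta\mathrm{lon})^2$ in raw decimal
   degrees. This is deliberately the simple screen-distance the reuse
   scenario computes, not a geodesic; a haversine mode exists behind a
   flag but is off by default. Ties break lexicographically; the full
   sorted distance table is attached for inspection.
5. **Trait aggregation** — per (genotype, study): reduce repeated dated
   measurements per unit (default: last dated record; `mean` and
   `first` selectable), then average arithmetically over units
   ("averaged by plant"). Union and complete-case restrictions are
   provided; genotype-level records pass through directly.
6. **PBTT and stability** — cumulative photo-beta thermal time per
   study (below) and per-genotype lines from the worst to the best
   environment, classified rising/falling/flat with the value spread as
   the stability indicator. Ties in value or PBTT classify as flat or
   resolve to the lexicographically smallest study id.

Each milestone accepts three source kinds: the in-memory model,
serialized Turtle graphs, and a SPARQL 1.1 engine (rdflib, run out of
process) loaded with the same Turtle. The engine route extracts its
tables with SELECT queries — its own parser, its own query algebra — so
the three-way agreement asserted over 100 seeded fixtures exercises the
entire serialization stack, not just the arithmetic. `sparql_prefetch()`
batches all extraction queries for many fixtures into one engine
invocation to keep the property test fast. Federation
(`federated_fetch()`) is the degenerate two-source case: study
coordinates joined to station coordinates, study windows joined to
weather series, with identical results whatever each side's kind.

## Photo-beta thermal time

Daily PBTT is $f_{photo}(P)\cdot f_\beta(T)$ summed over the study
window. $f_\beta$ is the beta temperature response standard in crop
phenology: zero at or below $T_{base}$ and at or above $T_{ceil}$,
maximum 1 at $T_{opt}$, with a curvature exponent. $f_{photo}$ is a
clipped linear multiplier in $[0,1]$: 1 at or above the critical
photoperiod, declining per hour of shorter day. Under this orientation a
high cumulative PBTT marks environments with long days and temperatures
near optimum — the axis on which a rising stability line means "the
genotype did worse where days were short and cool".

The defining functional family and its parameter values are the
package's own configuration, documented here rather than taken from any
single source: defaults are the common potato cardinal temperatures
$T_{base}=5.5$, $T_{opt}=23.4$, $T_{ceil}=34.6\,^\circ$C, curvature 1,
critical photoperiod 14 h, sensitivity 0.15 h$^{-1}$. Absolute PBTT
values are therefore configuration-dependent and are *not* treated as
reference numbers anywhere; what the package guarantees, and the tests
assert, are the properties that hold for any admissible
parameterization: non-negativity, additivity over adjacent windows
(to $10^{-9}$), monotonicity in window length, zero under all-
subthreshold temperatures, and exact agreement with an independent
per-day summation.

Missing days in either weather series fail by default, listing the
dates; a skip-with-warning override exists because real station series
have gaps and a screening analysis may accept a lower bound.

## The synthetic deposit generator

Because the original archive cannot be bundled, the generator produces a
deposit-shaped emulation, and its defaults *are* the scenario's
documented conditions: 5 studies with ids `1999NL`, `2003VE`, `2004Fin`,
`2005Fin`, `2010ET` at plausible coordinates/windows for those sites;
292 genotypes in total of which 101 occur in all five trials; the
Venezuelan trial deposited only as genotype-level averages; 80 of the
common genotypes carrying a tuber-weight value in every trial (the
remaining 21 lose their values in one trial each); 10 plants per
genotype per trial in two blocks; a sparse plant-height time series and
a categorical flowering score for a few plants; and one weather station
per site within half a degree of the trial. All quantities are
deterministic functions of the seed.

The trait model is the simplest structure under which per-cell means are
well defined: genotype baseline + study effect + Gaussian plant noise
(defaults 350 ± 120 g baseline, 150 g study effect, 40 g noise, rounded
to 0.1 g). Weather is a latitude-and-altitude-anchored seasonal
temperature curve with daily noise, and photoperiod from standard solar
declination geometry. The generator also records a ground-truth ledger —
computed by its own plain loops, independent of the package's query
code — for every quantity the milestones recompute: genotype sets,
trait-cell means, nearest stations, PBTT per study.

What the fixtures do *not* emulate: real trait distributions and their
genotype-by-environment correlation structure, real station records,
multi-trait correlations, and the full messiness of legacy files beyond
the five named defect injections (`perturb_fixture()`: date-less event,
undeclared variable column, undeclared categorical token, conflicting
duplicate, missing weather day). Passing tests therefore demonstrate
that the machinery is lossless, consistent and defect-detecting on
deposit-shaped data — not that any biological conclusion transfers to
the real archive.

Block-level units are design carriers: they reference a representative
material and never carry measurements, since a mixed-genotype block has
no single material of its own but the model requires every unit to
resolve to one.

## Numerical and determinism choices

* Numbers cross text boundaries through one canonical renderer (up to 15
  significant digits, plain notation); measurement values keep their
  verbatim lexical form through RDF so round trips are exact.
* All sorting uses C-locale radix order, making reports, Turtle files
  and TSV outputs byte-reproducible across environments.
* Trait means are exactly permutation-invariant (cells are computed on
  sorted groups); equality across the three routes is asserted at
  $10^{-12}$, oracle agreement at $10^{-9}$ for floating sums and
  exactly for counts and sets.
* Problem sizes in the property suites — 100 fixtures of 2–4 studies ×
  8–14 genotypes for route consistency, the full 292-genotype deposit
  shape for the count checks — were chosen as the smallest sizes that
  still exercise every code path (overlap, pre-averaging, sparsity,
  drop-out) while keeping a complete run in minutes on one CPU.

## Known limitations

* The workbook layer speaks the per-section TSV form of the MIAPPE
  spreadsheet, not XLSX itself; converting between the two is mechanical
  but outside this package.
* The SPARQL route runs a local engine over the serialized files; it
  does not implement an HTTP SPARQL protocol client, and no triple-store
  product is bundled.
* The Turtle writer emits the line-oriented subset described above;
  arbitrary external Turtle is readable only within the documented
  conveniences.
* Genotypic data, QTL-by-environment statistics and any biological
  modelling of the trials are out of scope: the package reproduces the
  data-integration workflow, not the downstream genetics.
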