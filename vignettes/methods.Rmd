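---
title: "Methods: generating a synthetic population with activity-travel schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generating a synthetic population with activity-travel schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `actipop`: its assumptions,
parameters, numerical choices, and limitations. Code chunks are illustrative
and not evaluated when the vignette is built.

## 1. The model

`actipop` generates, for a region divided into zones, a population of agents
with households, socio-demographic attributes, and a complete 24-hour
activity–travel schedule per agent. The pipeline is a chain of five
conditional models; each stage consumes the previous stage's output plus the
relevant input data, and all stochastic steps are driven by explicit seeds.

### 1.1 Population synthesis (IPF)

For each municipality, a seed cross-tabulation of gender × age group is
raked by iterative proportional fitting (IPF) to per-zone marginal counts.
IPF alternately scales the table along each axis until every marginal
matches; it converges whenever the targets are consistent and the seed has
positive mass wherever the targets require it (structural zeros are
preserved). The fitted real-valued table is integerized by
truncate–replicate–sample: integer parts are kept, and the remaining persons
are sampled without replacement with probability proportional to the
fractional parts. The result matches the gender and age marginals of every
zone *exactly*.

*Assumption:* the municipal cross-tabulation's association structure applies
to every zone in that municipality; only the marginals differ by zone.

### 1.2 Household formation

Civil status follows age and the zone's couple targets: persons under 18 are
children; adults are matched into couples by sorting one gender by age and
the other by age plus a Gaussian partner-age proxy (mean −2 years, standard
deviation 4 years) and pairing by rank. Children are attached to the couple
or single household whose parent–child age gap lies in [18, 50] and is
smallest (ties go to the lower household id); children with no feasible
parent, and leftover adults, are grouped into "other" households of size
2–6. Per-zone targets for single/couple/other household counts are honoured;
infeasible targets (e.g. more couples than pairable adults) are capped with
a warning.

*Assumption:* rank-matching on age is a sufficient proxy for assortative
partnering; no explicit spatial or income sorting within a zone.

### 1.3 Advanced attributes (classifier + biproportional adjustment + sampling)

Employment, student status, income class, and household car ownership are
assigned by a three-step generative model:

1. a multinomial logistic classifier (`nnet::multinom`) fitted to the survey
   microdata gives each person a probability vector over the attribute's
   categories, conditional on their already-assigned attributes;
2. the n × K probability matrix is adjusted biproportionally — IPF on the
   matrix with row targets 1 (each person keeps a proper distribution) and
   column targets equal to the zone's control totals — so *expected* counts
   match the controls;
3. each person samples a category from their adjusted row.

Sampled totals therefore match controls up to multinomial noise (within a
few binomial standard errors), not exactly. Car ownership is fitted and
sampled at household level, then broadcast to members, so a household's
members never disagree about the number of cars.

*Assumption:* the survey's conditional attribute structure transfers to the
synthetic population; controls are only enforced as expectations.

### 1.4 Activity schedules

The day is modelled on a 24-hour axis anchored at 03:00 (internal hour 0 =
03:00 wall clock), the hour at which almost everyone is at home, so every
schedule can begin and end with a Home episode. Three sub-steps:

1. **Participation set.** A fitted choice model assigns each agent one of
   the eight Home-anchored subsets of {Work, School, Other} (H, HW, HS, HO,
   HWS, HWO, HSO, HWSO), conditional on employment, studenthood, gender, and
   age.
2. **Durations.** Total daily duration per activity type is copied from the
   most similar survey donor with the *same* participation set. Candidate
   filters (gender, 10-year age band, employment, studenthood) are relaxed
   one at a time, last-listed first, until donors exist; similarity is
   Euclidean distance on the donor's (t_H, t_W, t_S, t_O) profile; exact
   ties go to the smallest respondent id, making the match deterministic.
   The donor's total travel time bracket (lower, upper) is retained, and
   durations are scaled so that total activity time plus travel time tiles
   24 hours exactly.
3. **Assembly.** Activity instances are laid out in the donor's order;
   travel time is split equally into the gaps between consecutive
   activities; when an activity type occurs in several instances its total
   duration is split equally among them, with the day's first and last Home
   episodes acting as the two halves of one boundary Home block. Every
   schedule starts and ends with Home and tiles [0, 24) exactly (activity
   time + travel time = 24).

*Assumption:* donor days are transferable across agents that agree on the
participation set and the relaxed filter set; travel time is uniform across
a day's trips.

### 1.5 Locations and modes

1. **Home.** Each household is placed in a residential building (detached
   house or apartment) of its zone, weighted by building footprint area;
   within a zone, virtual subdivisions are weighted by gridded population.
2. **Mode.** A tour main mode (Car, CarPassenger, PublicTransport, Bike,
   Walking) is sampled per agent-day from a fitted choice model, with a hard
   constraint: agents in carless households never draw Car (CarPassenger
   remains possible).
3. **Destination zone.** For each (purpose, mode), destination probabilities
   come from supplied OD matrices when available (row-normalized flows;
   all-zero rows are a data error) and otherwise from a gravity model
   P(j|i) ∝ mass_j · exp(−β · d_ij), where mass is the zone's total
   footprint area of buildings usable for the purpose (Work → workplaces,
   School → schools, Other → other). School trips always use the gravity
   variant. β is fitted per (purpose, mode) by solving for the value whose
   model-implied origin-weighted mean trip distance equals the observed
   survey mean (`uniroot` on log β over [log 10⁻⁴, log 50]). Cells with
   fewer than 20 trips, and cells whose observed mean is outside the
   kernel's reachable range, fall back to a pooled per-purpose fit; an
   unfittable pooled cell is an error.
4. **Travel-time coupling.** Within the chosen probability row, the
   destination is not drawn independently: the agent's travel-time quantile
   (computed among all same-mode trips in the run) is pushed through the
   inverse CDF of the destination distribution ordered by increasing
   distance from the origin. Agents with longer travel times are thereby
   assigned farther zones; within an (origin, purpose, mode) stratum the
   assigned distance is a nondecreasing function of travel time by
   construction. Consecutive activities chain: each trip's origin is the
   previous activity's zone.
5. **Building.** Within the destination zone a building of the mapped usage
   type is drawn with probability proportional to footprint area; if the
   zone lacks a suitable building, the nearest zone that has one is used and
   the row is flagged as relocated. Coordinates are the building's.

## 2. Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| IPF tolerance | 1e-10 | absolute count | far below the 1-person granularity that integerization introduces |
| IPF max iterations | 10 000 | — | small tables converge in tens of sweeps; the cap only guards divergence on inconsistent input |
| partner-age proxy | N(−2, 4²) | years | mild, noisy age assortativity; rank matching uses only the ordering |
| parent–child gap | [18, 50] | years | biological plausibility window for parenthood |
| "other" household size | 2–6 | persons | covers shared flats and multi-generation remainders without degenerate singletons |
| day anchor | 03:00 | wall clock | hour of near-universal presence at home; lets every day open and close with Home |
| donor filter order | gender, age band, employment, studenthood (relaxed from the end) | — | keeps the strongest schedule determinants longest |
| gravity β search | log-scale [10⁻⁴, 50] | km⁻¹ | spans effectively-uniform to essentially-nearest-zone destination choice |
| gravity cell minimum | 20 trips | — | below this, mean distance is too noisy to invert; pooled fit is used |
| mode set | Car, CarPassenger, PublicTransport, Bike, Walking | — | published table vocabulary |

Seeds: every exported stochastic function takes a `seed`; stage seeds in the
pipeline are derived from the master seed by a fixed affine map modulo
.Machine$integer.max, so one integer reproduces the entire run.

## 3. The toy-region generator

Real register and survey data cannot be redistributed, so the package ships
a generator that emulates the *structure* of the inputs: zones on a planar
grid with centroid coordinates, per-zone marginal counts consistent with a
known ground-truth population, a municipal cross-tabulation, a 100 m-style
population grid, a building register with footprint areas and usage types,
travel-diary microdata produced by a known behavioural model (participation
probabilities, duration distributions, a gravity destination kernel with
known β per purpose and mode), and OD matrices aggregated from that kernel.

What it deliberately does **not** emulate: realistic Swedish geography or
demography, seasonal or weekday/weekend variation, multi-day diaries,
public-transport network structure, or any spatial autocorrelation beyond
the gravity kernel. It exists so the pipeline's statistical machinery can be
verified against known ground truth, not to be mistaken for real data.

## 4. Numerical and design choices

- **Exact marginals by construction.** Truncate–replicate–sample
  integerization preserves fitted marginals exactly, so population-synthesis
  accuracy does not depend on rounding luck.
- **Expectations, not quotas, for advanced attributes.** Biproportional
  adjustment hits controls in expectation; we accept multinomial noise
  rather than forcing quotas, which would distort individual probability
  rows.
- **Deterministic tie-breaking everywhere.** Donor matching and child
  assignment break ties by smallest id; combined with explicit seeds this
  makes every run byte-reproducible (same seed ⇒ identical output files).
- **β fitted on the log scale** because the deterrence rate spans orders of
  magnitude and the mean-distance curve is monotone in log β, making
  `uniroot` robust.
- **Clock times are exported at one-decimal precision** in wall-clock hours
  (internal hour + 3 mod 24), matching the published table format; readers
  and writers round-trip all three table schemas losslessly at that
  precision.
- **S3, data-frame-first.** The objects are tabular (persons, households,
  activity rows); plain data frames with light S3 wrappers keep the package
  transparent and dependency-free rather than introducing a heavier class
  hierarchy.

## 5. Limitations

- Schedules are single-day and tour-simplified: one main mode per day,
  travel time split equally across gaps, no explicit trip chaining
  constraints beyond origin chaining.
- Destination choice ignores capacity: a building's footprint area is a
  proxy for attractiveness, and nothing prevents over-assignment to one
  building.
- The travel-time/distance coupling is a rank coupling, not a speed model:
  travel times are donor-inherited, not derived from network distance, so
  implied speeds are not physically constrained.
- Household formation matches counts and age structure but not income or
  ethnicity homophily.
- With few zones, destination distances take few distinct values; rank-based
  diagnostics of the travel-time coupling are then depressed by ties even
  though the coupling itself is exactly monotone.
- No road network, routing, or traffic assignment: the output is a demand
  description, intended as input to a downstream transport simulation.
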