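---
title: "Modeling grocery-shopping travel in a disinvested food environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling grocery-shopping travel in a disinvested food environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In urban neighborhoods that have lost their major supermarkets, household
grocery travel is shaped less by what the built environment offers nearby
than by who the households are: income determines car access, age determines
trip frequency and the tolerance for walking and cycling, and both determine
where people actually shop. `groceryabm` simulates this process explicitly.
Stratified household agents live in houses on a road network inside a small
case-study neighborhood (just under 10 square miles, 23 census tracts),
nested in a city, nested in a metropolitan region. Each week every household
decides how many grocery trips to make and, trip by trip, which store to
visit and how to travel there. The trip log — store, travel mode, shortest
network distance in miles, and the shopping zone of the store — is the
model's output surface.

## The agent groups

Households are grouped into eight income-by-age strata. The stratification
grid (income rows: under \$20,000; \$20,000–49,999; \$50,000 and above; age
columns: 18–44, 45–64, 65+, with the two highest-income older cells merged)
carries a survey sample of 188 households with group sizes 33, 43, 15, 23,
28, 11, 13, 22. Each group bundles every probability distribution the
decision process draws from:

* a trips-per-week distribution (truncated Poisson on 0–20, mean matched to
  the group's target rate),
* a car-ownership probability,
* a weighted pool of preferred stores (the stores the group's respondents
  reported),
* type-consideration weights over store types,
* a marginal mode distribution for carless mode-first trips, and a
  distance-binned non-motorized probability table for carless store-first
  trips,
* a mean household size per income stratum (2.20 / 2.37 / 2.56 persons).

## The weekly decision process

Every agent, every week:

1. draws the number of shopping trips `n` from its group's distribution;
2. for each trip, with probability `type_consideration_prob` (default 0.5)
   fixes a store type first — type is a proxy for what groceries to buy —
   restricting the candidate pool to that type (weights renormalized; an
   empty restriction falls back to the full pool);
3. with probability `mode_first_prob` (default 0.5) decides the travel mode
   before the store, otherwise the store before the mode;
4. households with a car always drive, in either ordering. Carless
   mode-first trips draw the mode from the group's marginal distribution and
   then the store with weights `w_s * exp(-d_s / lambda)` (`lambda_walk = 3`
   miles, `lambda_bike = 6` miles; no decay for bus/taxi). Carless
   store-first trips draw the store from the pool weights and then the mode
   from the distance-binned non-motorized table (1-mile bins with an
   open-ended tail beyond 10 miles).

The week has no carry-over state: the process is memoryless by design, which
matches a routine, habitual activity. Mixed-mode journeys (walk out, taxi
back) are collapsed to one primary mode per trip; taxi/jitney counts as
motorized, so non-motorized means walking or cycling only.

Both 0.5 defaults are deliberate: the order of the mode/store decision and
the strength of type consideration are the genuinely uncertain parts of the
decision structure, so they are set to indifference and exercised in the
sensitivity analysis rather than asserted.

The exponential decay for walking/cycling store choice, instead of a hard
distance cap, reflects that non-motorized trips are observed out to 7.5–8+
miles but taper quickly; the decay scales are configuration, not constants,
and are included in the sensitivity analysis.

## Spatial machinery

Coordinates are planar, in miles — at a metropolitan scale of ~20 miles the
projection error is negligible and fixtures stay hand-checkable. The road
network is an undirected graph with positive edge lengths; travel distance
is the length-shortest path (the survey behind the model used time-shortest
routes from a mapping service; length and time optima can differ, which we
accept and note). Houses and stores snap to their nearest network node
within 0.25 miles; snapped offsets are ignored. The origin–destination
matrix holds the shortest network distance for every house–store pair and is
validated in the tests against an independent Floyd–Warshall oracle.

Zones are defined by two nested polygons (neighborhood inside city); points
outside the city are suburbs. Polygon boundaries belong to the innermost
zone containing them — a deterministic tie-break for stores sitting exactly
on a boundary.

## The synthetic fixtures and their calibration

The survey microdata and the real GIS extracts behind the original study are
not public, so the package generates a synthetic study area and a synthetic
188-respondent sample, and calibrates the group fixtures so that the
*simulated aggregates* reproduce the published ones. Calibration targets are
inputs; the simulation must return them as outputs (closed-loop validation,
standing in for model-to-model comparison). The targets:

* zone-visit shares per group — core low income young 25% / 57% / 18%
  (neighborhood / city / suburbs), medium income young 11% / 36% / 53%;
* population aggregates — 23% of all trips in the neighborhood, 35% in the
  suburbs, 5.0 trips per household-week, mean trip distance above 5 miles;
* car access — over 30% of all households without a vehicle, about 10% in
  the highest income stratum;
* non-motorized travel — 40–50% of core-low-income-young trips, declining
  with age and income, with motorized travel exclusive beyond 6 miles for
  the low-income young group.

Where the published aggregates give only bounds ("over 50%"), mid-band
values are fixed once in `calibration_targets()`. Three conventions are
worth stating explicitly:

* **One group absorbs the population constraints.** Seven groups get round
  target values; the largest group (CoLwInMiAg) has its zone shares and trip
  mean solved so the population-level targets hold exactly in expectation.
* **Car-ownership is set per group, not per income stratum.** A uniform 30%
  no-car rate for the lowest income stratum cannot produce either the >30%
  population no-car share (the stratum is only half the population) or a
  40–50% non-motorized share for the core-poor young (car owners always
  drive, so the non-motorized share is bounded by the no-car share). The
  group values (0.60/0.40/0.30, 0.35/0.22/0.15, 0.10/0.10 no-car) reproduce
  both; the cost is that the core-poor:medium no-car ratio becomes ~4.6
  rather than ~3 — the published aggregates are mutually inconsistent under
  sample-proportional upscaling, and we keep the quantities that are
  measured surfaces.
* **Group parameters come from the targets, not re-estimated from the 188
  synthetic respondents.** Re-estimating a car-ownership probability from,
  say, 35 respondents adds ±5-point sampling drift that the closure checks
  would inherit. The respondent table carries the microdata face of the
  fixtures (ages, incomes, household sizes, reported store pools); only the
  store pools feed the group fixtures.

**Zone calibration.** Raw pool weights come from respondent report counts.
The calibrator then rescales the three zone blocks of each group's pool
weights (iterative proportional scaling) until the *expected* zone-visit
shares equal the targets to 1e-6 — where the expectation is taken under the
full decision law: the mixture over car ownership, decision order, carless
modes, type restriction, and exponential decay, averaged over the group's
expected house distribution (tract household counts times tract group mix).
Because the law is nonlinear in the weights, plain block scaling of the
weights alone would leave a systematic bias of a percentage point or two
from the decay and type terms; folding the full law into the fixed point
removes it. Groups already meeting their targets are returned unchanged.

**Mode-table scaling.** The logistic non-motorized curve (midpoint 5 miles,
scale 1.5, zero beyond the group's cutoff) is scaled so the expected
non-motorized share among carless store-first trips equals the group's
conditional target; the mode-first marginal uses the same value, so the
group's overall non-motorized share is `no_car * target` by construction.
Non-motorized trips split 65/35 walk/bike, carless motorized trips 80/20
bus/taxi.

**Type-consideration weights** are the pool's type masses tilted toward
supermarket types (chain 2.0, independent 1.5, convenience 0.5, dollar 0.7,
other 1.0): full grocery runs go to supermarkets. A mass-proportional choice
would make the type decision exactly neutral for store selection, which is
both behaviorally wrong and would erase the type decision's variance
contribution.

**Tract profiles.** Household counts (14,520 total — "a little over 14.5k")
are multinomial over 23 tracts; group mixes are Dirichlet draws
(concentration 60) centered on the sample proportions and then raked so the
household-weighted aggregate mix equals the sample proportions exactly.
Upscaling then draws each tract's households from its mix (multinomial) and
resamples respondent records within groups with replacement.

## What the synthetic data does and does not emulate

The synthetic city has the right *structure* — three nested zones, stores
clustered along arterial corridors running out of the neighborhood, chain
supermarkets only in the suburbs, houses only in the case-study tracts — and
the right *aggregates* (those listed above). It does not reproduce real
street geometry, transit schedules, actual store locations, or any real
household's behavior. Passing the closure tests therefore demonstrates that
the decision engine, distance machinery, upscaling and reductions are
mutually consistent and correctly implement the stated behavioral rules; it
does not re-validate the original empirical findings against independent
data.

## Sensitivity analysis

The Sobol engine is self-contained: Saltelli cross-sampling (A, B, AB_i,
BA_i blocks from Latin hypercube base samples; N(2k+2) evaluations), Jansen
estimators for S1 and ST averaged over the symmetric blocks, and percentile
bootstrap confidence intervals. It is validated against the closed-form
variance decomposition of the Ishigami function (a = 7, b = 0.1: S1 =
0.314, 0.442, 0) and an additive two-variable model, both within ±0.05 at
N = 1024.

`run_model_sa()` evaluates the full simulator over `mode_first_prob`,
`type_consideration_prob`, `lambda_walk` and `lambda_bike`, with the median
trip distance as output. Replicates use common random numbers (the same
simulation seeds at every design point), so purely stochastic variation
cancels from the index estimates; a parameter the model ignores gets an
exactly zero total-order index. Reduced-scale defaults (N = 32–64 design
points, 800–1000 agents, 12–20 weeks) are used because Sobol indices are
variance *ratios* and robust to population scale; the package supports
full-scale runs through the same interface. At these settings the
type-consideration parameter clearly dominates the decision-order parameter
for median distance traveled — the model's central structural finding.

## Numerical and testing conventions

* All randomness flows through explicit seeds; agents own independent RNG
  streams derived from the run seed and the agent id, so trip logs are
  invariant to agent iteration order and bit-reproducible.
* Closure tests compare simulated shares to targets within 3 standard
  errors, with the standard error computed cluster-robustly over agents:
  an agent's ~260 trips share its house and car status, so the naive
  binomial formula would understate the sampling variance.
* Medians use the midpoint convention for even counts and are checked
  against a sort-based oracle; the headline median is per trip (matching
  the distance axis of the mode-by-distance surface), with per-agent-week
  totals available via an argument.
* Degenerate inputs fail loudly: schema errors name the offending feature,
  snapping errors the offending house or store, infeasible calibration
  targets the offending zone.

## Known limitations

* One-way streets, transit routing and travel time are not modeled; distance
  is the output of record.
* Trip counts are i.i.d. across weeks; respondent-fixed weekly habits would
  add between-agent variance the current model does not carry.
* Store choice within a zone block is driven by report counts and decay
  only; no store-size or price attraction terms.
* The eight-group stratification ignores gender and education, and
  store-owner behavior (entry/exit) is out of scope.

## Problem sizes

The packaged runs use 14,520 agents over 52 weeks (~3.8 million trips,
about 15 seconds), a 690-house by 42-store OD table on a 1,681-node grid
network, and reduced-scale sensitivity runs of 320 simulator evaluations;
these sizes were chosen so the whole validation cycle stays interactive on
a laptop.
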