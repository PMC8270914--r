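---
title: "Linear-habitat home ranges and MPA coverage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-habitat home ranges and MPA coverage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reefrange estimates grey-reef-shark home ranges from passive acoustic
telemetry along quasi-linear barrier-reef habitat, tests how home range
varies with sex, maturity and season, and models whether a marine protected
area (MPA) of a given reef-slope area can fully contain individual home
ranges. This vignette is the package's own account of the methods: the
models and their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, the numerical choices, and known
limitations.

## 1. The one-dimensional utilization distribution

Receivers sit along the outer reef slope, which for this species is
effectively a one-dimensional habitat. Receiver spacing rules out kernel
density estimation, so home range is summarized by one-dimensional convex
hulls on the curvilinear reef axis:

1. **Daily binning.** The monitoring period is split into local calendar
   days (study timezone UTC+11 by default; stored timestamps remain UTC). A
   shark has an *occurrence* at a receiver on a day iff it was detected
   there at least once that day; one shark-day can contribute occurrences
   to several receivers.
2. **Receiver ranking.** Per shark, receivers are ranked by descending
   occurrence count. The *core* set is the shortest prefix whose cumulative
   count reaches 95% of the total. The ranking statement alone does not fix
   the rule precisely, so the package makes it exact as "shortest
   descending-count prefix with cumulative share >= 0.95", ties broken by
   ascending receiver id; both the threshold and the >= convention are
   arguments.
3. **Hull-to-area mapping.** Each reef carries a non-decreasing
   piecewise-linear cumulative slope-area function A(s) (km² of fore reef,
   reef pass and subtidal reef flat from the reef origin to curvilinear
   position s). The hull of a receiver set on one reef is
   [s_min, s_max]; its area is A(s_max) − A(s_min); hulls on different
   reefs are summed and inter-reef water contributes zero. UD100 uses all
   visited receivers, UD95 only the core set, so UD95 <= UD100 always.

A shark seen at a single receiver has a degenerate hull and UD95 = UD100 =
0: the array resolution cannot distinguish a range smaller than the
receiver spacing, and such sharks keep a *null*, not missing, home range.
A shark with no occurrence in a season is *absent*, represented as `NULL`,
deliberately distinct from UD = 0; seasonal statistics by default use only
sharks present in the season (the alternative — scoring absences as 0 — is
available by building the UD table for season `"all"` and subsetting).

Seasonal use contrasts the mating season (July–September) with its
complement. The mating-exclusive share of a shark's home range is the
per-reef interval difference (mating hull minus non-mating hull) mapped
through A, divided by the year-round UD100; it is 0 when there are no
mating-season detections or when UD100 = 0.

## 2. Telemetry ingestion rules

* **False-detection filter.** The field-standard tool for 69 kHz code
  collisions is proprietary, so the package uses a documented equivalent: a
  detection is removed iff no other detection of the same transmitter at
  the same receiver falls within ±3600 s. The window is about 60 times the
  60 s mean transmission delay and is configurable; the rule is idempotent.
* **Post-capture window.** Detections in [capture instant, capture instant
  + 14 × 86400 s) are dropped. Whether the two weeks count from the capture
  moment or from midnight is not specified in the source protocol; the
  package anchors the instant at local midnight of the tagging date, a
  closed-open interval, and exposes `days` as an argument.
* **Cohort rules.** Sharks tagged at a receiver that was subsequently lost
  are excluded first (their range cannot be anchored), then sharks with
  zero remaining detections. The precedence makes the two exclusion sets
  disjoint, so the arithmetic identity
  `n_retained = n_tagged − n_lost − n_silent` holds on any input, including
  sharks that are both silent and tagged at a lost receiver.

## 3. Population statistics

UD values are transformed as y = log10(1 + x) before all group tests. The
two-way test is a univariate permutation ANOVA: sequential (type-I) sums of
squares for sex, maturity and their interaction, with p-values from
unrestricted permutation of the responses and the +1 correction
(p = (1 + exceedances) / (1 + iterations)), so p is never exactly 0.
Permutation counts stop early per term by an Anscombe-style sequential
rule: after at least 100 permutations, a term freezes once the estimated
standard error of p falls below 0.1·p, else it runs to the 5000-permutation
budget. The exact stopping rule in the reference implementation is not
restated in its documentation; this one reproduces its visible behaviour
(terms with large p stop after a few hundred iterations, significant terms
exhaust the budget). Residual-permutation schemes are deliberately not
implemented; unrestricted response permutation matches the reference
default.

Pairwise contrasts use classic pooled-variance Student t statistics with
999 label permutations per pair (exhaustive enumeration available for small
groups). Group means carry 200-run percentile-bootstrap 95% intervals, and
cumulative UD curves carry pointwise 200-run bootstrap bands, clamped to
contain the point estimate. The degenerate cases are fixed by convention: a
zero pooled variance with zero mean difference gives t = 0 (p = 1), and a
single observation gives a width-zero interval.

## 4. The MPA coverage model

For a protected reef-slope area S, the axis [0, S] is discretized into
n = ⌈S/dS⌉ intervals of width dS = 1 km² (the last truncated at S when dS
does not divide S). A shark j *centred* in interval i — the package reads
"centred" as the interval midpoint c_i, which the source description leaves
open — is fully covered iff [c_i − UD_j/2, c_i + UD_j/2] ⊆ [0, S]. P_i
averages this indicator over the UD sample, and Π = mean(P_i) is the
probability that a shark placed uniformly in the MPA keeps its entire home
range protected. The model assumes a homogeneous distribution of
individuals over intervals considered independently, and evaluates Π on the
raw UD sample rather than an interpolated cumulative curve. In the
continuum limit Π → mean_j max(0, S − UD_j)/S, and the discretized value
agrees with this closed form to within dS/S — both facts are enforced by
tests, together with monotonicity in S, antitonicity in any single UD, and
permutation invariance. `min_size_for_target()` exploits the monotonicity
to find the grid-minimal S with Π(S) >= the target.

## 5. WDPA-style screening

MPA polygon records are retained when they have IUCN category I, Ia, Ib or
II (the "I and II" criterion is expanded to WDPA's subcategories), a
designation year, a centroid inside 26°S–26°N and 25°E eastward to 150°W
(longitudes tested on the [0°, 360°) scale so the box straddles the
antimeridian), and a non-empty reef intersection. Reef area is the
WGS84-ellipsoid area of the intersection, computed from a closed-form
meridian-band integral with edges densified in longitude/latitude space —
exact for the latitude/longitude-aligned fixtures and verified against an
independent numeric integration to much better than the 1% contract.
No geospatial stack is assumed: intersections use Sutherland–Hodgman
clipping, which requires convex reef polygons (checked, with an error
otherwise), and invalid rings receive a light repair — duplicate-vertex
and spike removal plus splitting self-intersecting rings at their crossing
points — standing in for a zero-width buffer. Multi-part records are
treated atomically by WDPA id. Manually added records (e.g. protected
areas missing from an extract) enter through the same GeoJSON channel, not
as hard-coded data.

## 6. The synthetic world

No telemetry accession is deposited for the study system, so the generator
is a first-class module that emulates its stated structure, with ground
truth retained for recovery tests:

* ~70 receivers at 2 km spacing along four reefs (lengths 46, 38, 30,
  26 km) laid out around 21°S; slope-area density 1 km²/km so A(s) = s.
* 147 tagged sharks in four sex-by-maturity groups. Group mean range spans
  10, 4.4, 6.2 and 2.7 km (adult male, adult female, juvenile male,
  juvenile female); individual spans are Gamma(shape 4) around the group
  mean (CV 0.5), floored at the array's detectability width and capped at
  60% of the reef. Adult males expand their interval by 11 km during
  July–September; with a 10 km baseline this yields a mating-exclusive
  share near one half, matching the reported behaviour qualitatively. The
  mating interval is a superset of the non-mating interval by
  construction; other groups do not expand.
* Daily positions are independent uniform draws from the seasonal interval
  — exchangeable by day, which is exactly what the daily-binning estimator
  assumes; no within-day movement model is claimed. Receivers within
  0.4 km (a typical VR2W detection range) log a Poisson burst of pings
  whose inter-ping delays are uniform on 30–90 s, the transmitter's duty
  cycle. A real tag would emit ~1200 pings/day; the shipped cohort
  fixture subsamples to a mean of 2 logged pings per shark-day and one
  simulated year (July 2015–June 2016, covering both seasons) purely to
  keep test runtimes small — cohort arithmetic and all tested quantities
  are unaffected by this scaling.
* Silent sharks transmit only during the 14-day post-capture window, so
  the exclusion rule — not the false-detection filter — removes them.
  Isolated false pings are injected at far-away receivers at a small daily
  rate to exercise the filter.
* The engineered cohort fixture tags 147 sharks of which 29 are silent,
  3 of them at receivers then flagged lost; with the lost-first precedence
  this retains exactly 118 (53 adult males, 19 adult females, 19 juvenile
  males, 27 juvenile females). The published counts (147 tagged, 29
  silent, "three other" lost-receiver animals, 118 analysed) are only
  mutually consistent if the lost-receiver animals are a subset of the
  silent ones, which is how the fixture is engineered. Exact-count fields
  (`n_silent`, `n_lost_receiver_sharks`) exist because per-seed tuning of
  a silence probability toward exact counts would be fragile; the
  stochastic `p_silent` path remains the default.

What a green recovery test establishes: on exchangeable-by-day uniform
movement with a dense enough array, hull endpoints converge to the true
interval within one receiver spacing and the configured group ordering of
mean UD100 is recovered. What it does not establish: robustness to
autocorrelated or tidally driven movement, heterogeneous detection
efficiency, receiver outages, or sharks whose true range spans several reefs —
none of which the generator emulates.

## 7. Determinism and seeds

Every stochastic routine takes a seed. The pipeline derives per-stage seeds
from a master seed (`seed + 100 + stage index`) so stages can be reproduced
in isolation, and two runs at the same master seed produce byte-identical
output files; orderings use radix sorting to stay locale-independent.

## 8. Known limitations

* UD is measured on reef-slope habitat only; use of lagoon or pelagic
  habitat is invisible to the array, so ranges are conservative.
* Single-receiver sharks are assigned UD 0, skewing small ranges to null —
  of little consequence for the coverage model, which is driven by the
  upper part of the UD distribution.
* The coverage model ignores habitat limits and range overlap between
  neighbouring intervals; for an isolated atoll smaller than a shark's
  nominal range it is pessimistic.
* Polygon clipping requires convex reef polygons, and the ring repair
  handles crossings, duplicates and spikes but not every exotic invalidity
  a full geometry engine would; shapefile input is not supported (GeoJSON
  only).
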