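---
title: "A rectangle-matched permutation null for urban biodiversity hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rectangle-matched permutation null for urban biodiversity hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardenspot)
```

## The question and why raw comparisons fail

A botanical garden embedded in a city will often show an impressive species
list on community-science platforms. That list confounds two things:
genuine habitat value, and the fact that gardens concentrate observers.
Comparing the garden's richness to the whole city's is no better — the city
is thousands of times larger. `gardenspot` frames the question the way a
permutation test frames any question: *if I carved out a piece of the city
the same size as the garden, how often would it look as rich as the garden
does?*

## The procedure

Given a de-duplicated city occurrence set and the garden's bounding
rectangle, `sample_null_distribution()` executes, in order:

1. **Garden exclusion.** Every record inside the garden rectangle (closed
   bounds) is removed from the city set. The garden's own observations must
   never contribute to the null it is judged against.
2. **Centroid pool.** The distinct coordinates of the remaining records
   become the candidate rectangle centres. Placing rectangles uniformly
   over the map would mostly sample streets and rooftops nobody surveys;
   anchoring them on observed coordinates confines the null to the observed
   effort surface. This deliberately weights the null toward heavily
   observed places — which is conservative for the garden, since those are
   the places most likely to rival it.
3. **Replicates.** `R` centroids are drawn uniformly *with replacement*;
   each centres a rectangle of exactly the garden's longitude/latitude
   extents, and the records inside (closed bounds) yield one replicate's
   species richness and Shannon index.
4. **Percentile.** `percentile_of()` places the garden's observed metric in
   the replicate distribution with the mid-rank convention
   `100 * (#below + 0.5 * #ties) / R`. `assess_garden()` flags a hotspot
   when the percentile strictly exceeds the threshold.

The metrics are the two standard ones: richness `S` is the distinct species
count; the Shannon index is `H = -sum(p_i * log(p_i))` over relative
abundances, with the per-species observation count as the abundance proxy.
Observation counts are a biased abundance estimator (conspicuous species
are over-reported), but the bias applies to garden and null rectangles
alike, which is all a permutation comparison needs.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `R` | 1000 | replicates | resolves percentiles to 0.1 at mid-rank; doubling it changes little beyond runtime |
| `threshold` | 75 | percentile | a-priori hotspot criterion, strict `>` |
| `min_garden_obs` | 40 | records | below this, community-science coverage is too thin to trust the garden metrics; a warning is raised but the assessment still runs |
| date window | 2000-01-01 .. 2022-06-21 | — | the modern community-science era; both ends inclusive |
| `base` / `log_base` | `exp(1)` | — | Shannon in nats, the ecological default; 2 and 10 available |
| `seed` | required | — | every stochastic step is seeded and the seed is logged in results |

## Numerical and convention choices

* **De-duplication key is exact.** Records are duplicates only when
  latitude, longitude, date and species match exactly as parsed. No
  tolerance is defensible without knowing platform rounding behaviour; an
  opt-in `round_coords` merges coordinates at a chosen decimal for noisy
  cross-platform pairs. The platform tag is excluded from the key — it is
  precisely what differs between the two copies of one observation.
* **Closed bounds everywhere.** A point on a rectangle edge is inside, for
  the garden and for every replicate, so the two sides of the comparison
  use one convention.
* **Degrees, not metres.** Null rectangles match the garden in degree
  extents. Within one city, the degree-to-metre distortion is the same for
  the garden and every null rectangle, so matched degrees are matched
  areas; a projected mode is out of scope.
* **Empty replicates score (0, 0).** A rectangle can be empty only in
  pathological geometries (the centroid's own record excluded by latitude
  clamping); defining richness 0 / Shannon 0 keeps the distribution total
  at `R`.
* **Mid-rank ties.** With integer richness, ties between the garden and
  replicates are common; half-weighting them makes a garden identical to
  the city score 50 rather than 0 or 100, and makes the percentile
  monotone in the observed value.
* **Dates need full precision.** Year-only or year-month records cannot
  participate in the exact dedup key and are dropped, with a count in the
  validation report.
* **Centroid pool built after exclusion.** Whether garden-interior
  coordinates should seed null rectangles is genuinely ambiguous; excluding
  them first is self-consistent (the null never re-imports excluded
  records) and prevents dense garden effort from steering the null toward
  the garden's own neighbourhood.
* **No clipping to a city boundary.** Replicate rectangles may overhang the
  supplied set's extent; records outside the set do not exist, so overhang
  only thins that replicate. The city is operationally its observation set,
  not an administrative polygon.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` produces data with the four properties the analysis
actually depends on: a **skewed species-abundance distribution** (log-normal
with shape `abundance_sigma`, default 1.5 — a standard ecological skew
model), **clustered observation effort** (a truncated-Gaussian cluster
mixture, `n_clusters = 5`, `cluster_sd = 0.02°`, half of effort clustered —
a simple Thomas-process stand-in that stresses the non-uniform centroid
pool), **cross-platform duplicates** (`duplicate_fraction = 0.15` of records
re-emitted verbatim under the other platform tag, with exact bookkeeping for
tests), and an optional **enriched garden** (`garden_enrichment = k` adds
`k` garden-exclusive species with 3 observations each plus `2k` extra
garden-interior records). The default city is a 0.4° × 0.3° box with a
0.02° × 0.02° garden; the null preset uses 60 species and 2000 observations.

It does not model phenology, detection covariates, taxonomic disagreement
between platforms, coordinate obfuscation, or species co-occurrence. A
passing calibration therefore shows the *procedure* is unbiased under its
own assumptions — not that real-city percentiles are free of effort
artefacts the generator omits (e.g. a garden that is the only surveyed
place in its quadrant).

## What the tests establish

* Every filter, the dedup rule, rectangle membership, the Shannon index and
  the percentile are checked against independent brute-force oracles
  (all-pairs scans, linear scans, rank-based percentiles, a straight-line
  reimplementation of the whole null procedure, and `vegan::diversity`).
* **Calibration:** over 400 independent null scenarios (no enrichment), a
  pseudo-garden rectangle centred on a random observed coordinate and
  scored with `R = 200` has mean richness percentile ≈ 50 and a roughly
  uniform decile histogram, with the >75 flag firing at roughly its nominal
  25% rate. Run counts here are chosen to keep Monte-Carlo error on the
  mean near ±1.5 percentile points.
* **Recovery:** a garden built to exceed every same-size rectangle
  (10 exclusive species over a sparse 400-observation background) scores
  percentile exactly 100 with `R = 1000`, and the flag is positive.
* **Monotonicity:** the mean richness percentile is non-decreasing in the
  enrichment strength `k` across a seeded sweep (`sweep_scenarios()`).

## Limitations

The percentile is a descriptive rank, not a p-value: replicates are
spatially autocorrelated (they share records), no multiplicity correction
is applied across gardens or metrics, and the 75th-percentile criterion is
a convention. Gardens below ~40 records give noisy metrics; the package
warns rather than refuses. Cities whose boundaries include large wildland
(mountain slopes, riparian corridors) inflate the null and can mask a
genuinely rich garden — a data-definition problem upstream of the
statistics.
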