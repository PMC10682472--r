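---
title: "Population-weighted proximity: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-weighted proximity: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkaccess)
```

## The problem and the model

In high-density cities, straight-line ("geometric") distance to the nearest
park is a poor stand-in for the walk residents actually face: street routes
are systematically longer than chords, residents weigh several candidate
parks rather than only the nearest, and larger or better-equipped parks draw
visitors from farther away. `parkaccess` models access as an *expected*
walking proximity under a destination-choice model, then aggregates that
expectation over the population.

The pipeline has three stages, always run in this order:

1. **Interaction.** Every block–park pair gets a gravity-type score
   $A_{ij} = \mathrm{attr}_j^{\lambda} S_j^{\alpha} / p_{ij}^{\beta}$, where
   $S_j$ is park area in m², $p_{ij}$ is proximity (meters or seconds), and
   $\mathrm{attr}_j$ is the Attractiveness Index. Variants that ignore
   attractiveness drop the $\mathrm{attr}^\lambda$ term.
2. **Choice.** Each block's choice set is its $k$ nearest reachable parks
   (default $k=7$), ranked by the *same* proximity metric the variant uses.
   Visit probabilities are the normalized scores
   $P_{ij} = A_{ij} / \sum_{j'} A_{ij'}$.
3. **Expectation and aggregation.** The block-level value is
   $\mathrm{PWP}_i = \sum_j P_{ij}\, p_{ij}$, and higher planning units take
   the population-weighted mean of member blocks,
   $\mathrm{PWP}_x = \sum_i \mathrm{Pop}_i \mathrm{PWP}_i / \mathrm{Pop}_x$.

The key assumptions: interaction declines as a power law in travel cost;
supply capacity (area) and quality (amenities) raise interaction
multiplicatively; and residents consider a bounded set of nearby parks. The
framework deliberately does not model catchment congestion (no 2SFCA-style
demand competition), transport modes other than walking, or time-of-day
variation.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $\alpha$ | 0.85 | — | park-size exponent |
| $\beta$ | 1.91 | — | proximity decay exponent (shared by distance and time) |
| $\lambda$ | 0.52 | — | attractiveness exponent |
| $k$ | 7 | parks | choice-set size |
| category weights | 13.3 / 66.0 / 20.7 | AI points | sports–recreation / nature / general amenities |
| NDVI threshold | 0.2 | — | binarizes mean NDVI into the `trees` flag |
| snap radius | 200 | m | graph provider's maximum node-snapping distance |
| proximity floor | 10 | m or s | lower bound on $p$ inside $p^\beta$ |
| AI floor | 0.1 | AI points | lower bound on attr in attractiveness variants |
| walking speed | 4.0 | km/h | factor provider's distance→time conversion |

The decay exponents are published survey-based estimates for walking access
to public open space; they are arguments everywhere, so locally estimated
values drop in without code changes. The same $\beta$ is applied to distance
and time variants because both measure the same physical separation. The
category weights are expert-panel importance ratings for physical-activity
participation, re-grouped into three categories and divided equally within
each; they are kept on their native scale (summing to 100) rather than
renormalized, because choice probabilities depend on attr only through
ratios of $\mathrm{attr}^\lambda$ and are therefore scale-free. The default
walking speed of 4.0 km/h is the implied average of route-distance over
route-time surfaces in dense, hilly, signal-interrupted street networks —
slower than the 5 km/h flat-ground convention on purpose.

## Numerical choices and degenerate inputs

* **Proximity floor.** A block centroid inside a park gives $p \approx 0$
  and an unbounded score. $p$ is floored at 10 m / 10 s *inside the score
  only*; the expectation $\sum_j P_{ij} p_{ij}$ uses raw proximities, so the
  convexity bound (block PWP lies within the choice set's proximity range)
  holds exactly.
* **Zero attractiveness.** A park with no attributes has $\mathrm{AI}=0$ and
  $\mathrm{attr}^\lambda = 0$ would silently delete it from every choice
  set. Whether such parks should be dropped or kept is genuinely open; we
  keep them, floored at AI = 0.1, so that a featureless park behaves as a
  very unattractive one rather than as a non-park. Both floors are
  arguments.
* **Unreachable pairs.** A destination that cannot be snapped to the
  network, or is disconnected from the origin, is recorded as `NA` in the
  proximity matrix (with one summary warning) and excluded from the choice
  set — never imputed, because imputation would distort the probabilities of
  the remaining parks. A block with *no* reachable park is dropped from the
  surface with a warning naming it.
* **Ties.** k-nearest selection breaks proximity ties by ascending park id,
  making choice sets deterministic across platforms. Hotspot thresholds are
  inclusive, so tied units flag together.
* **Population cancellation.** The block-level formula multiplies and
  divides by $\mathrm{Pop}_i$; implemented exactly as written, so
  zero-population blocks keep a well-defined PWP but contribute zero weight
  to aggregates. A unit whose blocks sum to zero population aggregates to
  `NA` rather than an arbitrary number.
* **Choice-set ranking metric.** Ranking uses the variant's own proximity
  metric (geometric for PWGD, route distance for PWRD/PWRD-Attr, route time
  for PWRT-Attr). With a constant detour factor and constant speed all
  rankings coincide, which is what makes the end-to-end identities
  (PWRD = factor × PWGD; PWRT-Attr = PWRD-Attr ÷ speed) exact — a property
  the test suite asserts at 1e−12.
* **Conversion factor.** "Route ≈ 1.5 × geometric" can mean the OLS slope or
  the mean per-pair ratio; the regression report emits both, and the fit is
  always with intercept, never forced through the origin.

## What the synthetic generator emulates — and what it does not

`generate_city()` produces, deterministically under one seed, the
statistical skeleton that the real inputs of such a study exhibit: blocks
clustered into dense neighborhoods with lognormal populations (median ≈
3,000/block); park areas lognormal with mean ≈ 10⁴ m², clamped to the
observed span of urban park inventories (10–687,237 m²); attribute presence
probabilities rising with log area through a single coupling parameter, with
an NDVI surrogate binarized at 0.2 for the `trees` flag; a nested TPU/DC
grid partition (every block in exactly one TPU, every TPU in exactly one
DC); and routes from either a lognormal detour factor (median 1.52,
σ-log 0.1, clamped at 1 so routes never undercut the chord) or a connected
grid street network with heterogeneous edge speeds.

The default coupling (1.1) was chosen so that the area–AI correlation on
generated inventories lands in the weakly-coupled regime (R² roughly
0.1–0.3) that real park audits show — strong enough that size is *some*
proxy for quality, weak enough that it is a demonstrably poor one, which is
the regime where the attractiveness term changes conclusions. Setting the
coupling to 0 gives the fully decoupled regime; tests exercise both ends.

What the generator does **not** emulate: real street topology (grid only),
spatially autocorrelated amenity placement, parks as polygons (centroids
only), shoreline/terrain barriers, or census-style heaping in populations.
Passing tests therefore demonstrate the *algebra and invariances* of the
framework on realistic marginals, not fidelity to any particular city.

## Problem sizes

The test suite runs the full pipeline on cities of 5–50 blocks and 6–40
parks, the invariance battery on 100 generated cities, the routing oracle on
graphs of ≤ 8 nodes (where exhaustive path enumeration is feasible), and the
factor-recovery regression on 2,000 origin–destination pairs; the one
full-scale computation is the 2,243 × 902 geometric matrix, which is a
single vectorized operation. These sizes were chosen so every property is
checked in seconds while still spanning the regimes (tiny exact cases,
Monte-Carlo recovery, degenerate inputs) that matter.

## Known limitations

* Route quality is only as good as the provider: the grid network is a
  caricature of real streets, and a cached provider inherits whatever
  error its source had.
* The attractiveness model is binary-presence only; it cannot distinguish
  one playground from five, and the equal within-category weight split is a
  simplification the audit literature does not justify per-attribute.
* Decay parameters are treated as universal constants; in reality they are
  population- and culture-specific, and age-group-specific weights are an
  obvious extension the API already permits but does not provide.
* PWP is an expectation under a choice model, not an observed behavior;
  validating it against survey or mobility data is outside this package.
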