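---
title: "Climatic niche evolution and historical biogeography on dated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climatic niche evolution and historical biogeography on dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicherange)
```

`nicherange` implements the comparative toolkit used to ask whether a clade's
present distribution was assembled by lineages tracking conserved climatic
tolerances through newly available habitat: continuous-trait evolution models
with phylogenetic-signal testing, ancestral niche reconstruction fed by
niche-model output, and time-stratified models of discrete geographic-range
evolution with stochastic mapping of the implied event history. Everything
operates on a rooted, ultrametric, time-calibrated phylogeny (ages in Ma).

The worked example throughout is the packaged data set for *Argylia*
(Bignoniaceae), an Andean plant genus of 13 taxa: a dated 13-tip tree,
weighted-mean values of 11 bioclimatic variables per species, tip codings
over four areas (A Pacific Coast, B Central Andes 20--33°S, C Central Andes
south of 33°S, D Patagonia), and a four-epoch time-slice scheme tracking
Andean uplift (50--35, 35--15, 15--5, 5--0 Ma).

## Models of continuous niche evolution

Let `C` be the phylogenetic covariance matrix: `C[i, j]` is the shared path
length (Ma) from the root to the MRCA of tips i and j. `fit_trait_model()`
fits four models of a single niche variable `x` by maximum likelihood:

* **BM** -- Brownian drift, `x ~ N(z0·1, σ²C)`. `z0` (root state) and `σ²`
  (rate, trait-units² per Ma) have closed-form GLS estimates; the ML rate
  uses divisor n.
* **OU** -- Ornstein--Uhlenbeck with pull `α` (1/Ma) toward an optimum and a
  fixed root: `Cov(i,j) = (σ²/2α)·exp(−α d_ij)·(1 − exp(−2α s_ij))` with
  `d_ij` the patristic distance and `s_ij` the shared time from the root to
  the MRCA. As `α → 0` this tends to BM; as `α → ∞` the tips decorrelate
  toward white noise. (Some writings index the second factor by the MRCA's
  age rather than by the shared time; only the shared-time form has the BM
  limit and a covariance that decreases with phylogenetic distance, so that
  is what is implemented.)
* **WN** -- white noise: iid `N(μ, σ²)`; no phylogenetic structure.
* **LAMBDA** -- Pagel's λ rescales the off-diagonal of `C`. λ = 0 is
  phylogenetic independence; λ = 1 is BM. The search range is
  `[0, λ_max]` where `λ_max` is the largest value keeping the rescaled
  matrix positive definite -- on real trees this exceeds 1, and published
  estimates above 1 are meaningful, so the search is *not* capped at 1.

Model comparison uses AIC = 2k − 2lnL (k = 2, 3, 2, 3 respectively) and
Akaike weights `exp(−0.5·ΔAIC)` normalised to sum 1; AICc is deliberately
not used because the weights being mirrored are defined through ΔAIC.
`lambda_signal_test()` compares the λ optimum against λ = 0 with a χ²(1)
likelihood-ratio test, truncating p at 1 when the statistic is non-positive.
λ = 0 lies on the boundary of the parameter space, where the asymptotic null
is strictly a 50:50 mixture of χ²(0) and χ²(1); the plain χ²(1) convention is
used because it is what the field's standard implementations report, making
p-values comparable with published tables. It is conservative.

Numerical strategy: rather than jointly optimising (z0, σ², α or λ) by
quasi-Newton, the package profiles z0 and σ² analytically (GLS) at every
value of the remaining parameter and optimises that single parameter by
golden-section search over several sub-brackets plus both endpoints. On
13-tip trees the OU and λ surfaces are extremely flat; the 1-D profiled
search is robust there and the reported optimum is a true maximum (the test
suite cross-checks λ estimates and likelihoods against an independent
implementation).

On the packaged data this reproduces the published qualitative pattern:
precipitation variables and temperature seasonality carry strong signal
(λ near or above 1, BM preferred), while most temperature means are best
described by white noise. Exact published λ values are *not* reproducible,
because only six of the twelve internal node ages were printed; the packaged
tree interpolates the rest evenly between their enclosing dated nodes and is
documented as an approximation.

## Ancestral niche reconstruction

`bm_ancestral_states()` gives the joint ML (GLS) ancestral estimate at every
internal node, a convex combination of tip values. Two rate estimators are
used on purpose: model *selection* uses the ML rate (divisor n), while
*confidence intervals* use the unbiased rate (divisor n − 1). With the
unbiased rate, the pivot for the root state is exactly Student-t with n − 1
degrees of freedom, so intervals use `qt(0.975, n − 1)` rather than a fixed
1.96. At n = 13 this is the difference between 92.6% and 95% coverage --
a fixed normal quantile demonstrably under-covers on trees this small,
which the calibration test in the suite (500 simulated data sets) would
catch.

`pno_ancestral()` propagates niche-model uncertainty: each tip's value is
drawn from its predicted niche occupancy (PNO) profile, a full
reconstruction (including re-estimation of σ²) is run per draw, and
per-node means and 2.5/97.5 percentiles are reported across draws. The
replicate count defaults to 1000 (configurable); the source material does
not state the value it used. `traitgram()` exports the (age, trait)
coordinates of nodes and edges for niche-space-through-time plots.

## PNO profiles

`compute_pno()` bins the climate values of all valid grid cells (equal
width, right-open except the last bin; 100 bins by default) and weights
each bin by the summed habitat suitability of its cells, normalised to
sum 1 -- so any positive rescaling of the suitability surface gives the
same profile. Grids are exchanged as plain-text ESRI-style ASCII rasters,
which keeps the pipeline dependency-light and the fixtures human-readable.
Profile statistics (weighted mean/SD, percentiles by cumulative-weight
interpolation) reproduce the "weighted mean derived from predicted niche
occupancy" summaries used in species-niche tables. The bin count is not a
sensitive choice: refining 100 → 1000 bins moves the weighted mean by less
than one coarse bin width (asserted in the suite).

## Range evolution

Ranges are subsets of discrete areas. Anagenesis is a CTMC on the subset
lattice: area k is gained at rate `d · Σ_{a ∈ range} m[a, k]` (with `m` the
epoch's dispersal multiplier matrix) and any occupied area is lost at rate
`e`; a single-area range collapses into an absorbing null range kept for
extinction bookkeeping and given zero observational probability at tips.
Cladogenesis redistributes the parent range over the two daughters:

| family | allowed events at widespread parents |
|---|---|
| DEC | subset sympatry; vicariance with one single-area daughter |
| DIVALIKE | any disjoint bipartition (widespread vicariance); no subset sympatry |
| BAYAREALIKE | the range is copied unchanged |

Single-area parents always speciate sympatrically. The +J variants add
founder-event speciation: one daughter keeps the parent range, the other
instantaneously colonises one outside area. Weighting follows the standard
convention of this model family: every allowed non-jump event carries
per-event weight (3 − j)/3 and every jump event carries weight j, with
probabilities normalised per parent state, so j = 0 reduces each +J model
to its base model exactly (a tested identity) and j is bounded in [0, 3).

The likelihood is Felsenstein pruning over the range states. Branches are
sliced at epoch boundaries and each segment propagated by `expm(Q·Δt)` with
that epoch's rate matrix; repeated exponentials reuse an eigendecomposition
of Q, with automatic fallback to scaling-and-squaring (`Matrix::expm`) when
the eigenbasis is ill-conditioned (equivalence to 1e-9 is asserted in the
suite). The root likelihood averages the conditional likelihoods under a
prior that is uniform over all non-null states. A prior restricted to
states with nonzero conditional likelihood was considered and rejected: its
normalising count changes with the parameters, which makes the likelihood
discontinuous in (d, e, j) and spuriously rewards degenerate corners of the
rate space where few root states remain reachable.

`fit_biogeo()` maximises over d, e (bounded in [1e-12, 5] per Ma) and j,
from several log-spaced starts, and computes per-node marginal range
probabilities by the standard conditional-times-outside two-pass
marginalisation. `compare_biogeo_models()` performs the nested χ²(1) LRTs
(+J vs base, p truncated at 1) and pairwise Akaike weights. The maximum
range size defaults to all areas, and per-epoch multiplier matrices default
to 1 everywhere; the study being mirrored stratified its dispersal
multipliers through four uplift epochs, but those matrices were published
only as supplementary material that is not reproduced here, so its printed
biogeographic log-likelihoods are treated as given inputs in the arithmetic
checks, not as recomputation targets.

## Stochastic mapping

`sample_history()` draws complete histories consistent with the fitted
model and the tips: node states from the joint smoothed distribution (root
from its marginal, descendants conditionally), then branch paths by
rejection sampling of forward CTMC trajectories conditioned on their
endpoint states (cap 1e5 attempts per branch; at the rates typical of
desk-scale data sets the acceptance probability is near 1, and the error
message points to uniformization as the fallback if a pathological case is
hit). Events are classified as within-area speciation (BAYAREALIKE-style
copy events at widespread parents are counted here, since the published
event tables carry no separate copy row), subset speciation, founder event,
vicariance, range expansion and range contraction; `bsm_summary()` reports
means, SDs and percentages over histories. Each history contains exactly
one cladogenetic event per internal node -- 12 on the packaged 13-taxon
tree -- which the suite asserts for every sampled history.

## The synthetic-data generators

`simulate_traits()` draws from the exact generating distributions of the
four trait models; `simulate_range_history()` runs the forward counterpart
of the range models (root drawn uniformly from the single-area states,
Gillespie simulation within epoch segments, cladogenesis at nodes) and
retains the full event log, so simulator bookkeeping can serve as an oracle
for the mapping summaries; `make_gaussian_raster()` builds
suitability surfaces with a known climatic optimum and breadth over any
climate grid. These generators emulate the *structure* of the real inputs
-- they do not emulate spatial autocorrelation of real climate rasters,
occurrence sampling bias, or phylogenetic uncertainty, so green simulation
tests certify the estimators, not the field pipeline upstream of them.

Calibration experiments in the test suite use sizes chosen to give stable
Monte-Carlo answers at desk scale: 200 replicates on a 64-tip balanced tree
for rate recovery and signal detection, 500 replicates for interval
coverage, and 20 replicates of 50-tip trees with three areas (d = 0.02,
e = 0.01, j = 1.5 where applicable) for dispersal-rate recovery and
founder-event power.

## Fixture provenance and known limitations

* The packaged tree fixes the six published node ages (38.21, 28.04, 25.77,
  19.25, 16.33, 9.76 Ma), resolves one six-taxon subclade as a ladder in
  the published listing order, and interpolates unprinted ages evenly.
  Quantities that depend on exact internal ages (published λ values, OU
  optima) are therefore only qualitatively reproducible.
* Tip-range codings were reconstructed from the published distributional
  prose, not from a machine-readable source. Two codings are genuinely
  ambiguous in the source and were resolved in favour of internal
  consistency with the published event budget: *A. radiata* is coded AC
  (its lineage is described as founding into the southern Central Andes and
  then expanding to the coast, with no range contraction reported) and
  *A. uspallatensis* B (its published event table admits exactly two range
  expansions, both attributed to other lineages). Under the alternative
  codings the fitted founder-event model places the root in BC and explains
  the tips by range contractions, contradicting the published root-state
  and event-count results.
* With flat dispersal multipliers the ML founder-event model mixes two
  near-equivalent explanations at two nodes (jump now vs expand later), so
  stochastic maps average ≈3.5 founder events where the source -- using its
  unpublished epoch multipliers -- reports exactly 3 with zero SD. The
  modal sampled history carries exactly 3 founders, 9 within-area
  speciations and 2 expansions.
* Polytomies are accepted for trait models (resolved arbitrarily is
  unnecessary: the covariance matrix is well defined) but rejected by the
  cladogenetic range models, which are defined on bifurcations.
* Bayesian range inference, distance-dependent dispersal (+x), fossil range
  constraints, multivariate trait models and measurement-error models are
  out of scope.

## A compact worked example

```{r example, eval = FALSE}
fx <- argylia_fixtures()

# Table-4-style signal report
signal_report(fx$tree, fx$traits)

# Range-evolution model comparison and stochastic mapping
fits <- lapply(c("BAYAREALIKE", "BAYAREALIKE+J"), function(m)
  fit_biogeo(fx$tree, fx$ranges, m, fx$epochs))
compare_biogeo_models(fits)
run_bsm(fits[[2]], n = 100, seed = 1)$summary
```
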