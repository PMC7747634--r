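---
title: "Quantifying community assembly across body sizes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly across body sizes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeassembly)
```

## The scientific question

Soil microbiome surveys repeatedly find that community composition varies
across space, but the *processes* behind that variation differ: stochastic
assembly (dispersal and ecological drift) versus deterministic assembly
(environmental selection). A long-standing hypothesis links the balance of
these processes to organism body size — small organisms (bacteria, ~1 µm)
disperse passively and abundantly, so their communities should look closer
to neutral expectations, while larger organisms (large protists, nematode
propagules up to ~1 mm) are dispersal-limited and more strongly filtered by
their environment.

`sizeassembly` implements the metric suite used to test this hypothesis on
rarefied sample-by-OTU count tables, plus a synthetic-study generator that
provides ground truth for every metric. The pipeline computes, per
taxonomic group:

1. **Distance-decay relationship (DDR)** — `fit_ddr()`
2. **β-null deviation (NDV)** — `ndv()`, `group_ndv()`
3. **Sloan neutral-model dispersal rate m** — `fit_sloan()`
4. **Outlying Mean Index (OMI) niche breadth** — `omi_per_otu()`
5. **Variation partitioning (environment vs space)** — `variation_partition()`
6. **Body-size scaling regressions** — `regress_on_size()`

## Models and estimators

### Distance-decay and halving-distance

Community similarity `S = 1 − BC` (Bray-Curtis) is regressed on geographic
distance on the log-log scale,

    log10 S = a + b log10 D,

by OLS over all unordered sample pairs (the field's convention, despite the
pseudo-replication it entails; a Mantel permutation test is available via
`fit_ddr(..., mantel = TRUE)` but off by default because the headline
statistics in this literature are regression ones). Log base 10 is forced by
the halving-distance formula, which exponentiates base 10:

    d_H = 10^((log10(s0/2) − a) / b),

the distance at which similarity falls to half its value at the 1 km
reference distance, with `s0 = 10^a`. Under that defining relation d_H
reduces to `10^(−log10 2 / b)`, which is how `fit_ddr()` computes it — this
stays valid even when a steep fit extrapolates `s0 > 1` (reported with a
warning). Pairs with `S ≤ 0` or `D < 1 km` are excluded with a logged count:
their logarithm is undefined, and 1 km is the floor that defines the
initial-similarity convention. Whether zero-similarity pairs should instead
enter via `log(S + c)` is undocumented in the source literature; exclusion
was chosen and is recorded in the fit object (`n_excluded`).

### β-null deviation

The abundance-based null model randomizes the community matrix while
preserving each sample's richness `R_j` and read total `N_j`: `R_j` distinct
OTUs are drawn with probability proportional to their *occurrence* counts,
each receives one read (this seeding is what guarantees exact richness
preservation), and the remaining `N_j − R_j` reads are distributed
multinomially with probabilities proportional to the selected OTUs' total
*abundances*, renormalized over the selected set so the multinomial is
well defined. The NDV of a sample pair is observed Bray-Curtis minus the
mean Bray-Curtis of (by default) 999 such null tables. NDV ≈ 0 means the
null explains the dissimilarity (stochastic assembly); values toward ±1
mean deterministic structure. Group-level NDV runs on each group's
sub-table with occurrence/abundance weights from that sub-table — the
self-contained choice; whole-table nulls restricted to group OTUs would be
an alternative the source description does not disambiguate.

### Sloan neutral model

The occurrence frequency of OTU *i* across local communities of size `N`
is predicted from its mean relative abundance `p_i`:

    Freq_i = 1 − I(1/N; N m p_i, N m (1 − p_i)),

where `I` is the regularized incomplete beta function — the beta *CDF* at
the detection threshold `1/N`. (The source text calls `I` a "probability
density function"; only the CDF yields probabilities in [0, 1], and the CDF
is the standard formulation, so that wording is treated as a misnomer.)
`m` is estimated by bounded least squares on (0, 1] with multi-start
(`nlminb` from 0.01, 0.1, 0.5 — the objective can be flat near the
boundaries). Fit quality is the generalized R² = 1 − SSerr/SStotal, not
clipped: poorly fitting groups legitimately score near or below zero.
Wilson 95% score intervals around the predicted frequencies classify OTUs
as above/within/below the neutral band, and `compare_binomial()` contrasts
the neutral AIC against a parameter-free binomial random-sampling model
(`Freq = 1 − (1 − p)^N`) over bootstrap resamples of the OTUs, using the
Gaussian least-squares AIC `n·ln(SSerr/n) + 2k`.

**Known accuracy limit.** The beta-CDF occupancy is a weak-immigration
diffusion approximation. Fitting it to the *exact* stationary occupancy of
the package's own birth-death simulator (solvable exactly: the chain is
reversible and tridiagonal) recovers m̂ ≈ 0.0235, 0.14 and 0.59 for true
m = 0.02, 0.1 and 0.3 at N = 1000. The estimator is therefore treated as an
*index* of dispersal: accurate near m ≤ a few percent, increasingly inflated
above that, but strictly monotone in the true rate — rank comparisons
across groups remain valid, which is how the body-size analysis uses it.

### OMI niche breadth

Environmental covariates are centered and scaled by their *population*
(divide-by-n) standard deviation — the convention of the duality-diagram
framework the OMI method comes from — and optionally rotated to full-rank
principal axes; the rotation is orthogonal, so OMI values are identical in
raw standardized space (a property the tests assert). An OTU's niche
position is the abundance-weighted mean of site coordinates; OMI is its
squared distance from the unweighted site mean. Low OMI = typical conditions
= wide niche breadth. Absolute OMI magnitudes depend on how many
environmental axes a study measures, so cross-study comparisons of raw
magnitudes are not meaningful; the package's tests target invariances and
ordered contrasts instead.

### Variation partitioning

Counts are Hellinger-transformed (the standard choice for RDA on abundance
data; the source is silent) and regressed on two blocks: forward-selected
environmental covariates and forward-selected spatial eigenvectors
(classical PCNM: distances truncated at the longest minimum-spanning-tree
edge, beyond-threshold entries replaced by 4× the threshold, positive
eigenvectors scaled by the square root of their eigenvalue). Forward
selection uses the double stopping criterion (permutation p < 0.05 *and*
cumulative adjusted R² below the global model's). Adjusted (Ezekiel) R² of
the models env, space, and env+space give pure, shared, and residual
fractions by subtraction; unadjusted fractions sum to 1 exactly by algebra,
adjusted ones by construction of the residual. Negative adjusted fractions
are reported as-is — they are a known, meaningful artifact of the
adjustment. Pure fractions are tested by permutation on the corresponding
partial RDA; the shared fraction is not testable. Duplicate site
coordinates are jittered by 1e-6 km with a warning (the MST truncation is
otherwise degenerate).

## The synthetic-study generator

`generate_study()` builds a world in which all of the above have known
answers:

* **Landscape** — `n_sites = 45` evenly spaced sites on a 4165 km
  north-south transect (the scale of a continental soil survey), with one
  environmental covariate = linear trend over `env_range = (0, 10)` plus
  Gaussian noise whose correlation decays as `exp(−d/1000 km)`. The
  noise standard deviation defaults to 10% of the range; the
  autocorrelation length is the one knob that controls how strongly
  environmental selection masquerades as spatial structure.
* **Metacommunity** — a lognormal rank-abundance vector per group
  (`sdlog = 1.2`, a typical amplicon-survey shape), 80 OTUs per group.
* **Local assembly** — a Moran-type zero-sum birth-death process: one
  individual dies per step and is replaced by a metacommunity immigrant
  with probability `m_true`, else by a local offspring. The immigrant pool
  is the metacommunity filtered by Gaussian niche weights
  `exp(−(env − µ_i)²/(2σ²))` with per-OTU optima µ_i uniform over the
  environmental range — so `m_true` tunes dispersal and `sigma_true` tunes
  selection in one process. Communities of `N = 5000` individuals run for
  50 generations (adequacy is checked against the exact multinomial
  stationary state at m = 1; parameter-recovery tests use ≥ 5/m
  generations, the mean-reversion timescale argument) and are rarefied to
  `depth = 2000` reads.
* **Size coupling** — eight groups with propagule sizes log-spaced over
  0.4–904 µm; by default `m_true` falls log-linearly from 0.5 to 0.02 and
  `sigma_true` from 8 to 0.8 environmental units as size grows. This
  encodes the hypothesis under test as ground truth. With
  `size_coupling = FALSE` all groups share the middle parameters — the
  null world used to check that the scaling regressions stay silent.

What the generator does *not* emulate: spatially explicit dispersal kernels
(all sites draw from one metacommunity, so distance decay arises only
through environmental autocorrelation plus selection), speciation and
diversification, sequencing error, compositional biases of PCR, or multiple
correlated environmental drivers. A green end-to-end test therefore
establishes that the estimators recover the *direction* of a known
dispersal/selection gradient — not that any particular field system obeys
it.

## Numerical choices and degenerate inputs

* Rarefaction is hypergeometric (without replacement), deterministic given
  a seed; samples below depth are an error listing the offenders.
* Chao1 uses the classic `S + F1²/(2F2)` form, switching to the
  bias-corrected `S + F1(F1−1)/(2(F2+1))` only when F2 = 0 (divide-by-zero
  guard).
* Geographic distances are haversine on a 6371 km mean-radius sphere.
* The dominant-group filter keeps groups with pooled relative abundance
  ≥ 1% *and* presence (≥ 1 read of any member OTU) in ≥ 80% of samples,
  computed on the rarefied table; presence at group level is defined as
  ≥ 1 pooled read because the pooled-abundance semantics make that the
  consistent reading. The filter is applied per study table; whether the
  source applied it per kingdom or to a combined table is unstated, and
  per-table is the default here.
* Per-group Sloan fits re-rarefy the group sub-table to its minimum
  positive row sum so that `N` is well defined within the group.
* All Monte-Carlo stages take explicit seeds; `run_pipeline()` derives
  per-stage sub-seeds from one master seed and logs them in a run manifest.

## Known limitations

* The Sloan m estimate is biased upward outside the weak-immigration
  regime (see above); treat cross-group comparisons, not absolute values,
  as the deliverable.
* Classical PCNM eigenvectors on a regular transect only approximate
  cosine waves (correlation ≈ 0.88 with a half-cosine for the first
  vector); graph-Laplacian MEM variants would be exact but are a different
  published recipe than the one implemented.
* All-pairs DDR regression inherits the field's pseudo-replication; its
  p-values are anti-conservative and should be read as descriptive.
* The NDV's occurrence/abundance-weighted null is one of several published
  abundance-based nulls; deviations are comparable only across tables
  analyzed with the same null.
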