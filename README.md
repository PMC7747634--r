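# sizeassembly

Quantify the balance between stochastic (dispersal, drift) and
deterministic (environmental selection) community assembly across organism
body sizes, from rarefied sample-by-OTU count tables.

Soil biodiversity surveys spanning bacteria (~1 µm propagules) to nematodes
(~1 mm) repeatedly suggest that *body size* sets how communities assemble:
small organisms disperse passively and look near-neutral, large organisms
are dispersal-limited and environmentally filtered. `sizeassembly` packages
the metric suite used to test this hypothesis, plus a synthetic-study
generator with tunable neutral vs niche assembly so that every estimator can
be validated against ground truth.

Per taxonomic group (phylum-level groups passing a ≥1% pooled abundance,
≥80% presence dominance filter), the pipeline computes:

* **Distance-decay relationship** — OLS of log10 Bray-Curtis similarity on
  log10 geographic distance, `log10 S = a + b log10 D`, with initial
  similarity `S0 = 10^a` (at 1 km) and halving-distance
  `d_H = 10^((log10(S0/2) − a)/b)`, the distance at which similarity halves.
* **β-null deviation (NDV)** — observed Bray-Curtis minus its mean over 999
  randomized tables that preserve each sample's richness and read total
  (OTUs drawn by occurrence weights, reads by abundance weights). NDV ≈ 0
  indicates stochastic assembly; values toward ±1 indicate determinism.
* **Sloan neutral-model dispersal rate** — least-squares fit of observed
  occurrence frequencies to
  `Freq_i = 1 − I(1/N; N·m·p_i, N·m·(1−p_i))` (`I` = regularized incomplete
  beta), with Wilson 95% bands, generalized R², and a bootstrap AIC
  comparison against binomial random sampling.
* **OMI niche breadth** — squared distance between an OTU's
  abundance-weighted mean environmental position and the study-area mean, in
  population-standardized (optionally PCA-rotated) environmental space.
* **Variation partitioning** — Hellinger-RDA of composition on
  forward-selected environmental covariates and PCNM/MEM spatial
  eigenvectors, reported as Ezekiel-adjusted pure/shared/residual fractions
  with permutation tests.
* **Body-size scaling** — OLS of each assembly metric on log10 body size
  (µm), overall and within kingdoms, plus one-way ANOVA with Tukey HSD and
  compact letter displays for group contrasts, and a batch harness
  (`meta_batch()`) for pooling NDVs across studies by ecosystem.

## Worked example

Generate a synthetic 30-site study whose eight groups span 0.4–904 µm with
dispersal decreasing and selection increasing in body size, then run the
pipeline and the scaling regression:

```r
library(sizeassembly)

cfg <- simulation_config(n_sites = 30, n_otus_per_group = 60, depth = 1000,
                         n_individuals = 2000, generations = 20, seed = 42)
st  <- generate_study(cfg)
st
#> synthetic_study: 30 sites x 480 OTUs (8 groups), depth 1000

gm <- run_pipeline(st, n_reps = 199, seed = 7,
                   stages = c("ddr", "ndv", "neutral", "omi"))
gm[, c("group", "size_um", "mean_ndv", "m", "mean_omi", "ddr_slope")]
#>   group size_um mean_ndv      m mean_omi ddr_slope
#> 1   G01    0.40  -0.0964 1.0000    0.168   -0.0082
#> 2   G02    1.21  -0.0495 1.0000    0.125   -0.0346
#> 3   G03    3.63  -0.0281 1.0000    0.186   -0.0910
#> 4   G04   11.00   0.0503 0.7500    0.422   -0.4190
#> 5   G05   33.00   0.0470 0.6160    0.747   -0.5480
#> 6   G06   99.50   0.0731 0.1980    0.680   -0.9820
#> 7   G07  300.00   0.0867 0.0915    0.939   -1.2100
#> 8   G08  904.00   0.0717 0.0418    0.782   -1.1300

regress_on_size(gm, "mean_ndv")
#>   scope     slope   intercept r_squared      p_value n
#> 1   all 0.0536072 -0.04922113 0.8587003 0.0009327146 8

regress_on_size(gm, "m")
#>   scope      slope intercept r_squared      p_value n
#> 1   all -0.3426265  1.025368 0.9178037 0.0001791717 8
```

Read: the null deviation rises from ≈ −0.1 (bacteria-sized groups,
indistinguishable from the stochastic null) to ≈ +0.09 for the largest
groups (deterministic structure), while the fitted dispersal rate falls from
1.0 to 0.04 and the distance-decay slope steepens from −0.008 to −1.1 —
the size-scaling signature the simulation encodes, recovered with
significant positive (NDV) and negative (m) regressions on log10 size.

Real studies enter the same way: `read_count_table()` (TSV or classic
dense-BIOM text), `read_metadata()` (CSV with `sample_id`, `latitude`,
`longitude` and environmental covariates), `read_taxon_map()` and
`read_body_sizes()`, then `rarefy()` and `run_pipeline()`.

See `vignettes/community-assembly-methods.Rmd` for the models, their
assumptions, what the generator does and does not emulate, and known
accuracy limits (in particular the upward bias of the Sloan m estimate
outside the weak-immigration regime).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analysis from scratch: it generates the
default 45-site synthetic study at the given seed, runs the full pipeline
(distance-decay, β-null deviation, neutral fit, OMI, variation
partitioning), prints the four body-size scaling regressions to the
console, and writes the JSON report to `--out`.
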