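# microassembly

Community assembly, co-occurrence and topological analysis of microbiome
OTU tables.

Large-scale amplicon surveys — the motivating case is prokaryotic
communities in mangrove sediments sampled along thousands of kilometres of
coastline — pose a recurring set of questions: how much of community
turnover is stochastic (dispersal and drift) versus deterministic
(environmental selection)? Do taxa with different traits (abundant vs
rare, habitat generalists vs specialists) assemble differently? Which taxa
occupy structurally important positions in the co-occurrence network, and
where do locations, taxa and functional guilds concentrate on the
topology of the data? `microassembly` implements that analysis as a
tested, reusable pipeline for ecologists working from an OTU count table
and sample metadata, with a synthetic-data generator so every stage is
verifiable by parameter recovery — no sequence data required.

## What it computes

* **Trait partitions** — abundant (>1% relative abundance in ≥1 sample)
  vs rare OTUs; generalists and specialists as the top/bottom 10% of the
  Levins niche breadth *B<sub>j</sub>* = 1 / Σ<sub>i</sub> q<sub>ij</sub>²,
  with all minimum-*B* OTUs forced into the specialist set.
* **Distance decay** — OLS of pairwise Bray–Curtis similarity on log10
  haversine distance, with a Mantel permutation p alongside.
* **Sloan neutral community model** — occurrence frequency fitted to
  *F(p)* = 1 − *I<sub>d</sub>*(*Nm·p*, *Nm*(1−*p*)) by bounded
  Levenberg–Marquardt NLS; reports *Nm*, *m*, *R*², and the per-OTU 95%
  envelope partition.
* **Canonical correspondence analysis** — constrained proportion,
  marginal permutation tests per factor, CCA-based variation
  partitioning.
* **SparCC networks** — compositional correlations from log-ratio
  variances with Dirichlet resampling and strong-pair exclusion;
  permutation p-values; edges at |r| > 0.6 and p < 0.05; degree,
  betweenness, harmonic closeness, clustering; hub (top-30% degree +
  betweenness) and keystone (top-30% degree + closeness, bottom-30%
  betweenness) taxa; per-pathway function overlay.
* **Mapper/SAFE** — a topological network of sample clusters built over
  an MDS lens (resolution 40, overlap 0.75, min cluster 2, eps at the
  98th distance percentile) with permutation-based SAFE enrichment
  scores per metadata/taxon/function variable.
* **Synthetic data** — beta-multinomial neutral tables with known *Nm*,
  planted spatial gradients, habitat specialists and correlated taxon
  blocks.

## Worked example

```r
library(microassembly)

spec <- neutral_sim_spec(n_taxa = 300, n_samples = 60, depth = 10000,
                         Nm = 1000, seed = 11)
neutral <- simulate_neutral_table(spec)
rar <- rarefy(neutral, 10000, seed = 13)

trait_summary(trait_partition(rar))
#>        class   n pct
#> 1   abundant  42  14
#> 2       rare 258  86
#> 3 generalist  30  10
#> 4 specialist  30  10

fit_ncm(rar)
#> Sloan NCM fit: Nm = 1073 (m = 0.1073), R2 = 0.972, d = 6.93e-05
#>   297 OTUs over 60 samples; above/within/below 95% CI: 81/204/12

metadata <- simulate_coastline_metadata(60, seed = 11)
spatial <- plant_gradient(neutral, metadata, strength = 0.001, seed = 12)
distance_decay_fit(community_similarity(spatial),
                   pairwise_distance_km(metadata), seed = 14)
#> Distance-decay fit (log10_distance): slope = -0.1728, r = -0.606, n_pairs = 1770
#>   P(OLS) = 1.24e-177, P(Mantel) = 0.001
```

The trait table reports group sizes with their percentages of all OTUs.
The neutral fit recovers the generator's *Nm* = 1000 to within ~7% with
*R*² = 0.97 — the community is consistent with dispersal and drift — and
the planted 0.001/km gradient produces the expected significant negative
distance-decay slope. On a niche-structured community the same fit
collapses (*R*² near or below zero), which is the diagnostic contrast the
pipeline is built around.

The full pipeline (rarefaction → traits → decay → NCM → CCA → SparCC
network and roles → Mapper/SAFE) runs from one configuration:

```r
run_pipeline(default_run_config(seed = 1), outdir = "run")
```

or from the shell via `Rscript inst/scripts/run_pipeline.R --config
cfg.yaml --outdir run`. Artifacts are TSV/JSON plus a manifest (config
hash, seeds, versions); reruns are byte-identical.

## Layout

```
R/                      implementation (tables_io, synthetic_data, traits,
                        assembly, ordination, sparcc + network, tda_safe,
                        pipeline)
tests/testthat/         unit, property and acceptance tests with
                        brute-force oracles in helper files
vignettes/              methods vignette: models, parameters, design
                        decisions, limitations
scripts/acceptance.R    headline-quantity reproduction script
inst/scripts/           thin command-line wrapper for run_pipeline()
```
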