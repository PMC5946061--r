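# ladco

Differential lamina-associated-domain (LAD) and pioneer-factor co-occupancy
analysis for two-condition ChIP-seq experiments, in R.

## The problem

In aging and laminopathy-model livers, broad genomic domains attached to the
nuclear lamina (LADs, marked by lamin B1 and repressive H3K9 methylation) are
partially lost, and the pioneer transcription factor Foxa2 gains binding
sites preferentially where lamina contact disappears. Quantifying that
interplay takes a chain of analyses that are usually stitched together ad
hoc: broad-domain calling from lamin B1/H3K9me3 tags, punctate peak calling
for the factor, shared-versus-exclusive classification across conditions,
overlap enrichment of binding sites inside domains against a matched random
background, local coverage-loss statistics around sites, and nearest-gene /
expression integration. `ladco` packages that chain as tested, tidyverse-style
building blocks plus a one-call pipeline, together with a ground-truth
synthetic data generator so every stage can be validated end to end without
any external download.

## Methods at a glance

* **Tag processing** — coordinate-level deduplication, seeded downsampling
  for depth equalization, strand-aware fragment extension, 5'-anchored
  binned coverage with counts-per-million normalization, and replicate
  Pearson correlation over a caller-supplied region universe.
* **Broad domains (islands)** — SICER-style calling: tag counts in
  non-overlapping windows (default 10 kb), a Poisson eligibility filter
  (smallest count `l0` with `P(X >= l0 | lambda_bg) < p0`), islands
  assembled by bridging up to `gap` ineligible windows (default 3), then a
  control-based Poisson upper-tail test per island with Benjamini–Hochberg
  FDR.
* **Punctate peaks** — candidate bins selected on pooled chip+control
  extended-fragment counts against a genome-wide Poisson tail, merged into
  regions and tested with an exact binomial tail
  `P(X >= chip | n = chip+control, theta = total_chip/(total_chip+total_control))`,
  BH-adjusted.
* **Co-occupancy** — two-way shared/exclusive (Venn) classification with
  both overlap directions reported, and overlap enrichment of sites inside
  a domain set versus chromosome- and length-matched random regions, tested
  with a two-sided Fisher's exact test (`[[k_obs, n-k_obs], [k_bg, n-k_bg]]`).
* **Coverage statistics** — site-centered profile matrices and average
  profiles, and windowed coverage-sum comparisons such as the fraction of
  sites whose 10 kb lamin B1 sum is higher in one condition.
* **Genes** — single-nearest-TSS assignment (GREAT's "single closest gene"
  mode), TSS-distance binning (0–5, 5–50, 50–500, >500 kb), and
  direct-target calling by expression fold change (> 2 up, < −2 down).

## Worked example

```r
library(ladco)

sim <- simulate_experiment(sim_config(seed = 1))   # 40 Mb genome, 7 libraries
fixture <- tempfile(); write_fixture(sim, fixture)
res <- run_pipeline(pipeline_config(fixture, seed = 1))
res
#> <lad_pipeline> seed 1
#>   domains: lamin_a=9, lamin_b=9, h3k9_a=9, h3k9_b=10
#>   peaks: tf_a=14, tf_b=48 (45 gained)
#>   enrichment: 32/45 vs 8 background, Fisher p = 5.72e-07
#>   lamin sum higher in A at 93.3% of gained sites
```

The printed lines mirror the scientific questions: 9 lamin B1 domains are
called per condition (6 of 9 shared — the generator planted 6 shared and 3
exclusive per condition); the factor gains 45 peaks in condition B; gained
peaks sit inside condition-A LADs far more often than matched random
regions (32/45 vs 8/45, Fisher p ≈ 6e-7); and at ~93% of called gained
peaks (96% of ground-truth gained sites) the 10 kb lamin B1 coverage sum is
higher in condition A — local lamina loss accompanies factor gain.

Each stage is also usable alone and returns tibbles or objects with
`tidy()`/`glance()`/`autoplot()` methods:

```r
lads <- call_domains(deduplicate_tags(sim$libraries$lamin_b1_a),
                     deduplicate_tags(sim$libraries$input),
                     sim$config$layout)
glance(lads)
cov <- binned_coverage(sim$libraries$lamin_b1_a, sim$config$layout,
                       100, normalize = TRUE)
autoplot(profile_matrix(lads, cov, flank = 5e4, nbins = 100))
```

## Vignette

`vignettes/ladco-methods.Rmd` documents the statistical models, parameter
choices, the structure the synthetic generator does and does not emulate,
and known limitations.
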