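---
title: "Models and methods behind ladco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ladco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladco)
```

`ladco` analyses two-condition ChIP-seq experiments in which broad
lamina-associated domains (LADs) and punctate pioneer-factor binding sites
are compared across conditions — young versus old tissue, wild-type versus
a laminopathy model. This vignette explains the statistical models, the
parameters that matter, the synthetic data the package validates itself
against, and the limits of both.

## Coordinate model and tag processing

All intervals are 0-based half-open (BED convention); adjacency is not
overlap, and chromosome names match exactly. A *tag* is the mapped
footprint of one read; its 5' position (start on the + strand, last base on
the − strand) is the counting anchor throughout, matching window-based
broad-domain callers that work on unshifted tag starts. Alternate
conventions (midpoint anchoring) would move counts by at most one bin and
are deliberately not offered as silent defaults.

Deduplication keeps one tag per (chromosome, start, strand), the
coordinate-level analogue of alignment-level duplicate marking; it assumes
mapping-quality filtering happened upstream. Depth equalization is plain
uniform downsampling without replacement, seeded, because the comparative
statistics downstream (binomial chip-vs-input, windowed-sum comparisons)
presuppose comparable library sizes. Fragment extension is 3'-directed to
the library insert size — 150 bp by default for every assay, since only the
factor library's insert is typically known; the value is a per-call
argument.

Replicate correlation is the Pearson r of per-region summed coverage. The
region universe is an explicit argument (e.g. the union of called domains,
filtered to ≥ 50 bp) rather than a built-in tiling: published correlation
values of this kind depend entirely on that universe, so the package
refuses to guess it.

## Broad-domain (island) calling

Lamin B1 and H3K9me3 enrichment comes in hundreds-of-kilobase domains, not
peaks. The caller follows the SICER/epic island construction:

1. Tag counts in non-overlapping windows of `window_size` (default 10 kb)
   tile each chromosome.
2. The background rate is
   `lambda_bg = total_tags * window_size / (genome_length * effective_genome_fraction)`
   with `effective_genome_fraction = 0.8` by default (the fraction of the
   genome treated as mappable). A window is *eligible* when its count
   reaches the smallest `l0` with `P(X >= l0 | lambda_bg) < p0`; the
   eligibility tail `p0 = 0.2` is the island-filtering default of the
   cited algorithm family.
3. Eligible windows separated by at most `gap_size` ineligible windows
   (default 3 windows, i.e. 30 kb) join into one island. The gap is in
   windows, not bases, matching the parameter semantics of the tools this
   caller emulates.
4. Each island is scored against the input-chromatin control: expected
   chip count = island control count scaled by the ratio of library
   totals, floored at one control-tag equivalent so an empty-control
   island cannot produce p = 0; p is the Poisson upper tail and q its
   Benjamini–Hochberg adjustment over all candidate islands; islands with
   `q < fdr` (default 0.05) are reported. Significance is control-based
   rather than the random-background E-value mode because an input library
   is part of the design.

Chromosome-end windows keep their true (shorter) width but share the global
`lambda_bg`; at both toy and genome scale the effect on calls is
negligible. The island score is the sum over eligible windows of
`-ln P(count; lambda_bg)`, useful for ranking but not for inference — the
control-based q is the inferential quantity.

## Punctate peak calling

The factor caller is a deliberately simple, fully testable two-stage
procedure rather than a reimplementation of any published tool:

1. Both libraries are extended to fragment length and counted per
   `bin_width` (50 bp) bin — a fragment contributes to every bin it
   overlaps. Candidate bins are those whose **pooled** chip + control
   count beats the genome-wide Poisson tail at `candidate_p0` (1e-4);
   candidate bins within `merge_gap` (100 bp) merge into regions and
   regions narrower than `min_peak_width` (100 bp) are dropped.
2. Each region is tested with the exact binomial tail
   `P(X >= chip | n = chip + control, theta = total_chip / (total_chip + total_control))`,
   BH-adjusted over the candidates; `q < fdr` is reported, with the summit
   at the base of maximal extended-fragment chip coverage.

Selecting candidates on the pooled count is the load-bearing design
choice. Selecting on the chip count alone — the obvious construction —
biases the subsequent chip-vs-control comparison: regions are chosen
*because* chip is high, so their binomial p-values are anti-conservative
and the nominal FDR does not control the false-call rate (in null
simulations roughly a fifth of runs produced a spurious peak). Conditional
on the pooled total `n`, the chip share is Binomial(`n`, theta) under the
null *independently of any selection that only looks at the pooled
total*, so pooled selection leaves the region p-values exactly valid and
the BH step's weak family-wise control makes "no peaks from null data" hold
at the nominal rate. The cost is that candidate discovery also responds to
control-library fluctuations; those candidates are then discarded by the
binomial test.

Equal-depth comparisons across conditions are the caller's precondition,
not its job: downsample first (the pipeline does this automatically per
assay pair).

## Co-occupancy statistics

Shared/exclusive classification counts, for two internally merged region
sets, how many A regions overlap (≥ 1 bp) any B region and vice versa.
The two directions differ whenever one broad region spans several on the
other side, so both are reported; when a single "shared" number is needed
the A-side count is the convention, with the B-side count retained in the
result.

Overlap enrichment asks whether sites fall inside a domain set more often
than chance. The background preserves exactly what the construction it
mirrors preserves — chromosome and length: each site is re-placed uniformly
on its own chromosome, optionally avoiding an exclusion set (assembly
gaps). G/C content and mappability structure are *not* matched; with a
homogeneous background model that is the correct null, and on real data it
is the user's responsibility to judge whether a composition-matched null
(as in GAT or regioneR) is needed instead. The default is a single
background draw, the faithful analogue of the published construction;
`n_draws > 1` averages background overlap counts (rounded) for variance
reduction. The 2×2 table `[[k_obs, n-k_obs], [k_bg, n-k_bg]]` is tested
two-sided by Fisher's exact test, computed in-package by hypergeometric
enumeration over the support (probabilities no larger than the observed
table's, with the customary 1e-7 relative tie tolerance); the odds ratio is
the sample odds ratio with the Haldane–Anscombe 0.5 correction on zero
cells.

## Site-anchored coverage statistics

Coverage tracks are per-chromosome bin-count vectors, optionally
normalized to counts per million mapped tags; bin counts are treated as a
piecewise-constant per-base density, so sums over arbitrary windows are
exact integrals of that density and partial bins contribute
proportionally. A profile matrix has one row per site and `nbins` columns
spanning `[midpoint - flank, midpoint + flank)`; each cell is the mean
per-base coverage in its column bin, so row sums times the column width
reproduce windowed sums exactly (a conservation property the tests check
to 1e-6 relative). Windows clipped at chromosome ends are zero-padded.
Row order follows input site order; an ngs.plot-style sort by descending
row sum sits behind `sort_rows`.

"A 10 kb region surrounding the site" is read as *total width* — ±5 kb
around the site midpoint — and likewise 5 kb means ±2.5 kb; the alternative
per-side reading is one argument away (`window = 2e4`). In the
fraction-of-sites-higher statistic, ties count as *not higher*, the
conservative choice; swapping conditions therefore yields the
strictly-higher-B fraction, not one minus the A fraction.

## Gene assignment

Sites map to the single nearest TSS by `|site midpoint − TSS|` on the same
chromosome, strand ignored, unassigned beyond 10,000 kb — the "single
closest gene" mode of regulatory-domain tools, without their basal-domain
extensions. Equidistant ties resolve to the lexicographically smallest
gene id so results are order-independent. TSS distances bin into
`[0,5)`, `[5,50)`, `[50,500)` and `≥ 500` kb, lower-inclusive. Direct
targets are bound genes passing a signed linear fold-change threshold
(> 2 up, < −2 down, each gene counted once); a switch accepts log2 inputs
with thresholds ±1. Bound genes absent from the expression table are
excluded and reported rather than silently dropped.

## The synthetic study

`simulate_experiment()` generates the package's validation world: a 40 Mb
genome (2 × 20 Mb), chosen so a full seven-library run at 2×10^5 reads per
library completes in well under a minute while every statistic retains
useful power. Condition A carries 9 LADs (300–800 kb, 3-fold enrichment
over a homogeneous Poisson background) of which condition B keeps 6 and
loses 3, gaining 3 of its own; H3K9me3 domains cover the central half of
each LAD. The factor binds 150 sites in condition B (200 bp, 10-fold point
sources whose fragments pile on the site center with strand asymmetry, as
in real ChIP-seq); 50 are shared with condition A and 100 are gained, and
90% of gained sites sit where lamina contact is lost — half in wholly lost
domains, half in retained domains where the generator erodes a 10 kb
window of condition-B lamin (and H3K9me3) signal around the site. A third
of the 300 genes have TSSs within 5 kb of gained sites, and those genes
are up-regulated (fold change > 2) with probability 0.6, down with 0.1.
Library sizes are Poisson around the target; everything is deterministic
given the seed.

Domain boundaries are placed on the 10 kb calling-window grid and separate
domains sit ≥ 50 kb apart. Both are generator conventions, not caller
assumptions: broad-domain boundaries are only defined to caller resolution
anyway, and the separation keeps distinct planted domains from being
legitimately bridged into one island, which would make base-level truth
accounting ambiguous rather than wrong.

What the generator does *not* emulate — G/C and mappability structure,
fragment-size variation, replicate structure, chromatin-state
autocorrelation beyond the planted domains — bounds what passing tests
mean: they demonstrate the statistics are computed correctly and recover
truth under a homogeneous background, not that defaults are tuned for any
particular real genome.

## Numerical and degenerate-input conventions

Poisson and binomial tails come from `ppois`/`pbinom` (upper tails as
`P(X >= k)`); BH from `p.adjust`; both are oracle-checked against direct
summation to 1e-10 in the test suite. Degenerate inputs fail loudly where
a silent answer would mislead: correlation over fewer than two regions or
zero variance, empty site sets for enrichment or windowed comparisons,
averaging an empty profile matrix, peak calling without a control, and
unmerged inputs to the Venn/enrichment routines (merge first) are all
errors. Empty *results* — no candidate islands, no peaks — are empty
tibbles, not errors. Expected island counts are floored at one control-tag
equivalent; q-to-BED scores cap at 1000.

## Pipeline problem sizes

The default pipeline and the acceptance script run on the default
synthetic study: 40 Mb, seven libraries of ~2×10^5 reads, 10 kb domain
windows, 50 bp peak bins, 100 bp coverage bins. The test suite's
stochastic calibrations use 100–200 seeded replicates of scaled-down null
configurations (2–10 Mb genomes, 2×10^4 reads); these sizes give the
binomial consistency checks their stated power while keeping a full run in
minutes.

## Known limitations

* The peak caller is not a reimplementation of any published two-pass
  simulated-background method; it trades that machinery for exact,
  verifiable error control.
* The enrichment background matches chromosome and length only.
* Nearest-TSS assignment ignores strand and regulatory-domain models.
* Coverage integrals assume within-bin uniformity; sub-bin structure is
  invisible at the chosen bin width.
* The replicate-correlation region universe must be supplied; published
  values are not reproducible without knowing theirs.
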