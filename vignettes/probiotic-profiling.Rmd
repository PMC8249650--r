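---
title: "Profiling strain replication, sRNAs and co-expression from community sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling strain replication, sRNAs and co-expression from community sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(strainprofiler)
```

When a sequenced bacterial strain — say an ingested probiotic — lives in a
complex community, shotgun metagenomic and metatranscriptomic reads that map
*uniquely* to its genome carry a surprising amount of information: whether
the population is actively replicating, which genes and small regulatory
RNAs (sRNAs) it expresses, and how that expression reorganizes across
conditions. This package implements the computational side of such a
profiling study as reusable, tested components, and ships simulators for
every input so that each stage can be validated against known ground truth
without any sequencing data.

## Replication rate as a peak-to-trough ratio

In a growing bacterial population, cells are caught at all stages of
bidirectional chromosome replication, so DNA near the replication origin
(*ori*) is over-represented relative to DNA near the terminus (*ter*). The
ratio of sequencing coverage at the origin to coverage at the terminus —
the peak-to-trough ratio (PTR) — therefore increases with the population
growth rate; a non-replicating population has PTR 1.

`ptr_fit()` estimates the PTR in five steps:

1. **Origin prediction from sequence alone.** The cumulative GC skew
   (per-window `(G - C) / (G + C)`, accumulated around the circle) attains
   its minimum at *ori* and its maximum at *ter*, because leading strands
   are G-rich. `cumulative_gc_skew()` implements this walk on the whole
   sequence. Classical origin finders use DNA walks on third codon
   positions of coding sequences; we deliberately use the whole-sequence
   walk, which needs no gene models and has the same extremum logic. The
   convention is configurable (`orientation = "max_ori"`) for genomes with
   the opposite strand bias, and `examples` below show the prediction is
   accurate to a fraction of a percent of genome length on simulated
   3 Mb-scale chromosomes with realistic skew (0.3).
2. **Binning.** Coverage is averaged in 10-kb bins (`bin_coverage()`);
   positions absent from the track count as zero, and a final partial bin
   keeps its true length.
3. **Outlier removal.** Bins more than 2 population standard deviations
   from the mean bin coverage are dropped in a single pass
   (`filter_outlier_bins()`); this removes phage insertions, repeats and
   deletions rather than genuine gradient structure. Mean and SD are taken
   over all bins *before* any removal, and a zero-SD guard keeps constant
   coverage intact.
4. **Smoothing.** The kept bins are lowess-smoothed (span 0.3, one
   robustness iteration). The predictor is the *circular distance of each
   bin midpoint from the predicted origin* rather than the raw bin index:
   the expected log-coverage declines linearly from *ori* to *ter* along
   both replichores, so folding the circle at the origin overlays the two
   arcs onto one axis along which the trend is monotone. A local-linear
   smoother evaluated at the apex of a tent-shaped series underestimates
   the peak by several percent at span 0.3 — enough to bias a PTR of 2
   down to roughly 1.8 — whereas on the folded axis there is no interior
   kink and the fit is essentially unbiased. Index-based smoothing
   remains available via `smooth_lowess(center = NULL)`.
5. **The ratio.** The peak is the smoothed value of the bin containing the
   skew-predicted origin; the trough is the smoothed minimum, wherever it
   falls. Taking the trough data-driven (rather than at the skew
   terminus) lets `trough_vs_skew_ter_distance` serve as an internal
   consistency check: on clean data the coverage trough should land near
   the skew-predicted terminus. A PTR below 1 usually means the origin
   prediction failed for this genome; the value is reported with a
   warning, never clamped.

```{r ptr-demo}
L <- 4e5
sim_g <- simulate_genome(L, ori = 1e5, ter = 3e5, skew_strength = 0.3,
                         seed = 1)
sim_c <- simulate_replication_coverage(L, ori = 1e5, ter = 3e5, ptr = 1.5,
                                       mean_depth = 50, seed = 1)
fit <- ptr_fit(sim_c$track, sim_g$genome)
summary(fit)
plot(fit)
```

### The coverage generative model

`simulate_replication_coverage()` draws depth whose expectation is
log2-linear in circular distance from the origin — `log2(ptr)` above the
trough level at *ori*, declining linearly to the trough at *ter* — which is
exactly the gradient shape the PTR statistic presumes, and the standard
model of replication-driven copy-number gradients. The trough level is
scaled so the genome-wide mean equals `mean_depth`, and
`expected(ori)/expected(ter) = ptr` holds exactly by construction. Noise is
Poisson per 100-bp chunk by default (negative binomial optional, per-base
via `bin_size = 1`); since 10-kb bin means average thousands of positions at
50x depth, counting noise on bins is small (~0.1% relative), and estimator
error is dominated by origin mis-location, which the skew predictor keeps
to a few kb.

Verified behaviour at these study conditions (3 Mb genome, 50x, 10-kb
bins, 20 replicates per grid point; computed in the test suite and
`scripts/acceptance.R`): median absolute PTR error below 0.01 across true
PTR 1.0–2.0, flat coverage returning PTR 1.000, and the estimate strictly
increasing in the true PTR. Note what the simulator does *not* emulate:
strain mixtures, mapping bias, GC-dependent coverage waves, or draft
(unordered-contig) references — passing tests show correctness of the
estimator under the gradient model, not robustness to those artefacts.

## Read filtering and unique-read quantification

`filter_reads()` applies the standard raw-read rules in order: discard
reads with more than 2 ambiguous `N` bases, trim 3' bases below Q20, then
discard reads shorter than 16 nt. The quality floor is a declared default
(the trimming direction — 3' only — matters more than its exact value);
adapter clipping is assumed done upstream. The filter is idempotent.

Strain-specific quantification deliberately uses only uniquely aligned
reads (`extract_unique()`, `n_hits == 1` in the alignment summary):
closely related genomes share so much sequence that multi-mapped reads
mostly measure conservation, not abundance. "Unique" is defined by the
aligner's reported hit count rather than a MAPQ threshold, matching how
alignment summaries are usually exported. `rpkm()` and `tpm()` implement
the standard length- and library-normalized measures, and
`aggregate_taxa()` rolls relative contig abundances up a lineage table,
conserving per-sample totals exactly.

## sRNA discovery from stranded coverage

Bacterial sRNAs (typically 50–600 nt) appear in strand-specific RNA-seq
as sharp coverage peaks in three kinds of places: between genes
(intergenic), inside a gene on its coding strand (intragenic), or across a
gene on the opposite strand (antisense). `detect_peaks()` calls maximal
runs above a per-position threshold:

* outside same-strand genes the seed threshold is `min_depth` (default
  10x) and the run must also exceed `min_fold` (default 5) times the
  local background median over a 2-kb flank, run excluded;
* inside a same-strand gene the threshold is `min_fold` times the gene's
  own body level (a robust 10% quantile of its depth, so a broad peak
  cannot hide itself in its own median) — otherwise every well-expressed
  gene would call as one giant peak;
* runs are split at same-strand gene boundaries, so a peak spilling out
  of a gene is not fused with intergenic signal, and every reported
  candidate's category equals `classify_region()` on its final
  coordinates. When a candidate overlaps genes on both strands, the
  same-strand call wins (intragenic over antisense) — the conservative
  choice that avoids double-annotation.

All thresholds live in `peak_call_config()` and are declared defaults, not
literature values; peak calling thresholds are rarely published and must
be tuned to library depth. Candidates from several growth stages are
merged by genomic location (`merge_stages()`; same-strand any-overlap by
default, reciprocal-50% optional), and `stage_overlap_counts()` produces
exact Venn counts per stage combination plus the usual summaries
(detected in all stages / in at least two). On simulated stranded tracks
(60-kb genome, 40 genes at 5x background, 20 planted peaks per replicate
at fold 10, lengths 100–500 nt, mixed categories), the caller's recall
and precision both exceed 0.99. The simulator plants rectangular
plateaus with Poisson noise; real sRNA peaks have ragged ends and
processed isoforms, so genomic coordinates of real calls should be treated
as approximate.

## Co-expression modules, eigengenes and enrichment

`detect_modules()` is a deliberately simplified, deterministic weighted
co-expression analysis: signed adjacency
`a_ij = ((1 + cor_ij)/2)^power` (power 6), topological-overlap
dissimilarity, average-linkage hierarchical clustering, and a *static*
cut at height 0.65, with clusters under 30 genes relabelled
"unassigned". The full WGCNA machinery (dynamic tree cut, block-wise
fitting) trades determinism for flexibility; here every step is exact and
reproducible, and all parameters are exposed. The cut height was chosen
from the geometry of the dissimilarity: with ~12 samples, within-module
topological-overlap dissimilarity sits near 0.5 while between-module and
noise dissimilarities sit above 0.85, so 0.65 separates the two regimes
with margin on both sides; simulations (3 planted modules of 50 genes,
12 samples, within-module noise SD 0.5) recover the planted partition
with adjusted Rand index ≥ 0.85 and leave pure-noise matrices entirely
unassigned.

`module_eigengene()` summarizes a module as the first right singular
vector of its gene-standardized submatrix — one unit-norm value per
sample, sign-oriented to correlate positively with the module's mean
profile — along with the variance explained. On the planted simulations
the eigengene correlates with the true module profile above 0.99.

```{r modules-demo}
sim <- simulate_expression_matrix(180, 12, c(50, 50, 50), noise_sd = 0.5,
                                  seed = 3)
mods <- detect_modules(sim$matrix)
mods
adjusted_rand_index(sim$labels, mods$labels)
```

Differential screening uses a Wilcoxon rank-sum test plus a fold-change
filter (`differential_features()`). This is a deliberate substitution for
count-model differential expression (edgeR-style): the rank test makes no
distributional assumptions, and for the screening role it plays here
(selecting genes to cluster) that robustness is worth the loss of power.
The Wilcoxon p-value is computed by exhaustive enumeration of all
`choose(n, n_a)` assignments when `n <= 12` — exact even under ties, via
mid-ranks — and by a tie-corrected normal approximation with continuity
correction otherwise.

Pathway enrichment (`hypergeometric_enrichment()`) is the exact
hypergeometric upper tail `P(X >= k)` for a module of `n` genes hitting
`k` of a pathway's `K` genes in a background of `N`, summed from point
masses, with Benjamini–Hochberg adjustment across pathways (the standard
choice when the pathway family is tested together). Both statistics are
verified against brute-force enumeration oracles in the test suite, and
the false-positive rate of the adjusted enrichment p-values is checked to
stay at or below nominal on random modules.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GFF3 convention); the
  single 0-based half-open conversion lives in `write_bed6()`.
* Zero-SD coverage passes the outlier filter untouched; an all-filtered
  track, an all-N sequence, an all-zero count vector, and a rank-0 module
  submatrix are errors, not silent NAs.
* Ties in lowess x-values (two bins equidistant from the origin) are
  handled by the smoother's internal tie collapsing; constant series are
  preserved exactly.
* Simulators take an explicit `seed` and restore the caller's RNG stream;
  the same seed gives bit-identical output.
* `wilcoxon_rank_sum` reports the rank sum of the first group as its
  statistic; p-values are capped at 1.

## Scales used for validation

The bundled checks run at deliberately compact scales chosen to exercise
the estimators' operating conditions: PTR recovery on 3 Mb genomes
(comparable to a *Lactobacillus* chromosome) at 50x with 20 replicates
per grid point; origin prediction and flat-coverage identities on 0.5 Mb
genomes; sRNA calling on 60-kb annotated segments with 20 replicates;
module recovery on 180 x 12 matrices. These sizes make the full suite run
in a few minutes while keeping every estimator in the regime it was
designed for.

## Known limitations

* One replicon at a time: multi-contig or multi-strain PTR deconvolution
  is out of scope, as is growth inference from draft genomes.
* The GC-skew origin predictor assumes a canonical skew structure; genomes
  with weak or inverted skew need the `orientation` flag or an external
  origin estimate (any position can be passed to `smooth_lowess()` as
  `center` and to `compute_ptr()` through a custom `skew_profile`).
* The sRNA caller reports coverage peaks, not transcription units; it does
  not model UTRs, operon read-through, or processing.
* The module detector's static cut is robust but blunt; closely correlated
  modules (profile correlation above ~0.8) will merge.
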