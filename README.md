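# strainprofiler

Profile the in vivo activity of a sequenced bacterial strain — an ingested
probiotic, a pathogen, any genome of interest — from shotgun metagenomic
and strand-specific metatranscriptomic sequencing of a community sample.
The package is aimed at microbiome researchers who have a reference genome
and per-base coverage (or alignment summaries) for their strain and want
four analyses that standard tooling scatters across ad hoc scripts:

* **Replication rate** as the peak-to-trough ratio (PTR) of genome
  coverage. In a replicating population, DNA near the replication origin
  is over-represented relative to the terminus; the ratio of smoothed
  coverage at the origin to the coverage trough,

  `PTR = smoothed_cov(ori) / min(smoothed_cov)`,

  increases with the population growth rate (PTR = 1 means no
  replication). The origin is predicted from the cumulative GC skew
  `sum over windows of (G - C)/(G + C)`, whose minimum and maximum mark
  *ori* and *ter* on bacterial chromosomes. Pipeline: 10-kb coverage bins
  → drop bins > 2 SD from the mean → lowess smoothing against circular
  distance from the predicted origin → ratio.
* **Candidate sRNA discovery** from stranded RNA-seq coverage: peaks in
  intergenic, intragenic, and antisense regions, merged across growth
  stages by genomic location, with exact Venn overlap counts and
  per-sample RPKM.
* **Strain-specific quantification** from uniquely aligned reads: mapped
  fractions, RPKM, TPM, and taxonomic roll-ups that conserve per-sample
  totals.
* **Co-expression modules**: deterministic weighted-correlation
  clustering (signed adjacency, topological overlap, average linkage,
  static cut), module eigengenes (first principal direction of the
  standardized module submatrix), exact Wilcoxon rank-sum screening, and
  exact hypergeometric pathway enrichment with BH adjustment.

Every input has a simulator with known ground truth (skewed circular
genomes, replication coverage gradients, stranded RNA-seq tracks with
planted peaks, expression matrices with planted modules), so the whole
pipeline is testable end to end without sequencing data.

## Worked example

Simulate a 400-kb circular genome with GC skew, coverage with a true PTR
of 1.5 at 50x, and estimate:

```r
library(strainprofiler)

L <- 4e5
sim_g <- simulate_genome(L, ori = 1e5, ter = 3e5, skew_strength = 0.3, seed = 1)
sim_c <- simulate_replication_coverage(L, ori = 1e5, ter = 3e5, ptr = 1.5,
                                       mean_depth = 50, seed = 1)
fit <- ptr_fit(sim_c$track, sim_g$genome)
summary(fit)
#> Peak-to-trough ratio fit
#>
#>   PTR:               1.474
#>   peak:              60.21x at 95,001 bp (skew-predicted ori)
#>   trough:            40.84x at 295,001 bp (smoothed minimum)
#>   skew ter_hat:      299,500 bp (4,499 bp from coverage trough)
#>   bins kept:         40 / 40 (10000 bp bins)
```

The estimate (1.474) recovers the planted ratio of 1.5; the skew-predicted
origin (95 kb) sits within half a bin of the true origin at 100 kb, and the
coverage trough lands 4.5 kb from the skew-predicted terminus — the
internal consistency check that the two independent terminus estimates
agree. `plot(fit)` draws the bin coverages with the lowess curve, and
`ptr_report(fit, sample = "v1_day0")` emits a one-row TSV-ready report.

Co-expression module recovery on a simulated matrix with three planted
modules of 50 genes (12 samples, noise SD 0.5):

```r
sim <- simulate_expression_matrix(180, 12, c(50, 50, 50), noise_sd = 0.5,
                                  seed = 3)
mods <- detect_modules(sim$matrix)
mods
#> Co-expression modules: 3 module(s) over 180 genes
#> labels
#>         M1         M2         M3 unassigned
#>         54         52         50         24
adjusted_rand_index(sim$labels, mods$labels)
#> [1] 0.9270425
```

The three planted modules are recovered (adjusted Rand index 0.93 against
the planted labels); most of the 30 pure-noise genes land in
`unassigned`. `mods$eigengenes` holds one unit-norm per-sample profile per
module, ready for bar plots and condition comparisons.

A thin command-line wrapper for the PTR estimator is installed at
`inst/scripts/run_ptr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_ptr.R", package = "strainprofiler"))')" \
  --genome genome.fasta --depth depth.tsv --out ptr.tsv
```

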