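# cpsar — size-resolved chromatin particle spectrum analysis for MNase-seq

MNase (micrococcal nuclease) digests DNA that is not shielded by a bound
protein; in paired-end sequencing, each template's insert length then
reports the *size* of the particle that protected it. `cpsar` implements
chromatin particle spectrum analysis (CPSA): it classifies protected
fragments into sub-nucleosomal particles (**subNSP**, < 120 bp — bound
transcription factors and other small complexes), mono-nucleosomes
(~150 bp) and multi-nucleosome chains (N·150 + (N−1)·30 bp), and analyses
how differential digestion — a gentle versus a complete MNase dose —
exposes labile chromatin features that a full digest destroys: a fragile
"−1" nucleosome upstream of transcription start sites and
condition-responsive TF footprints over promoters and binding sites.

The package is written for epigenomics analysts working with paired-end
MNase-seq (fragments as BED or paired BAM, annotation as GFF3, expression
and differential-expression tables as TSV, TFBS catalogs as BED) and ships
a seeded synthetic MNase-digestion simulator with planted ground truth, so
every stage of the pipeline is testable without any external download.

## The statistics at the core

For a fragment of length *L* the particle class is

- subNSP iff *L* < 120,
- otherwise order N̂ = round((L + ℓ)/(u + ℓ)) with unit u = 150 and
  linker ℓ = 30; N̂ = 1 is mono, N̂ ≥ 2 multi(N̂).

On top of the midpoint / interpolated-coverage / size×position tracks the
package computes, per sample and TSS-aligned:

- a **digestion index** (mono fraction of nucleosome-scale fragments) and
  its per-10 bp Pearson correlation with occupancy across samples —
  negative over labile particles, positive over stable genic dyads;
- a Welch t-test of mean occupancy in 50 bp windows at the −1 and +1
  dyads between dose groups (the fragile-nucleosome test);
- per-gene **excess kurtosis** g₂ = m₄/m₂² − 3 of subNSP midpoint offsets
  in the TSS window (footprint sharpness), with expression grouped by
  recruitment quartile;
- per-gene subNSP abundance log₂ fold change between conditions, its loess
  trend (tricube local-linear, bootstrap 95% band) and Spearman correlation
  against the expression log₂FC;
- genome-wide subNSP position calls with distance-to-CDS fractions, and
  strand-oriented aggregation of subNSP signal over TFBS sets per
  condition.

## Worked example

```r
library(cpsar)

cfg <- run_config(seed = 1)          # 2 chromosomes, 80 genes, 8 samples
sim <- simulate_experiment(cfg)      # fragments + coupled expression
res <- analyse_experiment(sim, cfg)  # the full analysis suite

res$window_test
#>    window span_start span_end mean_low mean_high          t            p significant degenerate
#> 1: minus1       -125      -75 146.2860  56.61953 139.568845 1.225830e-11        TRUE      FALSE
#> 2:  plus1         75      125 154.6238 154.91338  -1.413481 2.106918e-01       FALSE      FALSE

round(res$digestion_index, 3)
#>  light_low_r1  light_low_r2 light_high_r1 light_high_r2  dark_low_r1  dark_low_r2 dark_high_r1 dark_high_r2
#>         0.658         0.660         0.922         0.921        0.657        0.658        0.922        0.922

res$fc_correlation$rho_significant
#> [1] 0.7597
```

Reading: the mean coverage in the −1 window collapses from 146 to 57
(per-million-pass units) under high digestion with p ≈ 1e−11, while the
stable +1 window does not change (p = 0.21) — the fragile −1 nucleosome.
The digestion index cleanly separates the low- (~0.66) from the
high-digestion (~0.92) libraries. Among genes with significant expression
changes, subNSP recruitment at the TSS and expression change rank-correlate
at ρ ≈ 0.76.

For real data, start from `read_fragment_bed()` /
`fragments_from_paired_bam()`, `read_annotation_gff3()`,
`read_expression_table()` / `read_de_table()` and `read_tfbs_bed()`, and
use the same analysis functions; `pipeline_tracks()` exports
wiggle/bedGraph tracks per particle class.

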