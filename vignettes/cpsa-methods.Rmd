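---
title: "Size-resolved chromatin particle spectrum analysis: models and methods"
author: "cpsar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-resolved chromatin particle spectrum analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsar)
library(data.table)
```

## The measurement model

Micrococcal nuclease (MNase) degrades DNA that is not protected by a bound
protein. After paired-end sequencing of the surviving fragments, each
template's insert length reports the size of the particle that protected
it: a nucleosome core shields ~150 bp, a chain of N nucleosomes that
escaped inter-nucleosomal cleavage shields ~N·150 + (N−1)·30 bp (the ~30 bp
being linker DNA), and smaller bound factors — transcription factors,
initiation complexes, remodelers — shield fragments under 120 bp. Chromatin
particle spectrum analysis (CPSA) keeps this size coordinate while mapping,
so one library resolves three particle populations at once:

* **subNSP** — sub-nucleosomal particles, protected length < 120 bp
  (strictly; 120 itself falls on the nucleosomal side so the partition is
  total);
* **mono** — nucleosome-sized, assigned by the order rule
  \(\hat N = \mathrm{round}\big((L + \ell)/(u + \ell)\big)\) with unit
  \(u = 150\) and linker \(\ell = 30\), \(\hat N = 1\);
* **multi(N)** — \(\hat N \ge 2\), partially digested nucleosome chains.

Two mono windows deliberately coexist: midpoint tracks use the tight
150 ± 15 bp window (mapping each fragment's midpoint approximates the dyad),
while coverage classification uses the \(\hat N\) rule, whose mono band is
roughly [120, 255). Both are explicit fields of `size_scheme()`. Rounding
in the order rule is half-up, not banker's, so the class boundaries are
deterministic and documentable. Midpoints of even-length fragments round
down. All internal coordinates are 0-based half-open; 1-based conventions
appear only at format boundaries (GFF3, fixedStep wiggle).

The key dose-response idea is *differential digestion*: particles that bind
weakly protect their DNA only under gentle digestion. Comparing a low and a
high MNase dose therefore exposes labile features — most prominently a
fragile nucleosome immediately upstream of the TSS (the "−1") and the
sub-nucleosomal footprints over promoters and TF binding sites — that a
complete digest erases.

## Track and profile representations

`midpoint_track()` adds one count at each in-window fragment's midpoint, so
a raw track sums to the number of contributing fragments.
`coverage_track()` counts every base of every fragment at or above a length
cutoff (default: the 120 bp subNSP boundary), implemented by
difference-accumulation (+1 at starts, −1 at ends, cumulative sum), which
is exactly the naive per-base loop. `size_position_matrix()` is the 2D
histogram of (length bin, midpoint bin) — the "V-plot"-style landscape.
`normalize_per_million()` scales a raw track by 1e6 over the library size
and refuses to run twice; which denominator is appropriate depends on the
question (see the depth model below).

Anchor-aligned analyses all run through one code path: `extract_anchors()`
produces TSS, coding-start (CSS) or intron/exon-junction anchors
(strand-aware; junction profiles use the same machinery with no special
casing), `profile_matrix()` slices a track around each anchor with positive
offsets pointing downstream of transcription, and `aggregate_profile()`
averages columns. Cells outside the chromosome are *missing*, not zero, and
are excluded from means — zero-filling would dig artifactual troughs at
chromosome edges.

## Differential-digestion statistics

**Digestion index.** The study design needs a per-sample estimate of
digestion completeness, which must be computable from the fragments alone.
The default estimator is the mono fraction of nucleosome-scale fragments,
`count(length in [120, 180]) / count(length >= 120)`: as digestion
proceeds, di- and tri-nucleosomes are cleaved to monomers and the index
rises monotonically. The estimator is pluggable (`digestion_index()`
accepts a function) so median-length or 1 − multi-fraction variants can be
swapped in.

**Per-bin digestion correlation.** For each 10 bp offset bin of the
TSS-aligned mono-midpoint profile, the Pearson correlation across samples
between the digestion index and the depth-normalized abundance in that bin.
Stable genic dyads correlate positively (multi→mono conversion raises mono
counts), the labile −1 negatively. Bins with zero across-sample variance
are flagged undefined rather than given a fabricated value.

**Window occupancy test.** Mean occupancy over 50 bp windows centered on
the −1 and +1 dyad neighborhoods — defaults `[−125, −75)` and `[+75, +125)`
relative to the TSS, configurable because only the width, not the
coordinates, is canonical — compared between dose groups with a Welch
(unequal-variance) two-sample t-test at α = 0.05. Welch is the safe default
at n = 4 per group. Groups that are both constant and equal are flagged
degenerate rather than tested.

**+1 position.** `plus1_position()` reports the argmax of a 31 bp
moving-average-smoothed profile within `[0, +250]`; a maximal plateau
(which a moving average produces over a sharp peak) reports its center.
The 31 bp default stabilizes per-gene argmaxes on sparse profiles; for
dense aggregate tracks a narrower smoother (the 15 bp bandwidth the
position caller uses) resolves dyads more sharply.

## Linking chromatin to expression

Genes are quartiled two ways. `quartiles_by_expression()` ranks genes by
expression (ties broken deterministically by gene id; sizes balanced to
within one). `tss_subnsp_stats()` measures, per gene, the strand-oriented
subNSP midpoint offsets inside a TSS window (default `[−250, +50]` bp,
spanning the upstream footprint zone into the 5' UTR) and summarizes the
peak by its **Fisher excess kurtosis** \(g_2 = m_4/m_2^2 - 3\) on the raw
offsets. Kurtosis measures how sharply the footprint stands out of the
diffuse small-particle background: a uniform offset distribution scores
−1.2, a tight footprint-dominated one scores high. Genes with fewer than
20 fragments are ineligible (fourth moments are unstable below that) and
are excluded, never imputed. Both kurtosis and raw abundance are emitted;
which one drives the quartiling is a configuration choice
(`quartiles_by_kurtosis(statistic = )`).

`subnsp_log2fc()` contrasts conditions per gene:
\(\log_2(\mathrm{cpm}_L + pc) - \log_2(\mathrm{cpm}_D + pc)\) over subNSP
midpoints in the TSS window, replicates pooled within condition (a
per-replicate mode is available through per-sample calls). Writing the
statistic as a difference of logs makes label-swap antisymmetry bit-exact.
`fc_correlation()` relates it to the expression log2FC with a local-linear
(degree 1, tricube, nearest-neighbor span 0.5) loess trend evaluated on a
grid, a 95% bootstrap percentile band (500 resamples), and Spearman rank
correlations over all genes and over the FDR < 0.05 subset. On exactly
linear data any tricube-weighted linear fit reproduces the line, which is
the invariant the tests pin.

## Genome-wide subNSP positions and TFBS aggregation

The source study reports discrete subNSP positions without specifying a
caller, so `call_subnsp_positions()` is deliberately plain and fully
exposed: 15 bp moving-average smoothing, threshold at 4× the genome-wide
nonzero median of the smoothed signal, local maxima kept greedily
highest-first with a 60 bp minimum separation, ties leftmost, iteration
order independent of chromosome naming. Distances to coding sequence
(`distance_to_nearest_cds()`) are edge-to-edge gaps against CDS features
specifically — not gene or mRNA spans — strand-ignored, zero inside a CDS;
`fraction_beyond()` turns them into the distal percentages. Because the
calling rule is invented, distal fractions on real data should be read
qualitatively (promoter-proximal majority, distal minority), not as
reproductions of any particular published percentage.

`tfbs_aggregate()` builds site-centered, strand-oriented subNSP profiles
per condition from a BED site list (motif scanning is out of scope; site
catalogs are inputs), their aggregates, the light − dark difference, and
per-site matrices for heatmaps.

## The synthetic landscape: what it emulates

Every stage is validated against `plant_landscape()` +
`sample_fragments()`, a seeded generator with planted ground truth:

* per gene (strand-aware): a +1 nucleosome dyad at TSS + 100, a downstream
  array at 180 bp period filling the gene body, a **labile −1** at
  TSS − 100 with survival 0.8 (low dose) vs 0.3 (high dose), and one subNSP
  footprint at TSS − 60 with width drawn from [30, 110] bp;
* a diffuse promoter small-particle floor: 8 weak subNSP templates
  (total occupancy 0.25) tiled over TSS − 240..+40, condition-independent.
  This is the "noise floor" real promoters show, and it is what makes
  kurtosis informative: without it every footprint peak is the same narrow
  Gaussian regardless of occupancy;
* sparse stable nucleosomes in intergenic gaps (occupancy 0.45 at 240 bp
  spacing) and one light-only TFBS footprint per gap (occupancy 0.6 in
  light, 0 in dark) with a BED export of the site list;
* per-gene condition effects: a base footprint occupancy drawn from
  [0.15, 0.9]; 40% of genes are light-responsive with an occupancy log2FC
  drawn from N(1.5, 0.5²), the rest from N(0, 0.3²). High digestion
  multiplies all subNSP occupancies by 0.35 (these are digestion-sensitive
  particles). Nucleosome survival rates are free parameters of the dose
  model — no published per-class values exist to calibrate them — chosen
  once as a realistic stable occupancy of 0.85 at both doses.

Fragment generation works per genome pass (one pass = one cell's genome):
each template survives Bernoulli(occupancy); runs of adjacent surviving
nucleosomes stay joined with per-junction probability `p_link` (0.6 low
dose, 0.1 high), so digestion completeness is a single monotone knob and
multi-nucleosome lengths arise as N·150 + (N−1)·30 by construction; both
fragment boundaries then receive independent rounded-Gaussian jitter
(default sd 8 bp, so mono fragments span ≈135–165 bp); Poisson naked-DNA
background fragments (uniform positions, lengths uniform on [40, 400] bp;
0.02/kb/pass low dose, 0.05 high) complete the library.

**Depth model.** A sample's `depth` is converted into a fixed number of
passes using a landscape-level reference yield averaged over the four
condition × digestion combinations. All samples of an experiment therefore
receive *equal chromatin input*, and realized library sizes vary with
digestion (merging joins fragments; lability removes them) — exactly as
equal aliquots behave at the bench. This choice matters statistically: with
equal cell input, raw coverage at a stable nucleosome is identically
distributed across dose groups, so the −1/+1 window test isolates lability;
had we fixed the realized library size instead, losing the −1 would
mechanically inflate every other position by a few percent, far above
counting noise, and the stable +1 would test "significant" for reasons
that have nothing to do with chromatin.

**Coupled expression.** `simulate_expression()` draws negative-binomial
counts with per-condition mean
\(\mu = \text{baseline} \cdot (occ_{\text{cond}}/0.5)^{\text{link}}\), so a
single `link_coefficient` (default 1) produces both the within-sample
recruitment–expression association and a cross-condition expression log2FC
equal to link · log2(occ_L/occ_D). The bundled DE table (log2FC of means,
t-test on log2(count+1), Benjamini–Hochberg FDR) is plumbing standing in
for an external RNA-seq pipeline, not a reimplementation of one, and the
planted truth is always written alongside.

**What the generator does not emulate** — and hence what passing tests do
not certify on real data: sequence-dependent MNase bias, mappability and
alignment artifacts, repeat regions, nucleosome positioning heterogeneity
across cell populations, isoform complexity beyond a shared/non-shared
flag, batch effects, and biological replicate variability beyond counting
noise. Results on real libraries should be read with those caveats.

## Numerical and design choices

* **120 bp boundary**: subNSP is strictly < 120; 120 itself is nucleosomal,
  so the partition is total.
* **Peak-caller parameters** (15 bp bandwidth, 4× nonzero median, 60 bp
  separation) are invented defaults exposed in the API, because no
  published calling rule exists for these positions.
* **CDS distance** is computed against merged CDS intervals with a
  convention pinned by example (a position k bp left of a CDS start is at
  distance k); positions on chromosomes without CDS return `Inf` with a
  warning.
* **Degenerate inputs**: empty fragment sets are data (zero depth yields an
  empty library, not an error); all-zero tracks yield empty call lists;
  ineligible genes are flagged, not dropped silently; re-normalizing a
  normalized track, span outside (0, 1], fewer than 3 samples for a
  correlation, fewer than 2 replicates per group, and empty site sets are
  errors.
* **Determinism**: every stochastic stage takes an explicit integer seed;
  the pipeline derives all stage seeds from one master seed, and identical
  configuration yields byte-identical BED/GFF3/TSV/wiggle/bedGraph output.
* **Problem sizes**: the default experiment used throughout the tests and
  the acceptance script is 2 chromosomes × 150 kb, 80 genes, 8 samples of
  2 × 10⁵ target fragments; power-style repetition tests (window-test hit
  rates, null calibration, footprint recall) use a 20-gene, 80 kb genome
  with 50 seeded repetitions. These sizes keep every planted effect
  comfortably detectable while the whole suite remains quick on a single
  core.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
sim <- simulate_experiment(cfg)      # genome, landscape, 8 libraries, RNA
res <- analyse_experiment(sim, cfg)  # every stage of the analysis

res$window_test                      # fragile -1 vs stable +1
res$digestion_correlation            # per-10bp dose correlation profile
res$fc_correlation$rho_significant   # subNSP ~ expression linkage
res$distal_fractions                 # called positions far from CDS
```

## Known limitations

The caller is a smoothing-threshold heuristic, not a model-based
deconvolution; closely spaced footprints under 60 bp apart merge. The
digestion index saturates once virtually all material is mononucleosomal.
Kurtosis quartiling needs tens of subNSP fragments per gene and will mark
shallow libraries ineligible genome-wide. The DE stand-in is adequate for
synthetic validation but should be replaced by a dedicated count model
(e.g. edgeR output read via `read_de_table()`) for real data.
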