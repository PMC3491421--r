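---
title: "Methods: promoter tiling-array analysis of the liver 5-hydroxymethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter tiling-array analysis of the liver 5-hydroxymethylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

5-hydroxymethylcytosine (5hmC) is the oxidation product of 5-methylcytosine
(5mC) and a candidate intermediate of active DNA demethylation. In rodent
liver, exposure to the non-genotoxic carcinogen phenobarbital (PB) induces a
small cohort of xenobiotic-metabolism genes, and their promoters undergo a
characteristic epigenetic switch: a gain of 5hmC and loss of 5mC over the
promoter flanks, loss of both marks over the TSS core, and concordant
histone-mark changes (H3K4me2 and H3K36me3 up, H3K27me3 down).

`hydroxyscan` implements the full analytical chain used to detect and
quantify this switch from promoter tiling-array and ChIP-seq data, plus a
synthetic-data generator that emulates the assay well enough that every stage
can be verified against planted ground truth. All genomic intervals are
0-based and half-open; all probe scores are log2(IP/input) ratios.

## The synthetic study

The generator writes the study conditions the analysis assumes:

* **Genome and array.** Default 2 chromosomes x 5 Mb carrying 200
  non-overlapping genes on both strands (1-8 exons each), 20% of them
  "short" (2-3 kb, fully tiled). The array tiles a strand-aware window from
  7.25 kb upstream to 3 kb downstream of every TSS and a 1 kb window around
  each enhancer, with 50-70 bp probes every 100 bp start-to-start. The
  spacing is fixed at 100 bp for simple arithmetic and is configurable.
* **Baseline signal.** Probe scores are Gaussian, sd 0.5 log2 units, plus a
  per-animal offset (sd 0.1) for the n = 5 + 5 control/treated design.
  Between-animal variance is exposed as a parameter rather than asserted,
  since no variance components are published for such designs; 0.1 log2 is a
  modest technical-plus-biological spread that leaves group means dominated
  by probe noise.
* **Planted biology.** Intra-genic 5hmC peaks in 30% of genes (width
  1.5-3 kb, effect 2.0 log2 scaled 0.5/1/1.5 by expression tier); a broad
  +0.5 log2 5mC elevation over every gene body; +1.5 log2 5hmC over half of
  the enhancers; and, for 30 induced genes with true log2 fold changes drawn
  from U(1.6, 4): a +1/-1 log2 reciprocal 5hmC/5mC change over the promoter
  flanks (250 bp-3 kb from the TSS, scaled per gene by its fold change) and
  a -1 log2 loss of both marks over the TSS +/- 250 bp core, in treated
  animals only. Probe membership in planted intervals uses the probe
  midpoint, the same rule the analysis uses, so every effect is exactly
  recoverable from the raw tables.
* **ChIP-seq.** Fragment start positions are drawn region-proportionally
  (weight = region length x enrichment, the rest of the genome at weight 1);
  10% duplicate locations are injected so deduplication is exercised; each
  IP library has a uniformly sampled matched background.
* **Expression.** A latent per-gene baseline (log2 ~ N(8, 2)) is shared
  between the probe-signal and expression simulators so tiers agree; treated
  samples add the true fold change for induced genes. A tissue panel with
  designed uniform and single-tissue genes supports the specificity score.
* **EpiMark qPCR.** Cq = Cq_uncut - log2(surviving fraction), with Gaussian
  per-reaction noise and a ceiling of 40 cycles representing complete
  digestion (qPCR convention).

What the generator does **not** emulate: probe sequence effects, dye bias
beyond a single intensity covariate, copy-number variation, repeat elements
(the real array excludes them), mapping artefacts, and spatially correlated
array noise. Passing tests therefore demonstrate the correctness of the
algorithms under the stated statistical model, not robustness to every
artefact of real arrays.

## Normalization

Within-array saturation trends are removed by loess regression of each
sample's scores on its probe mean log-intensity (A-value): degree 1, tricube
weights, robust "symmetric" family (three robustness iterations), span 0.3.
The span is a deliberate default — wide enough to track broad saturation
trends without chasing individual peaks — and is configurable. A constant
intensity column falls back to median subtraction with a logged message.

Between arrays, scale normalization divides each sample by its median
absolute deviation and multiplies by the geometric mean of all samples'
MADs; afterwards all per-sample MADs are equal, and the operation is
idempotent to numerical precision. The 5hmC and 5mC tracks are normalized
separately, and the pipeline fixes the order within-array-first; the
configuration records it. Missing probe values propagate as missing, never
imputed — peak calling treats them as below threshold, which is
conservative.

## Peak calling

A peak is a merged run of windows of `w = 5` consecutive probes in which at
least `k = 4` probes strictly exceed the `q = 90`th percentile of the entire
(group-mean) score vector. Numerical choices, all recorded in the peak-set
metadata:

* *Quantile convention*: linear interpolation between order statistics (R
  type 7), the dominant convention.
* *Strict exceedance*: ties at the threshold do not count.
* *Window continuity*: windows never span tiled-region boundaries or probe
  gaps above `max_gap = 500` bp — the promoter array is a disjoint design
  and bridging gaps would fabricate intervals the array never measured.
* *Merging*: overlapping or adjacent qualifying windows merge into one peak
  spanning first to last member probe; by construction merged peaks never
  overlap.
* Thresholds are computed on group-mean tracks (peaks are called per
  group); per-animal calling is available by passing per-sample score
  vectors.

The caller is verified against a brute-force enumerator of every window on
1,000 seeded random tracks, and against planted peaks (effect 2.0, noise
0.5) where it attains per-probe sensitivity >= 0.9 with false discovery
proportion <= 0.1. The residual FDP is dominated by single edge probes
adjoining planted peaks: a window with four planted probes and one flanking
background probe legitimately qualifies under the 4-of-5 rule.

## Genic annotation

Probes and peaks are assigned uniquely to six categories by their midpoint:
promoter (TSS -1 kb..+250 bp, strand-aware), exon, intron, downstream
(1 kb past the transcript end), upstream (to -7.25 kb, the array's upstream
tiling reach), intergenic. Only the promoter window is published; the other
windows are declared here, not inferred, and are configurable and recorded
in output metadata. Precedence (promoter > exon > intron > downstream >
upstream > intergenic) makes the assignment a total function; the gene
context is the nearest TSS among windows containing the midpoint. Midpoint
assignment is the simplest deterministic resolution for peaks spanning
boundaries.

Distributions of peak probes are tested against the all-probe background
with a Pearson chi-square (categories with zero expected count are collapsed
with a warning), and optionally divided by per-category probe counts to
remove coverage bias. Feature overlap (CGIs, 1 kb CGI shores, 1 kb
enhancers) is counted over probes: a probe belongs to a feature if its
interval intersects it; region-level comparisons use per-region mean scores
and two-sided Wilcoxon rank-sum tests.

## Profiles and heat maps

TSS meta-profiles slide a 200 bp window in 50 bp steps over TSS +/- 1.5 kb
(57 offsets), strand-flipped, averaging per gene first and then across
genes; probe membership is by midpoint (declared in metadata — an any-overlap
rule would blur 50-70 bp probes over 200 bp windows). Expression tiers cut
genes at the quartiles (low 25% / medium 50% / high 25%) with stable
tie-breaks. Short (2-3 kb), fully tiled genes provide gene-body profiles in
absolute bp without length scaling.

The PPR (promoter proximal region, TSS +/- 1 kb) heat map clips per-animal
means to [-2.5, 2.5] and orders rows by hierarchical clustering with
Euclidean distance and Ward linkage (squared-Euclidean update, `ward.D2`).
Leaf order is made deterministic: at each merge the smaller subtree comes
first, ties resolved by smallest member index.

## ChIP-seq region scores

Fragment libraries are deduplicated by exact location, counted over
pre-defined regions with any-overlap (>= 1 bp) semantics, scaled to the mean
library size, and scored as log2((IP + 1)/(background + 1)) against the
per-sample matched background ("matched" per sample is the implemented
reading of the ambiguous protocol; a pooled background would be a one-line
change). The pseudocount of 1 is not published anywhere; it is the standard
choice that keeps empty regions finite and is recorded in metadata. H3K4me2
is scored over TSS -1/+2 kb, H3K27me3 and H3K36me3 over gene bodies, with
n = 2 replicates per group.

## Differential analysis

Expression changes are plain Welch two-sample t-tests on log2 expression —
a deliberate substitution for the moderated t-statistic of the array-era
pipelines, which is a package feature rather than a described method; with
n = 5 + 5 the practical difference is small. Induced genes exceed log2 1.5
strictly. "Unaffected" control genes are defined as |lfc| < 0.1 with
p > 0.5, down-sampled (seeded) to the induced-set size; the criterion is
declared in metadata since no published definition exists.

Per-gene changes of each mark over PPRs (or bodies/promoter windows for the
histone marks) are correlated with expression changes (Pearson, t-transform
p-value) within the induced set; change correlations are computed on
group-mean deltas. TSS change profiles use the 200/50 sliding window over
+/- 3 kb. The family region analysis compares a gene family's changes per
region kind against the unaffected set with two-sided Wilcoxon rank-sum
tests flagged at raw p < 0.005 — deliberately uncorrected, mirroring
standard practice for this analysis; the fold enrichment reported is the
family mean change over the unaffected mean absolute change. Note that
downstream windows of long genes lie outside the tiled array, so that region
kind can be absent on small synthetic genomes.

## CpG features and tissue specificity

CpG density is CG-dinucleotide count per 100 bp (case-insensitive, N never
matches; CG is its own reverse complement, making the density strand
symmetric), classified LCP < 1, ICP 1-5 inclusive, HCP > 5. The
classification window equals the promoter window (TSS -1 kb..+250 bp) for
consistency with the category scheme. 5hmC-enriched TSS regions are genes
whose TSS +/- 500 bp window intersects a 5hmC peak; the half-width is not
published and is flagged prominently in metadata.

The tissue specificity score is the Kullback-Leibler divergence of a gene's
expression shares from uniform: Si = sum p_t log2(p_t T). It is exactly 0
for uniform expression and exactly log2 T for single-tissue expression, and
scale-invariant. Published figures quote a maximum of 6.2, implying T of
about 74 tissues; T is left configurable since it is data-dependent.

## EpiMark quantification

The enzymology: T4-BGT glucosylation protects 5hmC from MspI; HpaII is
blocked by any CpG modification; non-glucosylated MspI cuts everything and
serves as the background. The fractions are the unique linear solution:

* f_5hmC = f(MspI | glucosylated) - f(MspI | non-glucosylated)
* f_5mC = f(HpaII | non-glucosylated) - f(MspI | glucosylated)
* f_C = 1 - f(HpaII | non-glucosylated)

with f = 2^(Cq_uncut - Cq_digested) clamped to [0, 1] and qPCR efficiency
fixed at 2.0. Two numerical decisions matter. First, a reaction at the
40-cycle ceiling is treated as zero surviving template when solving —
back-transforming the ceiling through the doubling formula would instead
yield ~1e-6 and break the exact noise-free inversion. Second, the three
states are a partition of the template molecules: the assay yields three
independent survivals, which cannot identify four quantities, so a fraction
triple summing to less than 1 has its shortfall absorbed into the unmodified
fraction (it is cut by HpaII like unmodified C). On the simplex the
round-trip through the forward model is exact to 1e-9. Replicates are solved
independently, averaged, and reported with standard errors; reproducibility
checks use technical triplicates, the usual qPCR practice.

## Orchestration and problem sizes

`default_config()` holds every tunable with its default; `validate_config()`
reports all violations at once; `run_pipeline()` runs simulation through
differential analysis deterministically given the master seed (stage seeds
are derived from it) and, with an output directory, writes TSV/BED/GFF3
tables plus a JSON manifest of parameters, package version and file digests
sufficient to re-run any stage. A thin `inst/scripts/hydroxyscan` Rscript
exposes `simulate` and `pipeline` subcommands.

The test suite runs on desk-scale problem sizes chosen as this package's
study conditions: the default 200-gene genome for planted-peak recovery, an
80-gene single-chromosome genome for the 100-replicate sign-recovery suite
(the published conditions it preserves are the n = 5 + 5 design, noise sd
0.5, 30 induced genes and +/-1 log2 reciprocal planting), 1,000 random
200-probe tracks for the brute-force peak-caller equivalence, and 200
synthetic null replicates for the family-analysis calibration.

## Known limitations

* Headline numbers of the motivating study (global peak counts, genome-wide
  correlation magnitudes, specific gene families) depend on the real arrays
  and are not reproduced at desk scale; the package reproduces the printed
  arithmetic, the algorithms' contracts, and the direction and recoverability
  of every planted effect.
* First-TSS-per-gene resolution; no isoform-aware multi-TSS handling.
* Peak calling is threshold-based by design; no FDR control is attempted.
* The EpiMark solver assumes fixed amplification efficiency 2.0 and no
  melt-curve QC.
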