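---
title: "Methods: single-nucleotide RNAPII profiling, readthrough statistics, and IP-MS enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleotide RNAPII profiling, readthrough statistics, and IP-MS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprof)
```

## The measurement and its model

Nascent-transcription protocols of the mNET-seq family immunoprecipitate
transcriptionally engaged RNA polymerase II and sequence the RNA still held
in the active site. Because the RNA 3' end is the last nucleotide the
polymerase incorporated, the genomic position of each fragment's 3' end is a
direct, single-base readout of polymerase position. The package turns
aligned reads into these single-nucleotide-resolution (SNR) positions and
everything downstream — coverage tracks, metagene profiles, readthrough
ratios — is computed from them.

Two sequencing chemistries are supported:

* **single-end**: the read aligns on the nascent-RNA strand and its aligned
  3' end (rightmost base of a plus alignment, leftmost of a minus
  alignment) is the polymerase position;
* **paired-end FR**: mate 1 aligns on the nascent strand; mate 2 aligns on
  the opposite strand with its 5' end at the fragment 3' end. Only mate 2
  is used, and its strand is flipped back to the nascent strand.

Ends are taken from the *aligned span*, never from soft-clipped bases:
clipped bases were not templated at the reported locus, so including them
would shift the polymerase position.

## Filtering

Upstream trimming and alignment are taken as given (inputs are aligned
SAM/BAM). Post-alignment, records are dropped in a fixed order — unmapped;
secondary/supplementary; multimapping (reported-alignment count `NH` > 1,
falling back to MAPQ 0 when the tag is absent); duplicates; and, for
paired data, records not in a proper pair. Each record is counted under
the first applicable reason, so the per-reason counts plus the retained
count always equal the input count — an invariant the tests assert on
every fixture.

Duplicates are keyed on *both* endpoints and the strand
((chrom, start, end, strand) for single-end reads; the fragment bounds and
first-in-pair strand for pairs). With 20–90 nt fragments the 3' end is the
signal of interest, so collapsing on the start coordinate alone would
destroy genuinely distinct polymerase positions. The first record per key
in coordinate order is kept, which makes the pass idempotent and
order-stable. A consequence worth knowing: two independent fragments that
happen to share exact coordinates are collapsed too. That is the correct
behavior for a duplicate filter but it means truth-level comparisons of
end extraction are run with the diagnostic `keep_duplicates` switch, so
the extraction check is not confounded by coincidental collisions.

## Tracks and profiles

SNR events are accumulated into per-strand, per-base coverage tracks
(run-length encoded; total mass always equals the number of retained
reads or pairs). Replicates are merged by summing raw counts *before* any
normalization — merging exists to increase depth, and density scaling
happens later at the profile level. Tracks serialize to bedGraph/bigWig
at single-base resolution with equal-value runs merged and zeros omitted;
round trips are lossless.

Profiles come in two geometries:

* **point windows** (TES, polyA sites): the window `[anchor − flank,
  anchor + flank)` tiled into `bin` bp bins, ordered in transcription
  direction. The anchor base falls in the first downstream bin; on the
  minus strand the window shifts one base so the two strands are exact
  mirror images. Defaults: ±5 kb/100 bp for TES profiles, ±2 kb/40 bp for
  polyA profiles — 100 bins in both cases.
* **scale-regions metagenes**: 5 kb flanks in 100 bp bins, the gene body
  linearly rescaled to 15 kb (150 bins), 50 + 150 + 50 = 250 bins total.
  Body bins are the mean per-genomic-bp signal of each bin's preimage,
  computed by piecewise-linear interpolation of the cumulative signal so
  every genomic base contributes to exactly the virtual bins its image
  spans. The mean convention keeps body bins on the same scale as flank
  bins (uniform coverage stays flat across the TSS boundary, as in the
  standard scale-regions profilers) and conserves mass in the form
  Σ bins × (gene length / n bins) = body mass. Genes shorter than one bin
  are retained through the proportional weighting, not excluded.

Aggregation across regions is the per-bin mean (sum and median are
options). **Density scaling** divides the aggregated profile by its total
so the area under the curve is 1, per sample, after binning. This is what
makes samples of very different depth comparable without spike-ins; it is
idempotent and invariant to global count scaling, and both properties are
tested. All profiles count sense-strand signal only by default.

One representative transcript is chosen per gene: strongest (smallest)
support level, ties broken by the widest TSS-to-TES span, then by smallest
transcript id for determinism. Width ties are read as *prefer the widest*
— the wider model covers every position of the narrower and is the
conservative choice for region derivation; transcripts with no support
level rank after level 5 so an unevidenced model never beats an evidenced
one.

## Readthrough

Transcription continuing past the transcript end site is quantified per
gene as the ratio of SNR read density, expressed as reads per kilobase
(RPK), in the 50 kb window downstream of the gene's *most distal* TES to
the RPK of the representative transcript's last exon. Windows are clamped
at chromosome ends, and the clamped length is the one used in the RPK
denominator. The ratio is invariant to global depth scaling, which is the
entire point: the double-IP protocol admits no spike-ins, so only
within-sample ratios are comparable across samples. Genes with zero
last-exon density cannot form a finite ratio and are dropped from all
statistics (`infinite_dropped` when downstream signal exists,
`empty_dropped` otherwise). Genes whose downstream window overlaps another
annotated gene body are flagged but kept by default, since a neighbor's
signal is indistinguishable from readthrough at this level; exclusion is
an option.

Distributions of ratios are compared with a two-sided Wilcoxon test —
rank-sum for independent gene sets, signed-rank for gene-matched pairs.
For total n ≤ 12 the rank-sum p-value is computed by full enumeration of
group assignments on midranks (exact even with ties); larger samples use
`stats::wilcox.test`, i.e. the exact distribution where available and the
normal approximation with continuity correction otherwise.

## IP-MS enrichment

Protein-group tables in the MaxQuant dialect are ingested with zeros
treated as missing and reverse/contaminant rows dropped. Protein groups
are kept only when their peptide count summed over biological replicates
is strictly greater than 3. Intensities are log2-transformed; missing
cells are imputed per column from a Gaussian centered 1.8 column standard
deviations below the column mean with width 0.3 column sd — the standard
down-shifted imputation for left-censored label-free data. The volcano
axes are the mean log2 difference (test − control) and the *negative
log2* (not log10) of a two-sided equal-variance Student t-test, with
injections as observations (n = 6 per side at the 2-replicate ×
3-injection design; a replicate-means mode with n = 2 is available for
sensitivity analysis, and a Welch variant by flag). Interactors are
called by strict inequalities on both axes: log2 difference > 2 *and*
−log2 p > 2, i.e. more than 4-fold up at p < 0.25. No multiple-testing
correction is applied — the thresholds act directly on raw p-values, and
the joint fold-change requirement is what controls the false-positive
rate (≤ 5% empirically on effect-free simulated tables, tested).
Degenerate rows (zero pooled variance) get p = 1 when the means agree and
a machine-minimum p with a flag when they differ. Double-IP runs are
compared to a single-IP reference by restricting to reference-enriched
proteins; proteins missing from the double-IP table are reported with NA
values, never silently dropped.

## The synthetic-data generator

Every stage is testable without external data because the generator emits
inputs with the statistical structure the analysis assumes, plus plain-TSV
truth tables that tests read independently of the package's own parsers.

* **Annotation**: genes placed sequentially with an isolation gap (default
  60 kb) so 50 kb downstream windows never reach a neighbor; 1–3
  transcripts per gene with varying support levels; both strands.
* **Occupancy density**: a per-base mixture over
  [TSS − 5 kb, TES + horizon] — Gaussian pause peak 50 bp downstream of
  the TSS (sd 150 bp), uniform body, Gaussian TES peak (sd 150 bp),
  exponential readthrough tail beyond the TES (mean 5 kb), optional
  intronic-polyA Gaussian. Default weights 0.25/0.30/0.20/0.25 give the
  canonical nascent-transcription shape: promoter-proximal pausing, a
  depleted body, 3'-end accumulation, and signal persisting several kb
  past the TES. Components are discretely normalized to their weights, so
  the tail's mass fraction beyond the TES equals the readthrough weight
  exactly.
* **Reads**: fragment 3' ends sampled from the density, lengths uniform
  on 20–90 nt (the library's insert range), single or FR-paired SAM with
  exact-coordinate duplicates, `NH`-tagged multimappers (primary record
  only, matching the filter's contract), and optional improper pairs.
  Fragment sampling is independent of the output mode, so single- and
  paired-mode truth coincide for a seed — the lever behind the cross-mode
  equivalence checks.
* **LFQ tables**: protein base log2 intensities N(25, 2²) across
  proteins, per-injection noise sd 0.4 (a realistic label-free CV),
  spiked proteins shifted by `log2_effect` in the test condition.
  Missingness is *left-censored*: cells drop out with logistic
  probability decreasing in intensity, calibrated so the marginal missing
  fraction equals `missing_rate`. Missing-completely-at-random would be
  both unrealistic (label-free dropout is abundance-driven — the very
  premise of down-shifted imputation) and misleading for spike-recovery
  checks, since it censors the high-abundance spiked cells that real data
  never loses.

What the generator does *not* emulate: sequence content and sequencing
error (reads carry placeholder sequence), base qualities, splicing-aware
alignment artifacts, antisense or intergenic background transcription,
and correlated biological replicate structure. Passing tests therefore
demonstrate the correctness of the computations — end extraction,
filtering, binning, the statistics — under the stated generative model,
not robustness to every artifact of real libraries.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open (BED convention); GTF
  converts at the boundary. bedGraph/bigWig output follows the same
  convention.
* Density scaling refuses all-zero profiles; region RPK refuses
  zero-length (post-clamping) regions; windows fully off-chromosome are
  errors while partial overhangs are zero-filled (profiles) or clamped
  and flagged (regions).
* Representative selection and deduplication are deterministic under
  input permutation (id tie-breaks, first-per-key in coordinate order).
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give byte-identical outputs.
* The empirical-vs-input density convergence test uses total-variation
  distance on 50 bp bins: at per-base resolution the sampling noise of
  10^5 draws over a ~50 kb support exceeds any meaningful bound, while at
  50 bp the distance cleanly separates a correct sampler from an
  off-by-one or mis-oriented one.

## Problem sizes used in the checks

Simulation-based checks run at: 10,000 reads for extraction and
conservation oracles; 100,000 reads for the density-convergence bound;
200 + 200 genes at 200 reads/gene for readthrough parameter recovery
(tail weights 0.4 vs 0.05); 1,000 background + 50 spiked proteins with
2 × 3 injections per side, 30% missingness, and a log2 effect of 4 for
spike recovery. These sizes make every distributional assertion stable
across seeds while keeping a full run of suite plus acceptance script in
the low minutes on one core.
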