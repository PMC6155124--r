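---
title: "Methods: linking chromatin accessibility to transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chromatin accessibility to transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromassoc)
```

## Scope and model

`chromassoc` implements the computational core of a common design in
regulatory epigenomics: given (i) peak sets from accessibility or
protein-binding assays across conditions or developmental stages, (ii) a
per-gene differential-expression table, and (iii) paired-end ATAC fragments,
quantify how regulatory-element changes relate to transcription as a function
of genomic distance, and characterize the elements themselves (enhancer
status, genomic context, nucleosome structure). The motivating application is
B-cell development, where loss of the chromatin reader BRWD1 reshapes
enhancer accessibility genome-wide, but nothing in the package is specific to
that system.

The central statistic is the merged differential value

$$D = \log_2\!\mathrm{FC} \times \left(-\log_{10} q\right),$$

which combines effect size and significance into one signed ordinal quantity
per gene (`merged_statistic()`). Gene subsets — for example, all genes whose
nearest gained-accessibility peak lies 20–100 kb from the TSS — are compared
to the all-gene background by matched empirical quantiles (Q–Q curves) and by
probability histograms over shared edges. Enrichment of differentially
expressed genes in a distance bin is tested with the hypergeometric upper
tail.

The base of the significance logarithm is not canonical; we fix base 10 and
expose it (`log_base`). Because $D$ is used ordinally (quantiles, ranks), the
base rescales values without reordering them, so no downstream conclusion
depends on the choice. A floor `q_floor = 1e-300` keeps $D$ finite when an
upstream tool reports $q = 0$.

## Coordinates and distance

Intervals are held as `GRanges` (1-based, closed), the standard container in
R genomics; BED-family formats (0-based, half-open) are converted at I/O and
round-trip bit-exactly. All distances are in bp. The peak–TSS distance is 0
when the TSS lies inside the peak and otherwise the distance to the nearest
covered base; "peak position" is sometimes taken to mean the midpoint
instead, and that is the main alternative a user may want when comparing with
other tools. The TSS is the strand-aware 5' transcript end.

The default distance-bin scheme is the set of non-overlapping cutoffs
0 exactly, 0–5 kb, 5–20 kb, 20–100 kb, 100–200 kb, 200–500 kb, and
500 kb–5 Mb, half-open `[lo, hi)`; published figures in this area use
several coarser schemes, so `distance_bins()` accepts any ordered
non-overlapping scheme. Genes beyond the outermost bin (or on peak-free
chromosomes) are left unassigned rather than forced into a bin. Nearest-peak
ties are broken deterministically toward the smaller genomic start.

## Overlap algebra and Venn partitioning

Two intervals overlap when they share at least `min_bp` bases on the same
chromosome. Peak-group construction conventionally requires `min_bp = 10`;
because no published rule exists for the multi-sample Venn figures
themselves, `venn_partition()` exposes `min_bp` (default 10) rather than
guessing a different one.

The exclusive Venn partition is defined by connected components of the
cross-set overlap graph: a peak of set A that overlaps peaks of B and C joins
the triple region even if the B and C peaks do not touch each other.
Components are the only definition that is simultaneously exclusive (every
peak in exactly one region) and exhaustive under chained overlap; per-set
region counts therefore always sum to the set totals, which the tests assert
exactly and the pipeline logs per run. Within-set overlaps do not link peaks.

## Differential bookkeeping

`bh_fdr()` applies the Benjamini–Hochberg step-up adjustment (via
`stats::p.adjust`; the test suite checks it against a literal transcription
of the step-up formula). Classification into up / down / unchanged uses a
*strict* `q < 0.05` threshold — a gene exactly at the threshold is unchanged
— and the three classes always partition the gene universe. Set-overlap
enrichment (`set_log2_enrichment()`) reports
$\log_2$ of observed-over-expected overlap with a hypergeometric tail
p-value; a t-test is sometimes quoted for such panels but cannot produce a
set-overlap p-value, so the hypergeometric tail is used deliberately.

## Fragmentomics

Tn5 inserts adapters 9 bp apart, so alignments are moved +4 bp (+ strand) or
−5 bp (− strand) onto the insertion centre (`tn5_shift()`). For whole
fragments the same per-mate correction moves the start +4 and the end −5,
shrinking the fragment by 9 bp; the synthetic generator draws sizes inside
the class ranges *post*-shift for this reason.

Fragment size classes: `< 100` bp nucleosome-free, 180–247 bp
mononucleosome, 315–473 bp dinucleosome, 558–615 bp trinucleosome. The gaps
between ranges are deliberately unclassified and excluded from nucleosome
analyses. Di- and trinucleosome fragments are replaced by two and three BED
regions of equal integer length, the last region absorbing the remainder, so
sub-regions tile the fragment exactly — a conservation law the tests check on
$10^5$ random fragments.

Coverage tracks are per-bp depths; the open-chromatin normalization scales by
$10^9 / \sum \text{aligned bp}$, and the cut-site (start-position)
normalization by $10^6 / N$ alignments. Footprint profiles average track
values in 10-bp bins across ±1 kb windows centred on supplied positions;
windows that would run off the chromosome start are excluded (configurable
by filtering centers beforehand) and counted. Whether NFR background regions
should be subtracted from footprints is not settled; no background
subtraction is applied, and the NFR track is emitted separately so users can
form their own ratio. Track comparison reports both Pearson and Spearman
coefficients — the latter so short regions of extreme enrichment do not
dominate — over per-bp vectors, with uncovered bases counted as 0.

## Enhancer landscape

A peak is an accessible enhancer when it overlaps at least one interval in
each of two histone-mark sets; the canonical pair is H3K4me1 + H3K27ac
(figure legends in the source literature occasionally swap in H3K4me3, so
the marks are plain arguments, not hard-wired). Mark overlap defaults to any
overlap (`min_bp = 1`); the 10-bp peak-group rule is available as an
alternative. Genomic context uses strand-aware promoter windows
(−1 kb, +500 bp) around the TSS with precedence
promoter > intragenic > intergenic.

## The synthetic-data generators

The generators exist so that every stage runs, and is validated, without
sequencing data. They emit the planted truth beside each dataset, so recovery
tests never re-derive it.

* **Association geometry.** Realizing nearest-peak distances up to 5 Mb
  requires isolation: on a dense genome (thousands of peaks per 100 Mb) every
  gene is within tens of kb of some peak and planted distances are
  unreachable. Each gene therefore occupies its own 12-Mb locus block
  (default 320 genes, 16 synthetic chromosomes), guaranteeing that the
  nearest differential peak of each direction is the gene's own planted one.
* **Planted structure.** 30% of genes are up-regulated (positive log2FC of
  mean 2, p-values $10^{-U(4,8)}$), 30% down (mirrored), 40% unchanged
  (log2FC ~ N(0, 0.25), p ~ U(0,1)). Each up-gene receives one *gained*
  accessibility peak at a distance drawn from a bin sampled uniformly over
  0–500 kb; each down-gene one *lost* peak within 0–5 kb; unchanged genes
  receive one peak of each direction spanning all bins, keeping every bin
  populated in both directions so that non-planted bins are tested against a
  class-balanced subset. This reproduces the qualitative structure the
  package is designed to detect: activation associated with accessibility
  out to 500 kb, repression confined to the TSS-proximal bin.
* **Fragments.** Mixture 0.5/0.3/0.15/0.05 over NFR/mono/di/tri; mono
  fragments are centred on planted dyads (jitter N(0, 10 bp)), di and tri on
  the midpoint of two and three 200-bp-spaced wrapped positions; NFR
  fragments fall uniformly.
* **Venn and enhancers.** Venn peak sets place one peak per member set at
  ≥2-kb-spaced anchors so planted region counts are recovered exactly;
  enhancer marks are constructed to cover their peaks, making truth recovery
  exact by construction, with one-mark decoys to exercise the
  both-marks-required rule.

What the generators do **not** emulate: read-level noise, mappability and GC
structure, MACS2 score distributions (scores are a monotone random column),
correlated replicate structure, peak-width biology, and chained many-to-many
peak–gene geometry on a dense genome. Passing recovery tests therefore shows
the *procedures* are correct on data with known structure, not that the
biological effect sizes in any real dataset are identifiable.

## Statistical validation choices

Parameter recovery of the planted distance model is checked by pooling
subset and background statistics over 20 seeded replicates and applying one
two-sided Wilcoxon rank-sum test per bin × direction at $\alpha = 0.01$,
with direction read from the rank-biserial sign. All planted bin/direction
combinations must be detected; among the seven non-planted combinations at
most one may exceed $\alpha$ (the binomial headroom for a 1% false-positive
rate). The FDR contract is checked by generating all-null tables across 50
seeds and requiring the mean fraction of genes at $q < 0.05$ to stay within
three standard errors of the nominal rate. Problem sizes throughout
(320 genes per replicate, $10^4$–$10^5$ fragments, $10^3$ peaks per random
oracle instance) were chosen so the full suite exercises every conservation
law and oracle comparison at comfortable statistical power.

## Known limitations

* Distances use the nearest-edge rule only; midpoint distance is provided as
  a configuration, not validated against external tools.
* The Q–Q background always includes the subset's own genes; excluding them
  is a defensible alternative that slightly sharpens deviations for small
  subsets.
* Venn partitioning is quadratic in the number of *overlap edges*, not
  peaks; pathological inputs (thousands of mutually overlapping peaks) are
  handled but slow.
* Footprint windows truncated at chromosome *ends* cannot be detected
  without sequence lengths, which plain BED inputs do not carry; only
  start-truncated windows are excluded.
* The pipeline consumes differential tables; it does not fit the
  differential model (edgeR/cuffdiff/DESeq2 territory), call peaks, or
  assign enhancers to genes through 3D contact data.
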