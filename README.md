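# chromassoc

Tools for linking chromatin accessibility to transcription in regulatory
epigenomics. The package grew out of studies of B-cell development in which
an epigenetic reader (BRWD1) reorders enhancer accessibility genome-wide; it
implements the analysis layer such studies need once peaks, differential
tables and fragments exist:

* **Merged differential statistic** — per gene,
  `D = log2FC × (−log10 q)`, combining effect size and Benjamini–Hochberg
  significance into one signed ordinal value.
* **Distance-binned peak–gene association** — genes binned by distance from
  their nearest peak (default cutoffs 0, 0–5 kb, 5–20 kb, 20–100 kb,
  100–200 kb, 200–500 kb, 500 kb–5 Mb), with per-bin Q–Q curves against the
  all-gene background, differential histograms, and hypergeometric bin
  enrichment.
* **Multi-set Venn partitioning** — exclusive assignment of peaks from 2–5
  samples to subset regions via connected components of the ≥ 10-bp
  cross-set overlap graph; per-set counts always sum to set totals.
* **Enhancer landscape** — enhancer = accessible peak overlapping both
  H3K4me1 and H3K27ac peaks; promoter (−1 kb, +500 bp) / intragenic /
  intergenic annotation; per-Venn-region composition summaries.
* **ATAC fragmentomics** — Tn5 +4/−5 insertion correction, nucleosome
  fragment-size classes (<100 NFR, 180–247 mono, 315–473 di, 558–615 tri),
  replacement of di/tri fragments by tiling BED regions, per-billion-bp and
  per-million-alignment normalized tracks, 10-bp-binned footprint profiles,
  Pearson/Spearman track correlation.
* **Seeded synthetic-data generators** that plant known gene classes,
  nearest-peak distance models, fragment mixtures phased on dyads, mark
  geometry and Venn counts, so the whole pipeline is testable offline.

Standard formats throughout: BED3/BED6, ENCODE narrowPeak, bedGraph,
TSV/CSV tables; intervals are `GenomicRanges::GRanges` in memory.

## Worked example

The `analysis/` directory holds the narrative workflow: `01_simulate.R`
writes the default synthetic study to `results/simulated/`, then
`02_association.R`, `03_fragmentomics.R` and `04_landscape.R` run the three
analyses over those files. From the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_association.R
```

prints (seed 1):

```
 gained accessibility peaks:
       bin median_qq_shift
         0    0.4958555838
     0-5kb    5.5624458402
 100-200kb    1.8097597183
  20-100kb    5.3377353020
 200-500kb    4.7193716112
    5-20kb    5.7962918637
 500kb-5Mb   -0.0001937207

 lost accessibility peaks:
       bin median_qq_shift
         0     0.001757289
     0-5kb    -9.789737487
 100-200kb     0.005780528
  20-100kb     0.023107663
 200-500kb     0.002655189
    5-20kb     0.001997567
 500kb-5Mb    -0.011875562
```

Each number is the median vertical displacement of the per-bin Q–Q curve of
the merged statistic `D` from the all-gene background: genes near *gained*
accessibility peaks show increased expression at every distance out to
500 kb (positive shifts; the 500 kb–5 Mb bin contains only unchanged genes
and sits on the identity line), while genes near *lost* peaks show decreased
expression only within 5 kb — exactly the planted structure. Programmatic
use mirrors the drivers:

```r
library(chromassoc)
sp    <- synth_spec(seed = 1)
genes <- gen_genome(sp)
diff  <- gen_differential_table(sp, genes)
pk    <- gen_peaks_with_distance_model(sp, genes, diff)
binned <- bin_genes_by_nearest_peak(genes, pk$peaks_up)
st     <- subset_statistics(binned, diff$table)
qq     <- qq_curve(st$subsets[["20-100kb"]], st$background)
```

`03_fragmentomics.R` reports the recovered fragment-class counts
(NFR 9981 / mono 6007 / di 3037 / tri 975 of 20,000, matching the planted
0.5/0.3/0.15/0.05 mixture) and nucleosome occupancy concentrated at the
planted dyads; `04_landscape.R` reports all seven planted Venn region counts
recovered exactly and enhancer-call accuracy 1.000 against planted truth.

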