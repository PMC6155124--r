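#!/usr/bin/env Rscript
# Enhancer landscape on the simulated peaks: Venn partition of the three
# stage peak sets, enhancer classification of the candidate peaks by
# histone-mark co-occurrence, and the per-region composition summary.

suppressMessages(library(chromassoc))

sim <- "results/simulated"
out <- "results/landscape"
stopifnot(file.exists(file.path(sim, "stage_A.bed")))

run_landscape(list(
  peak_sets = list(A = file.path(sim, "stage_A.bed"),
                   B = file.path(sim, "stage_B.bed"),
                   C = file.path(sim, "stage_C.bed")),
  mark1 = file.path(sim, "mark_h3k4me1.bed"),
  mark2 = file.path(sim, "mark_h3k27ac.bed"),
  genes = file.path(sim, "genes.tsv"),
  out_dir = out, seed = 1L
))

venn <- read.delim(file.path(out, "venn_counts.tsv"))
truth <- read.delim(file.path(sim, "truth_venn_counts.tsv"))
members <- vapply(strsplit(venn$subset, "&", fixed = TRUE), length, 0L)
venn$region_size <- venn$total / members
cat("\nVenn regions (recovered vs planted):\n")
print(merge(venn[, c("subset", "region_size")], truth,
            by.x = "subset", by.y = "region"), row.names = FALSE)

# Enhancer composition of the candidate peak set against its truth
cand <- read_peaks(file.path(sim, "enhancer_candidate_peaks.bed"))
m1 <- read_peaks(file.path(sim, "mark_h3k4me1.bed"))
m2 <- read_peaks(file.path(sim, "mark_h3k27ac.bed"))
called <- classify_enhancers(cand, m1, m2)
truth_e <- read.delim(file.path(sim, "truth_enhancers.tsv"))
cat(sprintf("\nEnhancer calls: %d of %d peaks (planted %d); accuracy %.3f\n",
            sum(called), length(cand), sum(truth_e$is_enhancer),
            mean(called == truth_e$is_enhancer)))
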