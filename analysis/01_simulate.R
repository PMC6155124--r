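#!/usr/bin/env Rscript
# Generate the default synthetic study inputs and write them, together with
# their planted truth, under results/simulated/ in the same standard formats
# the real pipeline reads (BED, TSV).

suppressMessages(library(chromassoc))

seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sp <- synth_spec(seed = seed)

genes <- gen_genome(sp)
gdf <- data.frame(gene_id = S4Vectors::mcols(genes)$gene_id,
                  chrom = as.character(GenomicRanges::seqnames(genes)),
                  strand = as.character(GenomicRanges::strand(genes)),
                  txStart = GenomicRanges::start(genes) - 1L,
                  txEnd = GenomicRanges::end(genes))
write.table(gdf, file.path(out, "genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

d <- gen_differential_table(sp, genes)
write.table(d$table[, c("gene_id", "log2fc", "pvalue", "qvalue")],
            file.path(out, "differential.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(d$truth, file.path(out, "truth_gene_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pk <- gen_peaks_with_distance_model(sp, genes, d)
write_peaks(pk$A, file.path(out, "atac_conditionA.bed"))
write_peaks(pk$B, file.path(out, "atac_conditionB.bed"))
write_peaks(pk$peaks_up, file.path(out, "peaks_gained.bed"))
write_peaks(pk$peaks_down, file.path(out, "peaks_lost.bed"))
write.table(pk$truth, file.path(out, "truth_planted_peaks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

spf <- synth_spec(seed = seed, n_fragments = 20000L)
fr <- gen_fragments(spf)
write_peaks(fr$fragments, file.path(out, "fragments.bed"))
write_peaks(fr$dyads, file.path(out, "truth_dyads.bed"))

me <- gen_marked_enhancers(sp)
write_peaks(me$peaks, file.path(out, "enhancer_candidate_peaks.bed"))
write_peaks(me$mark1, file.path(out, "mark_h3k4me1.bed"))
write_peaks(me$mark2, file.path(out, "mark_h3k27ac.bed"))
write.table(data.frame(peak = S4Vectors::mcols(me$peaks)$name,
                       is_enhancer = me$truth),
            file.path(out, "truth_enhancers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

vs <- gen_venn_peaksets(sp)
for (lab in names(vs$peak_sets)) {
  write_peaks(vs$peak_sets[[lab]], file.path(out, paste0("stage_", lab, ".bed")))
}
write.table(data.frame(region = names(vs$truth), planted = vs$truth),
            file.path(out, "truth_venn_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated inputs written to", out, "\n")
cat(sprintf("  %d genes (%d up / %d down planted), %d+%d condition peaks\n",
            length(genes), sum(d$truth$class == "up"),
            sum(d$truth$class == "down"), length(pk$A), length(pk$B)))
cat(sprintf("  %d fragments, %d candidate enhancer peaks, %d Venn peaks\n",
            length(fr$fragments), length(me$peaks),
            sum(vapply(vs$peak_sets, length, 0L))))
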