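#' Call accessible enhancers by histone-mark co-occurrence
#'
#' A peak is an enhancer when it overlaps at least one interval in *each* of
#' two histone-mark peak sets (canonically H3K4me1 and H3K27ac) by at least
#' `min_bp` bases — the open-chromatin+ mark1+ mark2+ definition.
#'
#' @param atac_peaks `GRanges` accessibility peaks.
#' @param mark1,mark2 `GRanges` histone-mark peak sets.
#' @param min_bp minimum overlap with each mark (default 1, any overlap; 10
#'   applies the peak-group rule instead).
#' @return logical vector, one flag per accessibility peak.
#' @export
classify_enhancers <- function(atac_peaks, mark1, mark2, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  hit <- function(marks) {
    suppressWarnings(
      GenomicRanges::countOverlaps(atac_peaks, marks, minoverlap = min_bp,
                                   ignore.strand = TRUE)) > 0L
  }
  hit(mark1) & hit(mark2)
}

#' Annotate peaks as promoter / intragenic / intergenic
#'
#' A peak is *promoter* if it overlaps any strand-aware promoter window
#' (-1 kb to +500 bp around a TSS; mirrored for `-`-strand genes), else
#' *intragenic* if it overlaps any gene body, else *intergenic*. Precedence:
#' promoter > intragenic > intergenic.
#'
#' @param peaks `GRanges`.
#' @param genes `GRanges` from [gene_annotation()] (non-empty).
#' @return character vector in `{"promoter", "intragenic", "intergenic"}`.
#' @export
annotate_genomic_region <- function(peaks, genes) {
  if (length(genes) == 0L) stop("empty gene annotation")
  prom <- GenomicRanges::promoters(genes, upstream = 1000L, downstream = 500L)
  prom <- GenomicRanges::trim(prom)
  in_prom <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, prom, ignore.strand = TRUE)) > 0L
  in_body <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, genes, ignore.strand = TRUE)) > 0L
  ifelse(in_prom, "promoter", ifelse(in_body, "intragenic", "intergenic"))
}

#' Per-Venn-region enhancer composition
#'
#' For each region of a peak Venn partition: total peak count, enhancer count
#' and fraction, and enhancer counts split by genomic context — the
#' number-and-percentage-of-enhancers summary per open-chromatin region.
#'
#' @param vp [venn_partition()] of the accessibility peak sets.
#' @param enhancer_flags named list (one logical vector per input set, in
#'   input peak order) from [classify_enhancers()].
#' @param region_classes named list (one character vector per input set) from
#'   [annotate_genomic_region()].
#' @return data.frame: subset, n_peaks, n_enhancers, pct_enhancer, and
#'   promoter / intragenic / intergenic enhancer counts.
#' @export
venn_enhancer_summary <- function(vp, enhancer_flags, region_classes) {
  stopifnot(inherits(vp, "venn_partition"))
  for (lab in vp$set_labels) {
    if (length(enhancer_flags[[lab]]) != vp$totals[[lab]] ||
        length(region_classes[[lab]]) != vp$totals[[lab]]) {
      stop("flags/classes must cover every peak of set ", lab)
    }
  }
  m <- vp$membership
  enh <- unlist(lapply(vp$set_labels, function(l) enhancer_flags[[l]]),
                use.names = FALSE)
  cls <- unlist(lapply(vp$set_labels, function(l) region_classes[[l]]),
                use.names = FALSE)
  if (anyNA(enh) || anyNA(cls)) stop("missing annotation for a peak")
  subsets <- rownames(vp$counts)
  rows <- lapply(subsets, function(s) {
    sel <- m$subset == s
    n <- sum(sel)
    ne <- sum(enh[sel])
    data.frame(subset = s, n_peaks = n, n_enhancers = ne,
               pct_enhancer = if (n > 0) ne / n else NA_real_,
               promoter = sum(enh[sel] & cls[sel] == "promoter"),
               intragenic = sum(enh[sel] & cls[sel] == "intragenic"),
               intergenic = sum(enh[sel] & cls[sel] == "intergenic"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
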