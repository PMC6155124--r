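# Orchestration over the analysis stages. Each run_* validates its config
# before any compute, writes tables under out_dir, and records a manifest
# (inputs, parameters, seed, package version) sufficient to reproduce the
# outputs byte-identically.

resolve_peaks <- function(x, what) {
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing ", what, " file: ", x)
    return(read_peaks(x))
  }
  stop(what, " must be a GRanges or a file path")
}

resolve_genes <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing gene annotation file: ", x)
    return(read_genes(x))
  }
  stop("genes must be a GRanges or a file path")
}

resolve_differential <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing differential table file: ", x)
    return(read_differential(x))
  }
  stop("differential must be a data.frame or a file path")
}

write_manifest <- function(out_dir, stage, params) {
  manifest <- c(list(stage = stage,
                     package = "chromassoc",
                     version = as.character(utils::packageVersion("chromassoc"))),
                params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
}

#' Run the peak–gene association analysis
#'
#' Bins genes by distance from their nearest peak in each supplied peak set,
#' then emits per-bin gene lists, Q–Q tables of the merged differential
#' statistic against the all-gene background, a differential histogram, and
#' per-bin hypergeometric enrichment for differentially regulated genes.
#'
#' @param config list with fields: `genes` (GRanges or path), `differential`
#'   (data.frame or path), `peak_sets` (named list of GRanges or paths, e.g.
#'   gained/lost accessibility peaks), `out_dir`; optional `bins`
#'   ([distance_bins()]), `q_threshold` (default 0.05), `n_points` (default
#'   199), `hist_edges`.
#' @return `out_dir`, invisibly; outputs written per peak set:
#'   `bin_genes_<set>.tsv`, `qq_<set>.tsv`, `enrichment_<set>.tsv`, plus
#'   `histogram.tsv` and `manifest.json`.
#' @export
run_association <- function(config) {
  need <- c("genes", "differential", "peak_sets", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  genes <- resolve_genes(config$genes)
  records <- resolve_differential(config$differential)
  if (is.null(names(config$peak_sets))) stop("peak_sets must be named")
  peak_sets <- lapply(names(config$peak_sets), function(nm)
    resolve_peaks(config$peak_sets[[nm]], nm))
  names(peak_sets) <- names(config$peak_sets)
  bins <- if (is.null(config$bins)) default_distance_bins() else config$bins
  q_threshold <- if (is.null(config$q_threshold)) 0.05 else config$q_threshold
  n_points <- if (is.null(config$n_points)) 199L else config$n_points

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- classify_genes(records, q_threshold)
  signif <- c(classes$up, classes$down)
  universe <- records$gene_id
  hist_edges <- if (is.null(config$hist_edges)) {
    lim <- max(abs(records$D), 1e-6)
    seq(-lim, lim, length.out = 41L)
  } else config$hist_edges

  hist_subsets <- list(background = records$D)
  for (nm in names(peak_sets)) {
    binned <- bin_genes_by_nearest_peak(genes, peak_sets[[nm]], bins)
    utils::write.table(binned$assignment,
                       file.path(out_dir, paste0("bin_genes_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_by_bin <- suppressWarnings(subset_statistics(binned, records))
    qq <- do.call(rbind, lapply(names(stats_by_bin$subsets), function(b) {
      v <- stats_by_bin$subsets[[b]]
      if (length(v) == 0L) return(NULL)
      cbind(bin = b, qq_curve(v, stats_by_bin$background, n_points))
    }))
    utils::write.table(qq, file.path(out_dir, paste0("qq_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- bin_enrichment_table(binned$by_bin, signif, universe)
    utils::write.table(enr,
                       file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    assigned <- unlist(binned$by_bin)
    hist_subsets[[nm]] <- stats_by_bin$background[match(assigned, universe)]
    log_stage("associate", nm, ":", length(peak_sets[[nm]]), "peaks,",
              length(assigned), "of", length(universe), "genes binned")
  }
  dh <- suppressWarnings(differential_histogram(hist_subsets, hist_edges))
  hist_df <- data.frame(lo = hist_edges[-length(hist_edges)],
                        hi = hist_edges[-1], dh$densities,
                        check.names = FALSE)
  utils::write.table(hist_df, file.path(out_dir, "histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "associate",
                 list(n_genes = length(genes),
                      peak_sets = lapply(peak_sets, length),
                      bins = bins, q_threshold = q_threshold,
                      n_points = n_points,
                      seed = config$seed))
  invisible(out_dir)
}

#' Run the ATAC fragmentomics analysis
#'
#' Applies the Tn5 +4/-5 correction to fragments, tabulates nucleosome
#' classes, replaces classified fragments by their nucleosome BED regions,
#' and writes normalized coverage tracks (nucleosome signal and NFR
#' background) plus optional footprint profiles around supplied centers.
#'
#' @param config list with fields: `fragments` (GRanges or BED path),
#'   `out_dir`; optional `centers` (GRanges), `half_width` (default 1000),
#'   `bin_width` (default 10), `shift` (apply Tn5 correction, default TRUE).
#' @return `out_dir`, invisibly; writes `class_counts.tsv`,
#'   `shifted_fragments.bed`, `nucleosome_regions.bed`, `nucleosome.bedgraph`,
#'   `nfr.bedgraph`, optional `footprint.tsv`, and `manifest.json`.
#' @export
run_fragmentomics <- function(config) {
  need <- c("fragments", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  fr <- if (inherits(config$fragments, "GRanges")) config$fragments else {
    if (!file.exists(config$fragments)) {
      stop("missing fragment file: ", config$fragments)
    }
    read_fragments(config$fragments)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  shift <- if (is.null(config$shift)) TRUE else config$shift
  if (shift) fr <- tn5_shift(fr, mode = "fragment")
  write_peaks(fr, file.path(out_dir, "shifted_fragments.bed"))
  cc <- fragment_class_counts(fr)
  utils::write.table(cc, file.path(out_dir, "class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- classify_fragment(GenomicRanges::width(fr))
  nuc <- nucleosome_regions(fr[cls %in% c("mono", "di", "tri")])
  write_peaks(nuc, file.path(out_dir, "nucleosome_regions.bed"))
  nfr <- fr[cls == "NFR"]
  write_bedgraph(coverage_track(nuc, "per_billion_aligned_bp"),
                 file.path(out_dir, "nucleosome.bedgraph"))
  if (length(nfr)) {
    write_bedgraph(coverage_track(nfr, "per_billion_aligned_bp"),
                   file.path(out_dir, "nfr.bedgraph"))
  }
  if (!is.null(config$centers)) {
    hw <- if (is.null(config$half_width)) 1000L else config$half_width
    bw <- if (is.null(config$bin_width)) 10L else config$bin_width
    fp <- footprint_profile(coverage_track(nuc, "per_billion_aligned_bp"),
                            config$centers, hw, bw)
    utils::write.table(
      data.frame(bin_center = seq(-hw + bw / 2, hw - bw / 2, by = bw),
                 value = fp$values),
      file.path(out_dir, "footprint.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_stage("fragmentomics", length(fr), "fragments;",
            sum(cc$count[cc$nuc_class != "unclassified"]), "classified")
  write_manifest(out_dir, "fragmentomics",
                 list(n_fragments = length(fr), shift = shift,
                      class_counts = stats::setNames(as.list(cc$count),
                                                     cc$nuc_class),
                      seed = config$seed))
  invisible(out_dir)
}

#' Run the enhancer-landscape analysis
#'
#' Venn-partitions the accessibility peak sets, classifies each peak as an
#' enhancer by histone-mark co-occurrence, annotates genomic context, and
#' writes the per-Venn-region composition summary.
#'
#' @param config list with fields: `peak_sets` (named list of GRanges or
#'   paths), `mark1`, `mark2` (GRanges or paths), `genes` (GRanges or path),
#'   `out_dir`; optional `min_bp` (Venn overlap rule, default 10),
#'   `mark_min_bp` (mark overlap rule, default 1).
#' @return `out_dir`, invisibly; writes `venn_counts.tsv`, per-region BEDs,
#'   `annotated_<set>.tsv`, `enhancer_summary.tsv`, `manifest.json`.
#' @export
run_landscape <- function(config) {
  need <- c("peak_sets", "mark1", "mark2", "genes", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(names(config$peak_sets))) stop("peak_sets must be named")
  peak_sets <- lapply(names(config$peak_sets), function(nm)
    resolve_peaks(config$peak_sets[[nm]], nm))
  names(peak_sets) <- names(config$peak_sets)
  mark1 <- resolve_peaks(config$mark1, "mark1")
  mark2 <- resolve_peaks(config$mark2, "mark2")
  genes <- resolve_genes(config$genes)
  min_bp <- if (is.null(config$min_bp)) 10L else config$min_bp
  mark_min_bp <- if (is.null(config$mark_min_bp)) 1L else config$mark_min_bp
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vp <- venn_partition(peak_sets, min_bp)
  write_venn(vp, out_dir)
  flags <- lapply(peak_sets, classify_enhancers, mark1 = mark1,
                  mark2 = mark2, min_bp = mark_min_bp)
  classes <- lapply(peak_sets, annotate_genomic_region, genes = genes)
  for (nm in names(peak_sets)) {
    ann <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(peak_sets[[nm]])),
      start = GenomicRanges::start(peak_sets[[nm]]) - 1L,
      end = GenomicRanges::end(peak_sets[[nm]]),
      is_enhancer = flags[[nm]], region_class = classes[[nm]])
    utils::write.table(ann,
                       file.path(out_dir, paste0("annotated_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- venn_enhancer_summary(vp, flags, classes)
  utils::write.table(summary, file.path(out_dir, "enhancer_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("landscape", sum(vp$totals), "peaks in",
            length(peak_sets), "sets;", sum(summary$n_enhancers), "enhancers")
  write_manifest(out_dir, "landscape",
                 list(totals = as.list(vp$totals), min_bp = min_bp,
                      mark_min_bp = mark_min_bp, seed = config$seed))
  invisible(out_dir)
}
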