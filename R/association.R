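#' Construct a gene annotation from 0-based transcript coordinates
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param txStart,txEnd 0-based half-open transcript span (UCSC flat-table
#'   convention).
#' @return `GRanges` with a `gene_id` metadata column; the TSS is the
#'   strand-aware 5' end (txStart for `+` genes, txEnd - 1 for `-` genes).
#' @export
gene_annotation <- function(gene_id, chrom, strand, txStart, txEnd) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (any(txStart >= txEnd)) stop("txStart must be < txEnd")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(as.integer(txStart) + 1L,
                                                as.integer(txEnd)),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  gr
}

#' Read a gene annotation flat table
#'
#' Tab-separated with header: gene_id, chrom, strand, txStart, txEnd
#' (0-based half-open).
#'
#' @param path file path.
#' @return `GRanges` as from [gene_annotation()].
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  gene_annotation(df$gene_id, df$chrom, df$strand, df$txStart, df$txEnd)
}

#' Strand-aware TSS positions of genes
#'
#' @param genes `GRanges` from [gene_annotation()].
#' @return width-1 `GRanges` at each gene's transcription start site.
#' @export
tss_positions <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' Distance between a peak and a gene's TSS
#'
#' Zero when the TSS falls inside the peak; otherwise the distance in bases
#' from the TSS to the nearest end of the peak; `Inf` across chromosomes.
#' Vectorised elementwise over equal-length (or length-1) inputs.
#'
#' @param peaks `GRanges` peaks.
#' @param genes `GRanges` genes ([gene_annotation()]).
#' @return numeric vector of distances in bp.
#' @export
peak_tss_distance <- function(peaks, genes) {
  tss <- tss_positions(genes)
  n <- max(length(peaks), length(tss))
  if (length(peaks) == 1L) peaks <- rep(peaks, n)
  if (length(tss) == 1L) tss <- rep(tss, n)
  t_pos <- GenomicRanges::start(tss)
  s <- GenomicRanges::start(peaks)
  e <- GenomicRanges::end(peaks)
  d <- ifelse(t_pos >= s & t_pos <= e, 0,
              pmin(abs(t_pos - s), abs(t_pos - e)))
  same <- as.character(GenomicRanges::seqnames(peaks)) ==
    as.character(GenomicRanges::seqnames(tss))
  ifelse(same, d, Inf)
}

#' Distance-bin scheme
#'
#' Half-open `[lo, hi)` bins in bp; must be non-overlapping and ordered.
#' The default scheme follows the non-overlapping TSS-distance cutoffs used
#' for peak–gene association: 0 exactly, then 0–5 kb, 5–20 kb, 20–100 kb,
#' 100–200 kb, 200–500 kb and 500 kb–5 Mb.
#'
#' @param label bin names.
#' @param lo,hi inclusive lower / exclusive upper distance bounds in bp.
#' @return data.frame with columns label, lo, hi.
#' @export
distance_bins <- function(label, lo, hi) {
  if (any(lo >= hi) || any(lo < 0)) stop("bins need 0 <= lo < hi")
  if (is.unsorted(lo, strictly = TRUE) || any(hi[-length(hi)] > lo[-1])) {
    stop("bins must be ordered and non-overlapping")
  }
  data.frame(label = as.character(label), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' @rdname distance_bins
#' @export
default_distance_bins <- function() {
  distance_bins(
    label = c("0", "0-5kb", "5-20kb", "20-100kb", "100-200kb",
              "200-500kb", "500kb-5Mb"),
    lo = c(0, 1, 5e3, 2e4, 1e5, 2e5, 5e5),
    hi = c(1, 5e3, 2e4, 1e5, 2e5, 5e5, 5e6)
  )
}

#' Assign genes to distance bins by their nearest peak
#'
#' For each gene, the distance to the nearest peak (per
#' [peak_tss_distance()]) selects the bin containing it; genes farther than
#' every bin (or on peak-free chromosomes) are left unassigned. Nearest-peak
#' ties are broken toward the smaller genomic start coordinate.
#'
#' @param genes `GRanges` genes.
#' @param peaks `GRanges` peaks.
#' @param bins bin scheme from [distance_bins()].
#' @return list with `assignment` (data.frame gene_id, distance,
#'   nearest_peak index, bin) and `by_bin` (named list bin label -> gene ids).
#' @export
bin_genes_by_nearest_peak <- function(genes, peaks,
                                      bins = default_distance_bins()) {
  gene_id <- S4Vectors::mcols(genes)$gene_id
  ng <- length(genes)
  dist <- rep(Inf, ng)
  nearest <- rep(NA_integer_, ng)
  if (length(peaks) == 0L) {
    warning("empty peak set: all genes unassigned")
  } else {
    tss <- tss_positions(genes)
    hits <- suppressWarnings(
      GenomicRanges::distanceToNearest(tss, peaks, select = "all",
                                       ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      d_exact <- peak_tss_distance(peaks[sh], genes[qh])
      ps <- GenomicRanges::start(peaks)[sh]
      # per gene: minimal exact distance, ties to smallest peak start
      o <- order(qh, d_exact, ps)
      first <- !duplicated(qh[o])
      dist[qh[o][first]] <- d_exact[o][first]
      nearest[qh[o][first]] <- sh[o][first]
    }
  }
  bin <- rep(NA_character_, ng)
  for (i in seq_len(nrow(bins))) {
    inbin <- is.finite(dist) & dist >= bins$lo[i] & dist < bins$hi[i]
    bin[inbin] <- bins$label[i]
  }
  assignment <- data.frame(gene_id = gene_id, distance = dist,
                           nearest_peak = nearest, bin = bin,
                           stringsAsFactors = FALSE)
  by_bin <- lapply(stats::setNames(bins$label, bins$label),
                   function(b) gene_id[!is.na(bin) & bin == b])
  list(assignment = assignment, bins = bins, by_bin = by_bin)
}

#' Per-bin merged-statistic vectors
#'
#' Resolves each binned gene set against a differential table and returns the
#' vector of merged statistics D per bin; the background is every gene's D.
#'
#' @param binned result of [bin_genes_by_nearest_peak()] (or a named list of
#'   gene-id vectors).
#' @param records differential table ([differential_table()]).
#' @return list with `subsets` (named list of D vectors) and `background`.
#' @export
subset_statistics <- function(binned, records) {
  by_bin <- if (is.list(binned) && !is.null(binned$by_bin)) binned$by_bin else binned
  missing <- setdiff(unique(unlist(by_bin)), records$gene_id)
  if (length(missing)) {
    stop("gene ids absent from differential table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  D <- stats::setNames(records$D, records$gene_id)
  subsets <- lapply(by_bin, function(g) {
    if (length(g) == 0L) warning("empty bin")
    unname(D[g])
  })
  list(subsets = subsets, background = unname(records$D))
}

#' Quantile–quantile curve of a subset against the background
#'
#' Evaluates matched empirical quantiles (linear interpolation between order
#' statistics, `stats::quantile` type 7) of a gene subset's statistic and the
#' all-gene background on a shared probability grid. A subset drawn from the
#' background lies on the identity line; vertical deviation shows the
#' direction and size of the distribution shift.
#'
#' @param subset numeric vector of subset statistics (non-empty).
#' @param background numeric vector of background statistics.
#' @param n_points number of evenly spaced grid probabilities (default 199,
#'   i.e. `k/200` for `k = 1..199`).
#' @param probs optional explicit probability grid in (0, 1).
#' @return data.frame with columns prob, background_q, subset_q.
#' @export
qq_curve <- function(subset, background, n_points = 199L, probs = NULL) {
  if (length(subset) == 0L) stop("empty subset")
  if (is.null(probs)) {
    if (n_points < 2L) stop("n_points must be >= 2")
    probs <- seq_len(n_points) / (n_points + 1L)
  }
  if (any(probs <= 0) || any(probs >= 1)) stop("probs must lie in (0, 1)")
  data.frame(
    prob = probs,
    background_q = unname(stats::quantile(background, probs, type = 7)),
    subset_q = unname(stats::quantile(subset, probs, type = 7))
  )
}

#' Differential histogram over shared bin edges
#'
#' Per-subset probability masses of the merged statistic over one common set
#' of edges; each subset's masses sum to 1. Values outside the edge range are
#' clipped into the end bins (with a warning).
#'
#' @param subsets named list of numeric vectors.
#' @param bin_edges strictly increasing numeric edges (length >= 2).
#' @return list with `bin_edges` and `densities`, an (nbins x nsubsets)
#'   matrix of probability masses.
#' @export
differential_histogram <- function(subsets, bin_edges) {
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing, length >= 2")
  }
  nb <- length(bin_edges) - 1L
  dens <- vapply(subsets, function(v) {
    if (length(v) == 0L) return(rep(NA_real_, nb))
    if (any(v < bin_edges[1] | v >= bin_edges[length(bin_edges)])) {
      warning("values outside edge range clipped into end bins")
    }
    idx <- findInterval(v, bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = nb) / length(v)
  }, numeric(nb))
  list(bin_edges = bin_edges,
       densities = matrix(dens, nrow = nb,
                          dimnames = list(NULL, names(subsets))))
}

#' Hypergeometric enrichment of significant genes in a distance bin
#'
#' Upper-tail probability of drawing at least the observed number of
#' significant genes when `|bin|` genes are sampled without replacement from
#' the universe.
#'
#' @param bin_genes,signif_genes,universe character vectors of gene ids;
#'   `bin_genes` and `signif_genes` are subsets of `universe`.
#' @return upper-tail p-value.
#' @export
bin_enrichment_test <- function(bin_genes, signif_genes, universe) {
  if (length(universe) == 0L) stop("empty universe")
  N <- length(unique(universe))
  K <- length(unique(signif_genes))
  n <- length(unique(bin_genes))
  k <- length(intersect(bin_genes, signif_genes))
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Per-bin enrichment table with BH correction across bins
#'
#' @param by_bin named list bin label -> gene ids.
#' @param signif_genes significant gene ids.
#' @param universe all gene ids.
#' @return data.frame: bin, n, overlap, p, q (BH across bins).
#' @export
bin_enrichment_table <- function(by_bin, signif_genes, universe) {
  p <- vapply(by_bin, bin_enrichment_test, 0, signif_genes = signif_genes,
              universe = universe)
  data.frame(bin = names(by_bin),
             n = vapply(by_bin, length, 0L),
             overlap = vapply(by_bin, function(g)
               length(intersect(g, signif_genes)), 0L),
             p = unname(p), q = bh_fdr(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}
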