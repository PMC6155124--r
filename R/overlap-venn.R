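#' Test whether two intervals overlap by at least `min_bp` bases
#'
#' Vectorised over pairs. Overlap length is the size of the intersection of
#' the two base intervals; intervals on different chromosomes never overlap.
#' `min_bp = 1` is the ordinary intersection test; peak-group construction
#' conventionally uses `min_bp = 10`.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param min_bp minimum shared bases (>= 1).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 10L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  same & ov >= min_bp
}

#' Partition peaks across samples into exclusive Venn regions
#'
#' Peaks from k sets are linked into connected components whenever a peak of
#' one set overlaps a peak of a *different* set by at least `min_bp` bases.
#' Each component is assigned to the Venn region named by the sets represented
#' in it, so every input peak lands in exactly one region and per-set region
#' counts sum to the set totals — the exclusive partition shown in multi-sample
#' open-chromatin Venn diagrams.
#'
#' @param peak_sets named list of `GRanges` (2 to 5 sets, unique names).
#' @param min_bp minimum cross-set overlap in bases (default 10).
#' @return An object of class `venn_partition`: list with `set_labels`,
#'   `counts` (region x set matrix), `totals`, `membership` (per-peak region
#'   assignment), and `regions` (per region, per set, the assigned peaks).
#' @export
venn_partition <- function(peak_sets, min_bp = 10L) {
  labels <- names(peak_sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("peak_sets must be a named list")
  }
  if (anyDuplicated(labels)) stop("duplicate set labels")
  k <- length(peak_sets)
  if (k < 2L || k > 5L) stop("venn_partition needs 2 to 5 peak sets")
  if (min_bp < 1L) stop("min_bp must be >= 1")

  sizes <- vapply(peak_sets, length, 0L)
  all_gr <- suppressWarnings(do.call(c, unname(lapply(peak_sets, GenomicRanges::granges))))
  set_of <- rep(seq_len(k), sizes)
  n <- length(all_gr)

  # union-find with path halving over cross-set overlap edges
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 0L) {
    hits <- GenomicRanges::findOverlaps(all_gr, minoverlap = min_bp,
                                        drop.self = TRUE, drop.redundant = TRUE,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cross <- set_of[qh] != set_of[sh]
    qh <- qh[cross]; sh <- sh[cross]
    for (e in seq_along(qh)) {
      ra <- find(qh[e]); rb <- find(sh[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), find, 0L)

  # region label per component = sorted labels of the sets represented in it
  subset_of_peak <- character(n)
  for (ix in split(seq_len(n), root)) {
    subset_of_peak[ix] <- paste(labels[sort(unique(set_of[ix]))], collapse = "&")
  }

  all_subsets <- unlist(lapply(seq_len(k), function(m) {
    apply(utils::combn(labels, m), 2L, paste, collapse = "&")
  }))
  tab <- table(factor(subset_of_peak, levels = all_subsets),
               factor(set_of, levels = seq_len(k)))
  counts <- matrix(as.integer(tab), nrow = length(all_subsets), ncol = k,
                   dimnames = list(all_subsets, labels))

  offs <- c(0L, cumsum(sizes))
  regions <- lapply(all_subsets, function(s) {
    out <- lapply(seq_len(k), function(j) {
      if (sizes[j] == 0L) return(peak_sets[[j]][0])
      local_lab <- subset_of_peak[(offs[j] + 1L):(offs[j] + sizes[j])]
      peak_sets[[j]][local_lab == s]
    })
    names(out) <- labels
    out
  })
  names(regions) <- all_subsets

  structure(list(
    set_labels = labels,
    min_bp = as.integer(min_bp),
    counts = counts,
    totals = stats::setNames(as.integer(sizes), labels),
    membership = data.frame(set = labels[set_of],
                            index = unlist(lapply(sizes, seq_len), use.names = FALSE),
                            subset = subset_of_peak,
                            stringsAsFactors = FALSE),
    regions = regions
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", length(x$set_labels), "peak sets (min overlap",
      x$min_bp, "bp)\n")
  nonzero <- rowSums(x$counts) > 0
  tot <- rowSums(x$counts[nonzero, , drop = FALSE])
  print(cbind(x$counts[nonzero, , drop = FALSE], total = tot))
  invisible(x)
}

#' Region counts of a Venn partition as a data frame
#'
#' @param vp a `venn_partition`.
#' @return data.frame with one row per Venn region: subset label, per-set
#'   counts, and the total peak count in the region.
#' @export
venn_counts <- function(vp) {
  stopifnot(inherits(vp, "venn_partition"))
  data.frame(subset = rownames(vp$counts), vp$counts,
             total = rowSums(vp$counts),
             check.names = FALSE, row.names = NULL)
}

#' Export a Venn partition as TSV and per-region BED files
#'
#' @param vp a `venn_partition`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_venn <- function(vp, dir) {
  stopifnot(inherits(vp, "venn_partition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "venn_counts.tsv")
  utils::write.table(venn_counts(vp), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- tsv
  for (s in names(vp$regions)) {
    gr <- suppressWarnings(do.call(c, unname(lapply(vp$regions[[s]],
                                                    GenomicRanges::granges))))
    if (length(gr) == 0L) next
    p <- file.path(dir, paste0("region_", gsub("&", "_AND_", s), ".bed"))
    write_peaks(sort_peaks(gr), p, format = "BED")
    paths <- c(paths, p)
  }
  invisible(paths)
}
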