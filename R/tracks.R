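#' Piecewise-constant signal track
#'
#' A thin wrapper around a per-chromosome [S4Vectors::RleList]: non-negative
#' coverage-like values over bp intervals plus a record of the normalization
#' applied. Positions beyond the stored run length are implicitly zero.
#'
#' @param cov `RleList` (one numeric/integer `Rle` per chromosome).
#' @param normalization one of `"raw"`, `"per_billion_aligned_bp"`,
#'   `"per_million_alignments"`.
#' @param scale_factor multiplier that was applied to the raw depths.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(cov, normalization = "raw", scale_factor = 1) {
  structure(list(cov = cov, normalization = normalization,
                 scale_factor = scale_factor),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$cov), "chromosome(s),",
      x$normalization, "normalization\n")
  invisible(x)
}

#' Per-base coverage track from intervals
#'
#' Depth at each base is the number of intervals covering it (bedtools
#' genomecov semantics). With `per_billion_aligned_bp` the depths are scaled
#' by `1e9 / sum(interval lengths)` — the open-chromatin enrichment-track
#' normalization.
#'
#' @param intervals non-empty `GRanges`.
#' @param normalization `"raw"` or `"per_billion_aligned_bp"`.
#' @return a [signal_track()].
#' @export
coverage_track <- function(intervals,
                           normalization = c("raw", "per_billion_aligned_bp")) {
  normalization <- match.arg(normalization)
  if (length(intervals) == 0L) stop("coverage_track: empty input")
  cov <- GenomicRanges::coverage(intervals)
  sf <- 1
  if (normalization == "per_billion_aligned_bp") {
    sf <- 1e9 / sum(as.numeric(GenomicRanges::width(intervals)))
    cov <- cov * sf
  }
  signal_track(cov, normalization, sf)
}

#' Cut-site (start-position) track from stranded alignments
#'
#' Places unit mass at the strand-appropriate terminal base of each
#' alignment: the first base for `+`-strand records, the last base for
#' `-`-strand records. With `per_million_alignments` masses are scaled by
#' `1e6 / N` so the total track mass is one million.
#'
#' @param alignments stranded `GRanges` (strand `*` is an error).
#' @param normalization `"raw"` or `"per_million_alignments"`.
#' @return a [signal_track()].
#' @export
cutsite_track <- function(alignments,
                          normalization = c("raw", "per_million_alignments")) {
  normalization <- match.arg(normalization)
  if (length(alignments) == 0L) stop("cutsite_track: empty input")
  if (any(as.character(GenomicRanges::strand(alignments)) == "*")) {
    stop("cutsite_track: unstranded alignment")
  }
  cuts <- GenomicRanges::resize(alignments, width = 1L, fix = "start")
  cov <- GenomicRanges::coverage(cuts)
  sf <- 1
  if (normalization == "per_million_alignments") {
    sf <- 1e6 / length(alignments)
    cov <- cov * sf
  }
  signal_track(cov, normalization, sf)
}

#' Extract per-base values of a track over a window
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end 1-based closed window; positions outside the stored run
#'   (or on chromosomes absent from the track) return 0.
#' @return numeric vector of length `end - start + 1`.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start + 1L
  if (!(chrom %in% names(track$cov))) return(numeric(n))
  r <- track$cov[[chrom]]
  len <- length(r)
  out <- numeric(n)
  lo <- max(start, 1L)
  hi <- min(end, len)
  if (lo <= hi) {
    out[(lo - start + 1L):(hi - start + 1L)] <-
      as.numeric(S4Vectors::window(r, lo, hi))
  }
  out
}

#' Footprint profile: binned average signal around aligned centers
#'
#' For each center, the `+/- half_width` window of track values is extracted,
#' averaged within consecutive `bin_width`-bp bins, and the per-bin values are
#' averaged across centers — the aggregate accessibility/occupancy footprint
#' around peak summits or motif sites. Windows that would run off the start
#' of a chromosome are excluded (and counted).
#'
#' @param track a [signal_track()].
#' @param centers width-1 `GRanges` (or any `GRanges`; midpoints are used).
#' @param half_width window half-size in bp (default 1000).
#' @param bin_width bin size in bp (default 10); must divide `2 * half_width`.
#' @return object of class `footprint_profile`: list with `values`
#'   (length `2 * half_width / bin_width`), `bin_width`, `half_width`,
#'   `n_regions` used and `n_excluded`.
#' @export
footprint_profile <- function(track, centers, half_width = 1000L,
                              bin_width = 10L) {
  if (length(centers) == 0L) stop("footprint_profile: no centers")
  if ((2L * half_width) %% bin_width != 0L) {
    stop("bin_width must divide 2 * half_width")
  }
  mid <- (GenomicRanges::start(centers) + GenomicRanges::end(centers)) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(centers))
  wstart <- mid - half_width
  keep <- wstart >= 1L
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("all footprint windows truncated at chromosome start")
  mid <- mid[keep]; chrom <- chrom[keep]; wstart <- wstart[keep]
  win <- 2L * half_width
  nb <- win %/% bin_width
  mat <- vapply(seq_along(mid), function(i) {
    v <- track_values(track, chrom[i], wstart[i], wstart[i] + win - 1L)
    colMeans(matrix(v, nrow = bin_width, ncol = nb))
  }, numeric(nb))
  structure(list(values = rowMeans(matrix(mat, nrow = nb)),
                 bin_width = as.integer(bin_width),
                 half_width = as.integer(half_width),
                 n_regions = length(mid), n_excluded = n_excluded),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat("footprint_profile: +/-", x$half_width, "bp,", x$bin_width,
      "bp bins,", x$n_regions, "regions\n")
  invisible(x)
}

#' Pearson and Spearman correlation of two tracks over a region
#'
#' Correlations of the per-base value vectors within the region; bases not
#' covered by a track count as 0. Spearman is reported alongside Pearson so
#' regions of very high enrichment do not dominate. Zero-variance input gives
#' `NaN` with a warning.
#'
#' @param a,b [signal_track()] objects.
#' @param region single-interval `GRanges`.
#' @return list with `pearson` and `spearman`.
#' @export
correlate_tracks <- function(a, b, region) {
  stopifnot(length(region) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(region))
  va <- track_values(a, chrom, GenomicRanges::start(region),
                     GenomicRanges::end(region))
  vb <- track_values(b, chrom, GenomicRanges::start(region),
                     GenomicRanges::end(region))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance track over region: correlation undefined")
    return(list(pearson = NaN, spearman = NaN))
  }
  list(pearson = stats::cor(va, vb, method = "pearson"),
       spearman = stats::cor(va, vb, method = "spearman"))
}

#' Write a signal track as 4-column sorted bedGraph
#'
#' Runs with value 0 are omitted; coordinates are 0-based half-open.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in sort(names(track$cov))) {
    r <- track$cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- as.numeric(S4Vectors::runValue(r))
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(paste(chrom, starts[keep], ends[keep],
                     sprintf("%.17g", vals[keep]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a 4-column bedGraph into a signal track
#'
#' @param path bedGraph path (0-based half-open intervals).
#' @param normalization label recorded on the returned track.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, normalization = "raw") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("invalid bedGraph interval in ", path)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  cov <- GenomicRanges::coverage(gr, weight = df$value)
  signal_track(cov, normalization, 1)
}
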