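#' Construct a peak set from 0-based half-open coordinates
#'
#' Peaks, histone-mark intervals and other genomic regions are represented
#' throughout as [GenomicRanges::GRanges] (1-based, closed). This constructor
#' accepts the BED convention (0-based start, half-open end) used by every
#' on-disk format the package reads and writes.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`end` exclusive).
#' @param strand strand codes (`"+"`, `"-"`, `"*"`); recycled.
#' @param score optional numeric peak score (e.g. MACS2 -log10 q).
#' @param name optional peak labels.
#' @param label sample/condition identifier stored in `metadata()$label`.
#' @param assay free-text provenance (e.g. `"ATAC"`, `"H3K27ac ChIP"`).
#' @param sort sort by (chrom, start, end)? Default `TRUE`.
#' @return A `GRanges` with `score` and `name` metadata columns.
#' @export
as_peaks <- function(chrom, start, end, strand = "*", score = NA_real_,
                     name = NA_character_, label = NA_character_,
                     assay = NA_character_, sort = TRUE) {
  if (any(start < 0L)) stop("start must be >= 0 (0-based half-open input)")
  if (any(end <= start)) stop("end must be > start for every interval")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand
  )
  S4Vectors::mcols(gr)$score <- as.numeric(score)
  S4Vectors::mcols(gr)$name <- as.character(name)
  if (sort) gr <- sort_peaks(gr)
  S4Vectors::metadata(gr)$label <- label
  S4Vectors::metadata(gr)$assay <- assay
  gr
}

#' @keywords internal
sort_peaks <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Read peaks from BED or narrowPeak
#'
#' A strict reader for BED3/BED6 and ENCODE 10-column narrowPeak. Coordinates
#' on disk are 0-based half-open and are converted to `GRanges`. Malformed
#' lines raise an error naming the offending line; identical duplicate
#' intervals are dropped with a warning.
#'
#' @param path file path.
#' @param format `"BED"` or `"narrowPeak"`.
#' @param label sample/condition identifier attached to the returned set.
#' @param dedup drop identical duplicate intervals with a warning (default
#'   `TRUE`; fragment readers keep duplicates, which are real observations).
#' @return sorted `GRanges` with `score`/`name` metadata columns.
#' @export
read_peaks <- function(path, format = c("BED", "narrowPeak"),
                       label = basename(path), dedup = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(as_peaks(character(), integer(), integer(), label = label)[0])
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < need)
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected >= %d fields, found %d",
                 idx[bad[1]], path, need, nf[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("line %d of %s: non-numeric coordinates", idx[bad[1]], path))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("line %d of %s: invalid interval %s:%d-%d (need 0 <= start < end)",
                 idx[bad[1]], path, chrom[bad[1]],
                 as.integer(start[bad[1]]), as.integer(end[bad[1]])))
  }
  name <- rep(NA_character_, length(chrom))
  score <- rep(NA_real_, length(chrom))
  strand <- rep("*", length(chrom))
  if (format == "narrowPeak" || any(nf >= 4L)) {
    has <- nf >= 4L
    name[has] <- vapply(fields[has], `[[`, "", 4L)
  }
  if (format == "narrowPeak" || any(nf >= 5L)) {
    has <- nf >= 5L
    score[has] <- suppressWarnings(as.numeric(vapply(fields[has], `[[`, "", 5L)))
  }
  if (format == "narrowPeak" || any(nf >= 6L)) {
    has <- nf >= 6L
    s6 <- vapply(fields[has], `[[`, "", 6L)
    strand[has] <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  key <- paste(chrom, start, end, sep = "\r")
  if (dedup && anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate interval(s) dropped from ", path)
    keep2 <- !duplicated(key)
    chrom <- chrom[keep2]; start <- start[keep2]; end <- end[keep2]
    name <- name[keep2]; score <- score[keep2]; strand <- strand[keep2]
  }
  as_peaks(chrom, start, end, strand = strand, score = score, name = name,
           label = label, assay = if (format == "narrowPeak") "narrowPeak" else NA)
}

#' Write peaks as BED or narrowPeak
#'
#' Inverse of [read_peaks()]: emits 0-based half-open coordinates. Scores are
#' printed with full precision so read/write round-trips are bit-exact.
#'
#' @param peaks `GRanges` with optional `score`/`name` metadata columns.
#' @param path output path.
#' @param format `"BED"` (6 columns; trailing defaults trimmed to BED3 when no
#'   name/score/strand information is present) or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("BED", "narrowPeak")) {
  format <- match.arg(format)
  n <- length(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start <- GenomicRanges::start(peaks) - 1L
  end <- GenomicRanges::end(peaks)
  score <- S4Vectors::mcols(peaks)$score
  if (is.null(score)) score <- rep(NA_real_, n)
  name <- S4Vectors::mcols(peaks)$name
  if (is.null(name)) name <- rep(NA_character_, n)
  strand <- as.character(GenomicRanges::strand(peaks))
  fmt_num <- function(x) ifelse(is.na(x), "0", sprintf("%.17g", x))
  if (format == "BED") {
    plain <- all(is.na(score)) && all(is.na(name)) && all(strand == "*")
    lines <- if (plain) {
      paste(chrom, start, end, sep = "\t")
    } else {
      paste(chrom, start, end,
            ifelse(is.na(name), ".", name), fmt_num(score),
            ifelse(strand == "*", ".", strand), sep = "\t")
    }
  } else {
    lines <- paste(chrom, start, end,
                   ifelse(is.na(name), ".", name), fmt_num(score),
                   ifelse(strand == "*", ".", strand),
                   "0", "-1", "-1", "-1", sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Retain peaks whose score exceeds a threshold
#'
#' Applies the strict `score > threshold` retention rule used when selecting
#' called peaks (the conventional cutoff is 5 on the MACS2 score scale).
#'
#' @param peaks `GRanges` with a `score` metadata column (no missing values).
#' @param threshold numeric; peaks with score strictly greater are retained.
#' @return filtered `GRanges`, input order preserved.
#' @export
filter_by_score <- function(peaks, threshold = 5) {
  score <- S4Vectors::mcols(peaks)$score
  if (length(peaks) == 0L) return(peaks)
  if (is.null(score) || anyNA(score)) {
    stop("filter_by_score: every peak must carry a score")
  }
  peaks[score > threshold]
}

#' Merge a peak set into disjoint covered intervals
#'
#' Union of all intervals: output ranges are disjoint, sorted, and cover
#' exactly the same bases as the input.
#'
#' @param peaks `GRanges`.
#' @return reduced `GRanges` (metadata columns dropped).
#' @export
merge_set <- function(peaks) {
  GenomicRanges::reduce(GenomicRanges::granges(peaks), ignore.strand = TRUE)
}
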