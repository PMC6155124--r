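#' Tn5 insertion-offset correction
#'
#' The transposase inserts adapters 9 bp apart, so alignments are adjusted to
#' the insertion centre: both coordinates move +4 bp for `+`-strand records
#' and -5 bp for `-`-strand records. Applied to paired fragments the same
#' rule shifts the `+` (5') end +4 and the `-` (3') end -5.
#'
#' @param x stranded `GRanges` (alignments or fragment ends); strand `*` is an
#'   error because the shift is undefined without it.
#' @param mode `"alignment"` shifts both coordinates of each record by the
#'   strand offset; `"fragment"` moves the fragment start +4 and the end -5
#'   (the per-mate correction applied to an unstranded fragment span).
#' @return shifted `GRanges`.
#' @export
tn5_shift <- function(x, mode = c("alignment", "fragment")) {
  mode <- match.arg(mode)
  str <- as.character(GenomicRanges::strand(x))
  if (mode == "alignment") {
    if (any(str == "*")) stop("tn5_shift: unstranded alignment; shift undefined")
    GenomicRanges::shift(x, ifelse(str == "+", 4L, -5L))
  } else {
    out <- x
    GenomicRanges::start(out) <- GenomicRanges::start(x) + 4L
    GenomicRanges::end(out) <- GenomicRanges::end(x) - 5L
    if (any(GenomicRanges::width(out) < 1L)) {
      stop("tn5_shift: fragment too short for the +4/-5 correction")
    }
    out
  }
}

#' Nucleosome class from fragment size
#'
#' Size bins: < 100 bp nucleosome-free (NFR); 180–247 bp mononucleosome;
#' 315–473 bp dinucleosome; 558–615 bp trinucleosome; anything else
#' (the gaps 100–179, 248–314, 474–557 and > 615 bp) is unclassified and is
#' dropped from nucleosome analyses.
#'
#' @param size integer fragment sizes in bp (>= 1).
#' @return character vector in
#'   `{"NFR", "mono", "di", "tri", "unclassified"}`.
#' @export
classify_fragment <- function(size) {
  if (any(size < 1L)) stop("fragment size must be >= 1")
  out <- rep("unclassified", length(size))
  out[size < 100] <- "NFR"
  out[size >= 180 & size <= 247] <- "mono"
  out[size >= 315 & size <= 473] <- "di"
  out[size >= 558 & size <= 615] <- "tri"
  out
}

#' Replace fragments by their nucleosome BED regions
#'
#' Mononucleosome (and NFR background) fragments become a single region;
#' dinucleosomes two regions each spanning half the fragment; trinucleosomes
#' three regions each spanning a third. Sub-regions tile the fragment exactly:
#' integer division, with the last region absorbing the remainder.
#'
#' @param fragments `GRanges` of (shifted) fragments; classes are derived
#'   from widths with [classify_fragment()]. Unclassified fragments raise an
#'   error — filter them first.
#' @return `GRanges` of replacement regions with a `nuc_class` metadata
#'   column and `fragment` index back into the input.
#' @export
nucleosome_regions <- function(fragments) {
  cls <- classify_fragment(GenomicRanges::width(fragments))
  if (any(cls == "unclassified")) {
    stop("nucleosome_regions: unclassified fragment size(s), e.g. ",
         GenomicRanges::width(fragments)[cls == "unclassified"][1], " bp")
  }
  k <- c(NFR = 1L, mono = 1L, di = 2L, tri = 3L)[cls]
  s <- GenomicRanges::start(fragments)
  e <- GenomicRanges::end(fragments)
  w <- GenomicRanges::width(fragments)
  idx <- rep(seq_along(fragments), k)
  part <- sequence(k)                      # 1..k within each fragment
  base <- (w %/% k)[idx]
  starts <- s[idx] + (part - 1L) * base
  ends <- ifelse(part == k[idx], e[idx], starts + base - 1L)
  out <- GenomicRanges::GRanges(
    rep(GenomicRanges::seqnames(fragments), k),
    IRanges::IRanges(starts, ends)
  )
  S4Vectors::mcols(out)$nuc_class <- cls[idx]
  S4Vectors::mcols(out)$fragment <- idx
  out
}

#' Read fragments from a 3+ column BED file
#'
#' @param path fragment BED (0-based half-open); column 6, if present, gives
#'   the strand of the `+`-mate convention but fragments are typically
#'   unstranded.
#' @return `GRanges`.
#' @export
read_fragments <- function(path) {
  fr <- read_peaks(path, format = "BED", label = basename(path),
                   dedup = FALSE)
  if (length(fr) == 0L) stop("empty fragment file: ", path)
  fr
}

#' Tabulate nucleosome classes of a fragment set
#'
#' @param fragments `GRanges`.
#' @return data.frame with class and count, in the fixed class order.
#' @export
fragment_class_counts <- function(fragments) {
  cls <- factor(classify_fragment(GenomicRanges::width(fragments)),
                levels = c("NFR", "mono", "di", "tri", "unclassified"))
  data.frame(nuc_class = levels(cls), count = as.integer(table(cls)),
             stringsAsFactors = FALSE)
}
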