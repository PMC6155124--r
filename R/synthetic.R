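# Seeded generators that plant known structure: gene classes with planted
# effects, nearest-peak distances drawn per class, fragment-size mixtures
# phased on planted dyads, mark-covered enhancer subsets, and Venn regions
# with planted counts. Every generator is a pure function of (spec, stream).

#' Synthetic-data specification
#'
#' Bundles the parameters of all generators. Two geometries are used: the
#' association generator places one gene per isolated 12-Mb locus block so
#' each gene's nearest differential peak is its own planted one (required to
#' realize nearest-peak distances up to 5 Mb); the fragment / enhancer / Venn
#' generators use a dense two-chromosome 50-Mb genome.
#'
#' @param seed global integer seed; per-generator streams are derived from it
#'   so datasets can be regenerated independently.
#' @param n_genes number of genes (association geometry).
#' @param genes_per_chrom locus blocks per synthetic chromosome.
#' @param block_bp locus-block size in bp.
#' @param frac_up,frac_down planted fractions of up-/down-regulated genes
#'   (remainder unchanged).
#' @param lfc_mean,lfc_sd magnitude distribution of planted log2 fold-changes.
#' @param null_lfc_sd log2FC spread of unchanged genes.
#' @param signal_p_exponents range `c(lo, hi)`: planted p-values are
#'   `10^-U(lo, hi)`.
#' @param up_bins,down_bins distance-bin labels (of
#'   [default_distance_bins()]) from which planted nearest-peak distances of
#'   up-/down-genes are drawn; defaults plant increased accessibility at all
#'   distances to 500 kb and decreased accessibility only within 5 kb.
#' @param peak_width_range accessibility peak width range in bp.
#' @param dense_chroms,dense_chrom_bp dense-geometry genome.
#' @param n_fragments fragment count.
#' @param fragment_weights mixture over NFR/mono/di/tri.
#' @param n_dyads planted nucleosome dyads.
#' @param n_enhancer_peaks peaks fed to the enhancer generator.
#' @param enhancer_fraction planted enhancer fraction.
#' @param venn_counts named planted per-region counts for labels A, B, C.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_genes = 320L,
                       genes_per_chrom = 20L,
                       block_bp = 12e6,
                       frac_up = 0.3, frac_down = 0.3,
                       lfc_mean = 2, lfc_sd = 0.5,
                       null_lfc_sd = 0.25,
                       signal_p_exponents = c(4, 8),
                       up_bins = c("0", "0-5kb", "5-20kb", "20-100kb",
                                   "100-200kb", "200-500kb"),
                       down_bins = c("0-5kb"),
                       peak_width_range = c(200L, 800L),
                       dense_chroms = 2L, dense_chrom_bp = 50e6,
                       n_fragments = 1e5L,
                       fragment_weights = c(NFR = 0.5, mono = 0.3,
                                            di = 0.15, tri = 0.05),
                       n_dyads = 50L,
                       n_enhancer_peaks = 1000L,
                       enhancer_fraction = 0.3,
                       venn_counts = c(A = 1500L, B = 1200L, C = 1000L,
                                       "A&B" = 800L, "A&C" = 600L,
                                       "B&C" = 500L, "A&B&C" = 700L)) {
  if (frac_up + frac_down > 1) stop("class fractions must sum to <= 1")
  if (abs(sum(fragment_weights) - 1) > 1e-9) {
    stop("fragment_weights must sum to 1")
  }
  structure(as.list(environment()), class = "synth_spec")
}

# evaluate expr under a seed derived from (spec$seed, stream id), restoring
# the caller's RNG state afterwards
with_stream <- function(seed, id, expr) {
  sub <- (as.numeric(seed) * 7919 + id * 104729) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(sub))
  expr
}

#' Generate a synthetic gene annotation
#'
#' One gene per locus block, block centres jittered by up to 200 kb, gene
#' lengths uniform on 2–50 kb, strands drawn at random. Blocks guarantee
#' pairwise non-overlap and >= 5 Mb clearance for planted peaks.
#'
#' @param spec a [synth_spec()].
#' @return `GRanges` as from [gene_annotation()].
#' @export
gen_genome <- function(spec) {
  n <- spec$n_genes
  if (n == 0L) {
    return(gene_annotation(character(), character(), character(),
                           integer(), integer())[0])
  }
  with_stream(spec$seed, 1L, {
    chrom_i <- (seq_len(n) - 1L) %/% spec$genes_per_chrom + 1L
    block_i <- (seq_len(n) - 1L) %% spec$genes_per_chrom
    centre <- block_i * spec$block_bp + spec$block_bp / 2
    tss0 <- round(centre + stats::runif(n, -2e5, 2e5))
    len <- round(stats::runif(n, 2e3, 5e4))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    txStart <- ifelse(strand == "+", tss0, tss0 - len + 1)
    txEnd <- txStart + len
    gene_annotation(sprintf("gene%04d", seq_len(n)),
                    sprintf("synchr%02d", chrom_i), strand, txStart, txEnd)
  })
}

#' Generate a differential-expression table with planted gene classes
#'
#' Up genes: positive log2FC with mean `lfc_mean`, p-values `10^-U(lo, hi)`;
#' down genes mirrored; unchanged genes: log2FC ~ N(0, null_lfc_sd), p ~
#' U(0, 1). q-values come from [bh_fdr()].
#'
#' @param spec a [synth_spec()].
#' @param genes gene annotation from [gen_genome()].
#' @return list with `table` ([differential_table()]) and `truth`
#'   (data.frame gene_id, class).
#' @export
gen_differential_table <- function(spec, genes) {
  ids <- S4Vectors::mcols(genes)$gene_id
  n <- length(ids)
  with_stream(spec$seed, 2L, {
    n_up <- round(spec$frac_up * n)
    n_down <- round(spec$frac_down * n)
    cls <- rep("noc", n)
    sig_idx <- sample.int(n, n_up + n_down)
    cls[sig_idx[seq_len(n_up)]] <- "up"
    if (n_down > 0) cls[sig_idx[n_up + seq_len(n_down)]] <- "down"
    lfc <- stats::rnorm(n, 0, spec$null_lfc_sd)
    p <- stats::runif(n)
    sig <- cls != "noc"
    mag <- abs(stats::rnorm(sum(sig), spec$lfc_mean, spec$lfc_sd))
    lfc[sig] <- ifelse(cls[sig] == "up", mag, -mag)
    p[sig] <- 10^-stats::runif(sum(sig), spec$signal_p_exponents[1],
                               spec$signal_p_exponents[2])
    list(table = differential_table(ids, lfc, p),
         truth = data.frame(gene_id = ids, class = cls,
                            stringsAsFactors = FALSE))
  })
}

# draw a planted nearest-peak distance inside a named default bin
draw_distance_in_bin <- function(bin_label) {
  bins <- default_distance_bins()
  row <- bins[bins$label == bin_label, ]
  if (nrow(row) != 1L) stop("unknown bin label: ", bin_label)
  if (row$hi - row$lo <= 1) return(row$lo)
  row$lo + floor(stats::runif(1) * (row$hi - row$lo))
}

#' Generate condition-pair accessibility peaks with a planted distance model
#'
#' Each up-regulated gene receives one *gained* peak (present only in
#' condition B) whose TSS distance is drawn from a bin sampled uniformly from
#' `spec$up_bins`; each down-regulated gene one *lost* peak (condition A
#' only) with distance drawn from `spec$down_bins`; unchanged genes receive
#' one gained and one lost peak with distances spanning all bins, plus every
#' gene a shared peak present in both conditions.
#'
#' @param spec a [synth_spec()].
#' @param genes gene annotation.
#' @param diff result of [gen_differential_table()] (its `truth` fixes the
#'   gene classes).
#' @return list with `A`, `B` (condition peak `GRanges`), `peaks_up`
#'   (B-only), `peaks_down` (A-only), and `truth` (per planted peak:
#'   gene_id, direction, distance, bin).
#' @export
gen_peaks_with_distance_model <- function(spec, genes, diff) {
  ids <- S4Vectors::mcols(genes)$gene_id
  cls <- diff$truth$class[match(ids, diff$truth$gene_id)]
  tss0 <- GenomicRanges::start(tss_positions(genes)) - 1L
  chrom <- as.character(GenomicRanges::seqnames(genes))
  all_bins <- default_distance_bins()$label
  with_stream(spec$seed, 3L, {
    rows <- list()
    place <- function(gene_i, direction, bin_label) {
      d <- draw_distance_in_bin(bin_label)
      w <- round(stats::runif(1, spec$peak_width_range[1],
                              spec$peak_width_range[2]))
      t <- tss0[gene_i]
      if (d == 0) {
        s0 <- t - w %/% 2L
      } else if (stats::runif(1) < 0.5) {
        s0 <- t + d                       # right of TSS: |start - t| = d
      } else {
        s0 <- t - d + 1 - w               # left of TSS: |t - (end-1)| = d
      }
      list(chrom = chrom[gene_i], start = s0, end = s0 + w,
           gene_id = ids[gene_i], direction = direction,
           distance = d, bin = bin_label)
    }
    for (i in seq_along(ids)) {
      if (cls[i] == "up") {
        rows[[length(rows) + 1L]] <-
          place(i, "up", sample(spec$up_bins, 1L))
      } else if (cls[i] == "down") {
        rows[[length(rows) + 1L]] <-
          place(i, "down", sample(spec$down_bins, 1L))
      } else {
        rows[[length(rows) + 1L]] <- place(i, "up", sample(all_bins, 1L))
        rows[[length(rows) + 1L]] <- place(i, "down", sample(all_bins, 1L))
      }
      rows[[length(rows) + 1L]] <- place(i, "shared", sample(all_bins, 1L))
    }
    truth <- do.call(rbind, lapply(rows, as.data.frame,
                                   stringsAsFactors = FALSE))
    gr <- as_peaks(truth$chrom, truth$start, truth$end,
                   score = round(stats::runif(nrow(truth), 6, 100), 2),
                   name = paste(truth$gene_id, truth$direction, sep = ":"),
                   sort = FALSE)
    peaks_up <- sort_peaks(gr[truth$direction == "up"])
    peaks_down <- sort_peaks(gr[truth$direction == "down"])
    shared <- sort_peaks(gr[truth$direction == "shared"])
    list(A = sort_peaks(c(peaks_down, shared)),
         B = sort_peaks(c(peaks_up, shared)),
         peaks_up = peaks_up, peaks_down = peaks_down, truth = truth)
  })
}

#' Generate ATAC fragments from a nucleosome-class mixture
#'
#' Fragment classes are drawn from `spec$fragment_weights`; mono/di/tri
#' fragments are phased around planted dyads (centres jittered N(0, 10 bp));
#' NFR fragments fall uniformly. Sizes are drawn inside each class range
#' *after* the +4/-5 correction, so fragments are emitted 9 bp wider,
#' pre-shift.
#'
#' @param spec a [synth_spec()].
#' @return list with `fragments` (unstranded `GRanges`, pre-shift), `dyads`
#'   (planted dyad positions, `GRanges`), and `truth` (per-fragment class).
#' @export
gen_fragments <- function(spec) {
  size_range <- list(NFR = c(30, 99), mono = c(180, 247),
                     di = c(315, 473), tri = c(558, 615))
  with_stream(spec$seed, 4L, {
    chroms <- sprintf("simdense%d", seq_len(spec$dense_chroms))
    dy_chrom <- sample(chroms, spec$n_dyads, replace = TRUE)
    dy_pos <- round(stats::runif(spec$n_dyads, 1e4, spec$dense_chrom_bp - 1e4))
    n <- spec$n_fragments
    cls <- sample(names(spec$fragment_weights), n, replace = TRUE,
                  prob = spec$fragment_weights)
    post_size <- vapply(cls, function(cl) {
      r <- size_range[[cl]]
      r[1] + floor(stats::runif(1) * (r[2] - r[1] + 1))
    }, 0)
    pre_size <- post_size + 9L
    di <- sample.int(spec$n_dyads, n, replace = TRUE)
    # centre: dyad for mono, +100/+200 for di/tri (second/third wrapped
    # nucleosome), uniform for NFR
    offset <- c(NFR = NA, mono = 0, di = 100, tri = 200)[cls]
    centre <- dy_pos[di] + offset + round(stats::rnorm(n, 0, 10))
    chromv <- dy_chrom[di]
    is_nfr <- cls == "NFR"
    centre[is_nfr] <- round(stats::runif(sum(is_nfr), 1e3,
                                         spec$dense_chrom_bp - 1e3))
    chromv[is_nfr] <- sample(chroms, sum(is_nfr), replace = TRUE)
    start0 <- centre - pre_size %/% 2L
    fr <- as_peaks(chromv, start0, start0 + pre_size, sort = FALSE)
    list(fragments = fr,
         dyads = GenomicRanges::GRanges(dy_chrom,
                                        IRanges::IRanges(dy_pos, dy_pos)),
         truth = data.frame(nuc_class = cls, dyad = ifelse(is_nfr, NA, dy_pos[di]),
                            stringsAsFactors = FALSE))
  })
}

#' Generate accessibility peaks with planted mark-covered enhancers
#'
#' Well-separated peaks (>= 2 kb apart) of which a planted fraction is
#' covered by intervals in both histone-mark sets; a further slice of
#' non-enhancer peaks receives one mark only, as decoys. Construction
#' guarantees the mark overlap, so the returned truth flags are exact.
#'
#' @param spec a [synth_spec()].
#' @param peaks optional peak `GRanges`; generated if `NULL`.
#' @return list with `peaks`, `mark1`, `mark2` (`GRanges`), and logical
#'   `truth` flags.
#' @export
gen_marked_enhancers <- function(spec, peaks = NULL) {
  with_stream(spec$seed, 5L, {
    if (is.null(peaks)) {
      n <- spec$n_enhancer_peaks
      per_chrom <- ceiling(n / spec$dense_chroms)
      slots <- seq(1e4, spec$dense_chrom_bp - 1e4, by = 5e3)
      chrom <- rep(sprintf("simdense%d", seq_len(spec$dense_chroms)),
                   each = per_chrom)[seq_len(n)]
      pos <- unlist(lapply(seq_len(spec$dense_chroms), function(i) {
        sort(sample(slots, min(per_chrom, length(slots)))) +
          round(stats::runif(per_chrom, 0, 1500))
      }))[seq_len(n)]
      w <- round(stats::runif(n, 200, 800))
      peaks <- as_peaks(chrom, pos, pos + w,
                        score = round(stats::runif(n, 6, 100), 2),
                        name = sprintf("peak%05d", seq_len(n)), sort = FALSE)
    }
    n <- length(peaks)
    truth <- rep(FALSE, n)
    enh <- sample.int(n, round(spec$enhancer_fraction * n))
    truth[enh] <- TRUE
    rest <- setdiff(seq_len(n), enh)
    only1 <- rest[seq_len(floor(length(rest) / 4))]
    only2 <- rest[floor(length(rest) / 4) + seq_len(floor(length(rest) / 4))]
    mk <- function(idx, pad) {
      if (length(idx) == 0L) {
        return(GenomicRanges::GRanges())
      }
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(peaks)[idx],
        IRanges::IRanges(pmax(1L, GenomicRanges::start(peaks)[idx] - pad),
                         GenomicRanges::end(peaks)[idx] + pad))
    }
    list(peaks = peaks,
         mark1 = sort_peaks(mk(sort(c(enh, only1)), 100L)),
         mark2 = sort_peaks(mk(sort(c(enh, only2)), 150L)),
         truth = truth)
  })
}

#' Generate stage-structured peak sets with planted Venn region counts
#'
#' For every named region (e.g. `"A&C"`) the planted number of anchor
#' locations is drawn on a >= 2-kb-spaced grid; each member set receives one
#' peak per anchor, overlapping co-members by well over 10 bp. The resulting
#' [venn_partition()] recovers the planted counts exactly.
#'
#' @param spec a [synth_spec()]; `spec$venn_counts` names the regions over
#'   labels A, B, C.
#' @return list with `peak_sets` (named list of `GRanges`) and
#'   `truth` (planted per-region counts).
#' @export
gen_venn_peaksets <- function(spec) {
  counts <- spec$venn_counts
  labels <- sort(unique(unlist(strsplit(names(counts), "&", fixed = TRUE))))
  with_stream(spec$seed, 6L, {
    total <- sum(counts)
    spacing <- 2e3
    capacity <- floor(spec$dense_chroms * (spec$dense_chrom_bp - 2e4) / spacing)
    if (total > capacity) stop("planted Venn counts exceed genome capacity")
    slot <- sample.int(capacity, total)
    per_chrom <- floor((spec$dense_chrom_bp - 2e4) / spacing)
    anchor_chrom <- sprintf("simdense%d", (slot - 1L) %/% per_chrom + 1L)
    anchor_pos <- ((slot - 1L) %% per_chrom) * spacing + 1e4
    region_of <- rep(names(counts), counts)
    sets <- lapply(labels, function(lab) {
      member <- vapply(strsplit(region_of, "&", fixed = TRUE),
                       function(x) lab %in% x, TRUE)
      idx <- which(member)
      if (length(idx) == 0L) {
        return(as_peaks(character(), integer(), integer()))
      }
      jitter <- round(stats::runif(length(idx), -50, 50))
      w <- round(stats::runif(length(idx), 300, 600))
      as_peaks(anchor_chrom[idx], pmax(0, anchor_pos[idx] + jitter),
               pmax(0, anchor_pos[idx] + jitter) + w,
               score = round(stats::runif(length(idx), 6, 100), 2),
               label = lab)
    })
    names(sets) <- labels
    list(peak_sets = sets, truth = counts)
  })
}
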