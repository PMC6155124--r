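# Brute-force oracles and random-instance builders, independent of the
# package's interval machinery: all arithmetic is done on plain vectors of
# 1-based closed coordinates.

random_peakset <- function(n, chroms = c("c1", "c2"), max_pos = 5e4,
                           wmax = 400) {
  start0 <- floor(runif(n, 0, max_pos))
  w <- ceiling(runif(n, 1, wmax))
  as_peaks(sample(chroms, n, replace = TRUE), start0, start0 + w,
           score = runif(n, 0, 100))
}

gr_coords <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# pairwise overlap length matrix between two coordinate frames (1-based)
overlap_matrix <- function(a, b) {
  ov <- outer(a$end, b$end, pmin) - outer(a$start, b$start, pmax) + 1L
  same <- outer(a$chrom, b$chrom, "==")
  ov * same - (!same) * 1e9
}

# Venn partition oracle: igraph components over the all-pairs cross-set
# overlap graph
oracle_venn_subsets <- function(peak_sets, min_bp) {
  co <- lapply(peak_sets, gr_coords)
  all <- do.call(rbind, co)
  set_of <- rep(names(peak_sets), vapply(co, nrow, 0L))
  n <- nrow(all)
  m <- overlap_matrix(all, all) >= min_bp
  m <- m & outer(set_of, set_of, "!=")
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  comp <- igraph::components(g)$membership
  vapply(seq_len(n), function(i) {
    members <- sort(unique(set_of[comp == comp[i]]))
    paste(members, collapse = "&")
  }, "")
}

# exact TSS distance per the nearest-edge rule, plain arithmetic
oracle_tss_distance <- function(p_chrom, p_start, p_end, t_chrom, t_pos) {
  if (p_chrom != t_chrom) return(Inf)
  if (t_pos >= p_start && t_pos <= p_end) return(0)
  min(abs(t_pos - p_start), abs(t_pos - p_end))
}

# per-gene scan over all peaks -> nearest distance and bin label
oracle_bin_assignment <- function(genes, peaks, bins) {
  tss <- tss_positions(genes)
  tc <- gr_coords(tss)
  pc <- gr_coords(peaks)
  vapply(seq_len(nrow(tc)), function(i) {
    d <- vapply(seq_len(nrow(pc)), function(j) {
      oracle_tss_distance(pc$chrom[j], pc$start[j], pc$end[j],
                          tc$chrom[i], tc$start[i])
    }, 0)
    dm <- if (length(d)) min(d) else Inf
    hit <- which(bins$lo <= dm & dm < bins$hi)
    if (length(hit)) bins$label[hit] else NA_character_
  }, "")
}

oracle_enhancer_flags <- function(peaks, mark1, mark2, min_bp) {
  pc <- gr_coords(peaks)
  f <- function(marks) {
    mc <- gr_coords(marks)
    if (nrow(mc) == 0L) return(rep(FALSE, nrow(pc)))
    apply(overlap_matrix(pc, mc) >= min_bp, 1L, any)
  }
  f(mark1) & f(mark2)
}

# footprint oracle: expand each chromosome to a dense vector, loop per bp
oracle_footprint <- function(track, centers, half_width, bin_width) {
  dense <- lapply(track$cov, as.numeric)
  mid <- (GenomicRanges::start(centers) + GenomicRanges::end(centers)) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(centers))
  keep <- mid - half_width >= 1L
  mid <- mid[keep]; chrom <- chrom[keep]
  nb <- 2L * half_width / bin_width
  acc <- matrix(0, nrow = nb, ncol = length(mid))
  for (i in seq_along(mid)) {
    v <- dense[[chrom[i]]]
    for (b in seq_len(nb)) {
      tot <- 0
      for (o in seq_len(bin_width)) {
        pos <- mid[i] - half_width + (b - 1L) * bin_width + o - 1L
        tot <- tot + if (pos >= 1L && pos <= length(v)) v[pos] else 0
      }
      acc[b, i] <- tot / bin_width
    }
  }
  rowMeans(acc)
}

# literal transcription of the BH step-up rule
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(seq_len(n), function(j) {
      if (p[o[j]] >= p[o[i]]) n * p[o[j]] / j else Inf
    }, 0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}
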