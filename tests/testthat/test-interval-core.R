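test_that("read_peaks parses, sorts, validates and round-trips", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t50\t80", "chr2\t0\t10"), bed)
  pk <- read_peaks(bed, "BED")
  expect_length(pk, 3L)
  expect_equal(GenomicRanges::start(pk)[1], 51L)  # chr1:50-80 sorts first
  expect_equal(GenomicRanges::end(pk)[1], 80L)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t10\t110\tp1\t12.0\t.\t3.2\t8.1\t6.0\t50", np)
  pk2 <- read_peaks(np, "narrowPeak")
  expect_equal(S4Vectors::mcols(pk2)$score, 12.0)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), bad)
  expect_error(read_peaks(bad, "BED"), "line 2")
  writeLines("chr1\tten\t20", bad)
  expect_error(read_peaks(bad, "BED"), "line 1")

  # write -> read round-trips coordinates and scores bit-exactly
  set.seed(11)
  pk3 <- random_peakset(50)
  out <- tempfile(fileext = ".bed")
  write_peaks(pk3, out, "BED")
  back <- read_peaks(out, "BED")
  expect_identical(gr_coords(back), gr_coords(pk3))
  expect_identical(S4Vectors::mcols(back)$score, S4Vectors::mcols(pk3)$score)

  dup <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t10\t20"), dup)
  expect_warning(pkd <- read_peaks(dup, "BED"), "duplicate")
  expect_length(pkd, 1L)
})

test_that("score filtering is strictly greater-than", {
  pk <- as_peaks("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                 score = c(4, 5, 5.01, 12))
  expect_length(filter_by_score(pk, 5), 2L)
  expect_length(filter_by_score(pk, -Inf), 4L)
  expect_length(filter_by_score(pk[0], 5), 0L)
  pk_nos <- as_peaks("chr1", 0, 10)
  expect_error(filter_by_score(pk_nos, 5), "score")
})

test_that("interval_overlaps applies the minimum-overlap rule symmetrically", {
  a <- as_peaks("chr1", 100, 200)
  b <- as_peaks("chr1", 185, 300)
  c_ <- as_peaks("chr1", 195, 300)
  d <- as_peaks("chr2", 100, 200)
  expect_true(interval_overlaps(a, b, 10))   # 15-bp overlap
  expect_false(interval_overlaps(a, c_, 10)) # 5-bp overlap
  expect_false(interval_overlaps(a, d, 1))
  # symmetry and agreement with the standard intersection test at min_bp = 1
  set.seed(21)
  x <- random_peakset(80)
  y <- random_peakset(80)
  expect_identical(interval_overlaps(x, y, 10), interval_overlaps(y, x, 10))
  cx <- gr_coords(x); cy <- gr_coords(y)
  expect_identical(
    interval_overlaps(x, y, 1),
    cx$chrom == cy$chrom & cx$start <= cy$end & cy$start <= cx$end
  )
})

test_that("merge_set unions intervals and conserves covered bases", {
  m <- merge_set(as_peaks("chr1", c(0, 5), c(10, 20)))
  expect_length(m, 1L)
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 20L)

  disjoint <- as_peaks("chr1", c(0, 100), c(10, 150))
  expect_equal(gr_coords(merge_set(disjoint)), gr_coords(disjoint))

  set.seed(31)
  pk <- random_peakset(100, chroms = "c1", max_pos = 5000, wmax = 100)
  merged <- merge_set(pk)
  # per-base boolean-array oracle for covered bp
  covered <- rep(FALSE, 6000)
  co <- gr_coords(pk)
  for (i in seq_len(nrow(co))) covered[co$start[i]:co$end[i]] <- TRUE
  expect_equal(sum(GenomicRanges::width(merged)), sum(covered))
  expect_true(all(GenomicRanges::width(IRanges::gaps(GenomicRanges::ranges(merged))) > 0))
})

test_that("venn_partition handles canonical overlap cases and conserves counts", {
  A <- as_peaks("chr1", 0, 100)
  B <- as_peaks("chr1", 50, 150)
  vp <- venn_partition(list(A = A, B = B), 10)
  expect_equal(unname(vp$counts["A&B", ]), c(1L, 1L))
  expect_equal(sum(vp$counts[c("A", "B"), ]), 0L)

  B2 <- as_peaks("chr1", 95, 150)  # 5-bp overlap fails the 10-bp rule
  vp2 <- venn_partition(list(A = A, B = B2), 10)
  expect_equal(unname(vp2$counts["A", "A"]), 1L)
  expect_equal(unname(vp2$counts["B", "B"]), 1L)
  expect_equal(unname(vp2$counts["A&B", ]), c(0L, 0L))

  expect_error(venn_partition(list(A = A, A = B), 10), "named|duplicate")

  set.seed(41)
  sets <- list(A = random_peakset(30), B = random_peakset(30),
               C = random_peakset(30))
  vp3 <- venn_partition(sets, 10)
  expect_equal(unname(colSums(vp3$counts)), unname(vp3$totals))
  expect_identical(vp3$membership$subset, oracle_venn_subsets(sets, 10))
})

test_that("chained cross-set overlap joins peaks into one region", {
  # A-peak overlaps B-peak, B-peak overlaps C-peak: one A&B&C component
  sets <- list(A = as_peaks("chr1", 0, 100),
               B = as_peaks("chr1", 80, 300),
               C = as_peaks("chr1", 280, 400))
  vp <- venn_partition(sets, 10)
  expect_equal(unname(vp$counts["A&B&C", ]), c(1L, 1L, 1L))
})
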