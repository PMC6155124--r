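test_that("Tn5 shift moves +strand records +4 and -strand records -5", {
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150), strand = "+")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150), strand = "-")
  sp <- tn5_shift(plus)
  sm <- tn5_shift(minus)
  # 0-based: (+,100,150) -> (104,154); (-,100,150) -> (95,145)
  expect_equal(GenomicRanges::start(sp) - 1L, 104L)
  expect_equal(GenomicRanges::end(sp), 154L)
  expect_equal(GenomicRanges::start(sm) - 1L, 95L)
  expect_equal(GenomicRanges::end(sm), 145L)
  # shift then unshift is the identity
  unshift <- GenomicRanges::shift(sp, -4L)
  expect_identical(GenomicRanges::ranges(unshift), GenomicRanges::ranges(plus))
  star <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50), strand = "*")
  expect_error(tn5_shift(star), "unstranded")
  # fragment mode: start +4, end -5, width shrinks by 9
  fr <- as_peaks("chr1", 1000, 1200)
  sf <- tn5_shift(fr, mode = "fragment")
  expect_equal(GenomicRanges::width(sf), 200L - 9L)
})

test_that("fragment sizes classify into the published nucleosome bins", {
  expect_equal(classify_fragment(90), "NFR")
  expect_equal(classify_fragment(c(200, 400, 600)), c("mono", "di", "tri"))
  expect_equal(classify_fragment(150), "unclassified")
  # boundary values of every stated range
  expect_equal(classify_fragment(c(99, 100, 180, 247, 248, 314, 315, 473,
                                   557, 558, 615, 616)),
               c("NFR", "unclassified", "mono", "mono", "unclassified",
                 "unclassified", "di", "di", "unclassified", "tri", "tri",
                 "unclassified"))
  # every positive size maps to exactly one class
  cls <- classify_fragment(1:1000)
  expect_true(all(cls %in% c("NFR", "mono", "di", "tri", "unclassified")))
  expect_error(classify_fragment(0), ">= 1")
})

test_that("nucleosome regions tile fragments exactly", {
  di <- as_peaks("chr1", 1000, 1400)
  r <- nucleosome_regions(di)
  expect_equal(GenomicRanges::start(r) - 1L, c(1000L, 1200L))
  expect_equal(GenomicRanges::end(r), c(1200L, 1400L))

  tri <- as_peaks("chr1", 0, 600)
  r3 <- nucleosome_regions(tri)
  expect_equal(GenomicRanges::start(r3) - 1L, c(0L, 200L, 400L))
  expect_equal(GenomicRanges::end(r3), c(200L, 400L, 600L))

  # odd di length: halves of 200 and 201 bp, concatenation exact
  odd <- as_peaks("chr1", 1000, 1401)
  ro <- nucleosome_regions(odd)
  expect_equal(GenomicRanges::width(ro), c(200L, 201L))
  expect_equal(GenomicRanges::start(ro)[2], GenomicRanges::end(ro)[1] + 1L)

  expect_error(nucleosome_regions(as_peaks("chr1", 0, 150)), "unclassified")
})

test_that("coverage and cut-site tracks respect their normalizations", {
  one <- as_peaks("chr1", 0, 10)
  tr <- coverage_track(one, "raw")
  expect_equal(track_values(tr, "chr1", 1, 10), rep(1, 10))
  two <- as_peaks("chr1", c(0, 5), c(10, 15))
  tr2 <- coverage_track(two, "raw")
  expect_equal(track_values(tr2, "chr1", 6, 10), rep(2, 5))
  expect_error(coverage_track(one[0]), "empty")

  # conservation: sum(depth * width) = total aligned bp, scaled by the factor
  set.seed(107)
  pk <- random_peakset(1000, chroms = "c1", max_pos = 1e5)
  raw <- coverage_track(pk, "raw")
  norm <- coverage_track(pk, "per_billion_aligned_bp")
  total_bp <- sum(as.numeric(GenomicRanges::width(pk)))
  expect_equal(sum(as.numeric(raw$cov[["c1"]])), total_bp)
  expect_equal(sum(as.numeric(norm$cov[["c1"]])), 1e9, tolerance = 1e-9)

  aplus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150), strand = "+")
  aminus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150), strand = "-")
  expect_equal(track_values(cutsite_track(aplus, "raw"), "chr1", 101, 101), 1)
  expect_equal(track_values(cutsite_track(aminus, "raw"), "chr1", 150, 150), 1)
  both <- c(aplus, aminus)
  pm <- cutsite_track(both, "per_million_alignments")
  expect_equal(sum(vapply(pm$cov, function(r) sum(as.numeric(r)), 0)), 1e6)
  expect_error(cutsite_track(as_peaks("chr1", 0, 50)), "unstranded")
})

test_that("footprint profiles average windows by bin and stay linear", {
  const <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(3, 5000)))
  centers <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(2000, 3000), width = 1))
  fp <- footprint_profile(const, centers, half_width = 500, bin_width = 10)
  expect_equal(fp$values, rep(3, 100))

  # unit impulse at one center: only the central bin responds
  imp <- numeric(5000); imp[2000] <- 1
  imp_tr <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(imp)))
  fp2 <- footprint_profile(imp_tr, centers[1], half_width = 100, bin_width = 10)
  expect_equal(sum(fp2$values > 0), 1L)
  expect_equal(which(fp2$values > 0), 11L)  # bin covering positions 2000-2009

  # windows off the chromosome start are excluded and counted
  near_edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(50, 2000), width = 1))
  fp3 <- footprint_profile(const, near_edge, half_width = 500, bin_width = 10)
  expect_equal(fp3$n_excluded, 1L)
  expect_equal(fp3$n_regions, 1L)

  # linearity: profile(a*A + b*B) = a*profile(A) + b*profile(B)
  set.seed(118)
  va <- runif(5000); vb <- runif(5000)
  tA <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(va)))
  tB <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(vb)))
  tAB <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(2 * va + 5 * vb)))
  f <- function(t) footprint_profile(t, centers, 200, 10)$values
  expect_equal(f(tAB), 2 * f(tA) + 5 * f(tB), tolerance = 1e-9)
})

test_that("track correlations flag zero variance and monotone transforms", {
  set.seed(129)
  v <- runif(2000)
  ta <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(v)))
  tb <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(-v)))
  texp <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(exp(3 * v))))
  region <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 2000))
  self <- correlate_tracks(ta, ta, region)
  expect_equal(self$pearson, 1)
  expect_equal(self$spearman, 1)
  expect_equal(correlate_tracks(ta, tb, region)$pearson, -1)
  mono <- correlate_tracks(ta, texp, region)
  expect_equal(mono$spearman, 1)
  expect_lt(mono$pearson, 1)
  flat <- signal_track(IRanges::RleList(c1 = S4Vectors::Rle(1, 2000)))
  expect_warning(cz <- correlate_tracks(ta, flat, region), "zero-variance")
  expect_true(is.nan(cz$pearson))
})

test_that("bedGraph write/read preserves the track", {
  set.seed(140)
  pk <- random_peakset(200, chroms = c("c1", "c2"), max_pos = 2e4)
  tr <- coverage_track(pk, "per_billion_aligned_bp")
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path)
  for (ch in names(tr$cov)) {
    n <- length(tr$cov[[ch]])
    expect_equal(track_values(back, ch, 1, n), track_values(tr, ch, 1, n))
  }
})
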