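test_that("generators are deterministic per seed and isolated per stream", {
  sp <- synth_spec(seed = 5)
  expect_identical(gen_genome(sp), gen_genome(sp))
  d1 <- gen_differential_table(sp, gen_genome(sp))
  d2 <- gen_differential_table(sp, gen_genome(sp))
  expect_identical(d1, d2)
  f1 <- gen_fragments(synth_spec(seed = 5, n_fragments = 500))
  f2 <- gen_fragments(synth_spec(seed = 5, n_fragments = 500))
  expect_identical(f1, f2)
  expect_false(identical(gen_genome(synth_spec(seed = 6)), gen_genome(sp)))
  # generating one dataset does not perturb another stream
  g_before <- gen_genome(sp)
  invisible(gen_fragments(synth_spec(seed = 5, n_fragments = 100)))
  expect_identical(gen_genome(sp), g_before)
})

test_that("synthetic genes are non-overlapping with valid structure", {
  sp <- synth_spec(seed = 15)
  genes <- gen_genome(sp)
  expect_length(genes, sp$n_genes)
  co <- gr_coords(genes)
  # exhaustive pairwise non-overlap check
  ov <- overlap_matrix(co, co) >= 1
  diag(ov) <- FALSE
  expect_false(any(ov))
  expect_length(gen_genome(synth_spec(seed = 1, n_genes = 0)), 0L)
})

test_that("planted differential classes are recovered at q < 0.05", {
  recovered <- vapply(1:20, function(s) {
    sp <- synth_spec(seed = s)
    genes <- gen_genome(sp)
    d <- gen_differential_table(sp, genes)
    cl <- classify_genes(d$table, 0.05)
    planted_up <- d$truth$gene_id[d$truth$class == "up"]
    length(intersect(cl$up, planted_up)) / length(planted_up)
  }, 0)
  expect_true(all(recovered >= 0.95))
})

test_that("planted nearest-peak distances drive the expected bins", {
  sp <- synth_spec(seed = 25)
  genes <- gen_genome(sp)
  d <- gen_differential_table(sp, genes)
  pk <- gen_peaks_with_distance_model(sp, genes, d)
  binned <- bin_genes_by_nearest_peak(genes, pk$peaks_up)
  asg <- binned$assignment
  tr_up <- pk$truth[pk$truth$direction == "up", ]
  m <- merge(asg, tr_up, by = "gene_id")
  # the planted peak is the nearest one: distances and bins agree exactly
  expect_equal(m$distance.x, m$distance.y)
  expect_identical(m$bin.x, m$bin.y)
  # up-genes' planted distances all fall within 500 kb
  up_ids <- d$truth$gene_id[d$truth$class == "up"]
  expect_true(all(m$distance.x[m$gene_id %in% up_ids] < 5e5))
  # down-genes' planted lost-peak distances all fall within 5 kb
  binned_dn <- bin_genes_by_nearest_peak(genes, pk$peaks_down)
  dn_ids <- d$truth$gene_id[d$truth$class == "down"]
  ddn <- binned_dn$assignment
  expect_true(all(ddn$distance[ddn$gene_id %in% dn_ids] < 5e3))
  # condition sets: A = lost + shared, B = gained + shared
  expect_length(pk$A, length(pk$peaks_down) + sum(pk$truth$direction == "shared"))
  expect_length(pk$B, length(pk$peaks_up) + sum(pk$truth$direction == "shared"))
})

test_that("fragment mixture weights and planted dyads are recoverable", {
  sp <- synth_spec(seed = 35, n_fragments = 10000L)
  fr <- gen_fragments(sp)
  shifted <- tn5_shift(fr$fragments, mode = "fragment")
  cc <- fragment_class_counts(shifted)
  w <- cc$count[match(names(sp$fragment_weights), cc$nuc_class)] /
    length(shifted)
  expect_true(all(abs(w - sp$fragment_weights) < 0.02))
  expect_equal(cc$count[cc$nuc_class == "unclassified"], 0L)

  # all-mono spec: nucleosome-region occupancy peaks at the planted dyads
  spm <- synth_spec(seed = 35, n_fragments = 4000L, n_dyads = 5L,
                    fragment_weights = c(NFR = 0, mono = 1, di = 0, tri = 0))
  frm <- gen_fragments(spm)
  nuc <- nucleosome_regions(tn5_shift(frm$fragments, mode = "fragment"))
  cov <- coverage_track(nuc, "raw")
  dy <- gr_coords(frm$dyads)
  for (ch in unique(dy$chrom)) {
    v <- cov$cov[[ch]]
    rv <- S4Vectors::runValue(v); rl <- S4Vectors::runLength(v)
    ends <- cumsum(rl); starts <- ends - rl + 1L
    sel <- rv == max(rv)
    # occupancy has a flat top; take the midpoint of the maximal plateau
    mode_pos <- round(mean(c(min(starts[sel]), max(ends[sel]))))
    expect_lte(min(abs(mode_pos - dy$start[dy$chrom == ch])), 20)
  }
})

test_that("planted enhancer marks are recovered exactly, with boundaries", {
  sp <- synth_spec(seed = 45, n_enhancer_peaks = 1000L)
  me <- gen_marked_enhancers(sp)
  expect_identical(classify_enhancers(me$peaks, me$mark1, me$mark2), me$truth)
  expect_equal(sum(me$truth), round(0.3 * 1000))

  none <- gen_marked_enhancers(synth_spec(seed = 45, enhancer_fraction = 0))
  expect_equal(sum(classify_enhancers(none$peaks, none$mark1, none$mark2)), 0L)

  # marks offset to overlap by exactly min_bp - 1 are not called
  pk <- as_peaks("chr1", 1000, 1100)
  mark <- as_peaks("chr1", 1091, 1200)  # 9 shared bases
  expect_false(classify_enhancers(pk, mark, mark, min_bp = 10))
})

test_that("planted Venn counts are recovered exactly", {
  sp <- synth_spec(seed = 55)
  vs <- gen_venn_peaksets(sp)
  vp <- venn_partition(vs$peak_sets, 10)
  # per-region total peaks = planted count x number of member sets
  members <- vapply(strsplit(rownames(vp$counts), "&"), length, 0L)
  per_region <- stats::setNames(rowSums(vp$counts) / members,
                                rownames(vp$counts))
  expect_equal(per_region[names(vs$truth)], vs$truth / 1)
  expect_equal(unname(colSums(vp$counts)), unname(vp$totals))
})
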