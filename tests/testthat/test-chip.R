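test_that("signed TSS offsets are strand-aware and mirror under strand flips", {
  fx <- chip_fixture()
  off <- signed_tss_offsets(fx$peaks, fx$tx)
  expect_equal(off$offset, fx$expected_offsets)
  expect_equal(off$gene_id, c("gA", "gA", "gB", "gB", "gC", "gC"))
  # mirroring every gene's strand (TSS held fixed) negates all signed offsets
  off_flip <- signed_tss_offsets(fx$peaks, flip_tx_keep_tss(fx$tx))
  expect_equal(off_flip$offset, -fx$expected_offsets)
  # peak on an unannotated chromosome is skipped with a warning
  stray <- GenomicRanges::GRanges("chrX", IRanges::IRanges(10, 20), name = "x",
                                  score = 1, summit_offset = 5)
  both <- suppressWarnings(c(fx$peaks, stray))
  expect_warning(out <- signed_tss_offsets(both, fx$tx), "no TSS")
  expect_equal(nrow(out), 6)
})

test_that("TSS density profile tallies and smooths as computed by hand", {
  fx <- chip_fixture()
  prof <- tss_density_profile(fx$peaks, fx$tx, window = 30000, bin = 10000,
                              smooth_bins = 1)
  # offsets: -10000, +1000, -5000, +200, -25000, -1000
  # left-closed bins [-30,-20) [-20,-10) [-10,0) [0,10) [10,20) [20,30]:
  # -25000 | (none) | -10000,-5000,-1000 | +200,+1000 | none | none
  expect_equal(prof$raw, c(1, 0, 3, 2, 0, 0))
  expect_equal(sum(prof$raw), 6)
  expect_equal(prof$smoothed, prof$raw)  # identity kernel
  prof3 <- tss_density_profile(fx$peaks, fx$tx, window = 30000, bin = 10000,
                               smooth_bins = 3)
  # centered moving average, edges truncated
  expect_equal(prof3$smoothed,
               c(mean(c(1, 0)), mean(c(1, 0, 3)), mean(c(0, 3, 2)),
                 mean(c(3, 2, 0)), mean(c(2, 0, 0)), mean(c(0, 0))))
  # a peak whose summit sits on a TSS lands in the 0-offset bin
  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99951, 100050),
                                   name = "s", summit_offset = 49)
  p1 <- tss_density_profile(single, fx$tx, window = 1000, bin = 100,
                            smooth_bins = 1)
  expect_equal(sum(p1$raw), 1)
  expect_equal(p1$bin_center[p1$raw == 1], 50)  # bin [0, 100)
})

test_that("region classification matches hand labels and fractions sum to 1", {
  fx <- chip_fixture()
  # summit offsets to own gene: -10000 (upstream far), +1000 (gene body),
  # -5000, +200 (promoter), -25000 (distal), -1000 (promoter)
  cls <- classify_peak_regions(fx$peaks, fx$tx, promoter_window = c(2000, 500))
  expect_equal(cls$labels,
               c("distal", "gene_body", "distal", "promoter", "distal",
                 "promoter"))
  expect_equal(sum(cls$fractions$fraction), 1)
  expect_length(cls$labels, 6)
  # 100 bp upstream of a TSS is promoter under (2000, 500)
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99850, 99949),
                                 name = "n", summit_offset = 50)
  expect_equal(classify_peak_regions(near, fx$tx)$labels, "promoter")
})

test_that("candidate-gene filter reproduces the hand enumeration", {
  fx <- chip_fixture()
  res <- select_candidate_genes(fx$peaks, fx$has_site, fx$tx,
                                window = c(-20000, 500))
  expect_equal(res$candidates$gene_id, c("gA", "gB"))
  expect_equal(res$candidates$n_supporting_peaks, c(1L, 2L))
  expect_equal(res$candidates$best_offset, c(-10000, 200))
  expect_equal(res$support$peak[res$support$gene_id == "gB"], c("p3", "p4"))
  # motif-bearing peak at -25000 with none closer: gene excluded
  expect_false("gC" %in% res$candidates$gene_id)

  # monotone in the window: enlarging it never removes a candidate
  wider <- select_candidate_genes(fx$peaks, fx$has_site, fx$tx,
                                  window = c(-30000, 2000))
  expect_true(all(res$candidates$gene_id %in% wider$candidates$gene_id))
  expect_true("gC" %in% wider$candidates$gene_id)

  # strand mirroring (TSS fixed) flips the accepted set: gB's +200 peak
  # becomes -200 (still inside), its -5000 peak becomes +5000 (outside)
  flipped <- select_candidate_genes(fx$peaks, fx$has_site,
                                    flip_tx_keep_tss(fx$tx),
                                    window = c(-20000, 500))
  gB <- flipped$support[flipped$support$gene_id == "gB", ]
  expect_equal(gB$peak, "p4")
  expect_equal(gB$offset, -200)
})

test_that("peak files round-trip through narrowPeak without off-by-one", {
  fx <- chip_fixture()
  path <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(fx$peaks, path)
  back <- read_peaks(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(fx$peaks))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(fx$peaks))
  expect_equal(back$summit_offset, fx$peaks$summit_offset)
  expect_equal(back$name, fx$peaks$name)
  # GTF round-trip preserves 1-based gene coordinates and strand
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(fx$tx, gtf)
  tx2 <- read_transcripts(gtf)
  expect_equal(GenomicRanges::start(tx2), GenomicRanges::start(fx$tx))
  expect_equal(GenomicRanges::end(tx2), GenomicRanges::end(fx$tx))
  expect_equal(as.character(GenomicRanges::strand(tx2)),
               as.character(GenomicRanges::strand(fx$tx)))
  expect_equal(tx2$gene_id, fx$tx$gene_id)
  # identical signed offsets after the disk round-trip
  expect_equal(signed_tss_offsets(back, tx2)$offset, fx$expected_offsets)
})

test_that("peak depth comparison normalizes and matches hand-computed means", {
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(101, 301, 501), width = 100),
    name = c("k1", "k2", "k3"))
  cov <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(101, 151, 301, 701),
                             end = c(150, 200, 400, 800)),
    score = c(10, 20, 4, 8))
  # k1: 50bp@10 + 50bp@20 -> mean 15 ; k2: 100bp@4 -> 4 ; k3: uncovered
  cmp <- compare_peak_depth(cov, cov, peaks, pseudocount = 1e-9)
  expect_equal(cmp$n_excluded, 1)
  expect_equal(cmp$depths$peak, c("k1", "k2"))
  raw_means <- c(15, 4)
  total <- sum(c(50 * 10, 50 * 20, 100 * 4, 100 * 8)) / 1e6
  expect_equal(cmp$depths$control, raw_means / total)
  # identical tracks -> all log-ratios zero
  expect_equal(cmp$depths$log2_ratio, c(0, 0))
  expect_equal(cmp$median_log2_ratio, 0)
  # treated uniformly halved at equal library sizes -> median log-ratio -1
  half <- cov; half$score <- cov$score / 2
  cmp2 <- compare_peak_depth(cov, half, peaks, pseudocount = 1e-9,
                             control_total = 1e6, treated_total = 1e6)
  expect_equal(cmp2$median_log2_ratio, -1, tolerance = 1e-6)
})
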