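test_that("screen simulator is reproducible and conserves dimensions", {
  cfg <- screen_sim_config(n_cells_per_class = 40, n_genes = 120, n_tfs = 10,
                           planted_interactors = 20, background_edges = 300,
                           seed = 11)
  a <- simulate_screen_inputs(cfg)
  b <- simulate_screen_inputs(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(as.data.frame(a$network), as.data.frame(b$network))
  expect_identical(a$ground_truth, b$ground_truth)

  expect_equal(dim(a$matrix), c(40 * 3, 120))
  # edges = planted + background - dropped collisions
  expect_equal(nrow(a$network) + a$ground_truth$n_edges_dropped, 20 + 300)
  # planted TF's neighborhood is exactly the planted interactors
  expect_setequal(get_interactors(a$network, a$ground_truth$planted_tf),
                  a$ground_truth$planted_interactors)
})

test_that("planted effect shifts non-basal means by 2^log2fc", {
  cfg <- screen_sim_config(planted_log2fc = 2, planted_interactors = 50,
                           n_cells_per_class = 200, n_genes = 300, seed = 21)
  sim <- simulate_screen_inputs(cfg)
  v <- as.matrix(sim$matrix$values)[, sim$ground_truth$planted_interactors]
  basal <- sim$matrix$cell_class == "basal"
  m_b <- mean(v[basal, ])
  m_nb <- mean(v[!basal, ])
  # empirical ratio of group means within 3 standard errors of 4
  n_nb <- sum(!basal) * ncol(v)
  n_b <- sum(basal) * ncol(v)
  se <- sqrt(var(as.vector(v[!basal, ])) / n_nb +
               16 * var(as.vector(v[basal, ])) / n_b) / m_b
  expect_lt(abs(m_nb / m_b - 4), 3 * se)
  expect_gt(m_nb / m_b, 3)
})

test_that("null config leaves planted genes indistinguishable", {
  cfg <- screen_sim_config(planted_log2fc = 0, n_cells_per_class = 150,
                           n_genes = 200, seed = 31)
  sim <- simulate_screen_inputs(cfg)
  fc <- vapply(sim$ground_truth$planted_interactors,
               function(g) gene_fold_change(sim$matrix, g), numeric(1))
  expect_lt(abs(mean(fc) - 1), 0.1)
})

test_that("screen config validation names the offending field", {
  expect_error(screen_sim_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(screen_sim_config(n_genes = 0), "n_genes")
  expect_error(screen_sim_config(n_genes = 50, planted_interactors = 50),
               "planted_interactors")
  sim_cfg <- screen_sim_config(planted_tf = "not_a_tf", seed = 1)
  expect_error(simulate_screen_inputs(sim_cfg), "planted_tf")
})

test_that("genome simulator plants consensus sites as configured", {
  cfg1 <- genome_sim_config(n_peaks = 60, n_genes = 40, chrom_length = 400000,
                            planted_site_fraction = 1, seed = 5)
  g1 <- simulate_genome_inputs(cfg1)
  seqs <- vapply(seq_along(g1$peaks), function(i) {
    ch <- as.character(GenomicRanges::seqnames(g1$peaks))[i]
    as.character(Biostrings::subseq(
      g1$genome[[ch]], GenomicRanges::start(g1$peaks)[i],
      GenomicRanges::end(g1$peaks)[i]))
  }, character(1))
  expect_true(all(grepl(cfg1$motif_consensus, seqs, fixed = TRUE)))
  expect_true(all(g1$ground_truth$planted_site))

  # zero planting: consensus occurrences match the uniform-background
  # expectation within Poisson error
  cfg0 <- genome_sim_config(n_peaks = 200, n_genes = 40, chrom_length = 400000,
                            planted_site_fraction = 0, peak_width = 300,
                            seed = 6)
  g0 <- simulate_genome_inputs(cfg0)
  seqs0 <- vapply(seq_along(g0$peaks), function(i) {
    ch <- as.character(GenomicRanges::seqnames(g0$peaks))[i]
    as.character(Biostrings::subseq(
      g0$genome[[ch]], GenomicRanges::start(g0$peaks)[i],
      GenomicRanges::end(g0$peaks)[i]))
  }, character(1))
  L <- nchar(cfg0$motif_consensus)
  n_pos <- sum(nchar(seqs0) - L + 1)
  observed <- sum(vapply(seqs0, function(s) {
    length(gregexpr(cfg0$motif_consensus, s, fixed = TRUE)[[1]]) -
      (gregexpr(cfg0$motif_consensus, s, fixed = TRUE)[[1]][1] == -1)
  }, numeric(1)))
  expected <- n_pos * 0.25^L
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 3)
})

test_that("genome simulator is byte-reproducible and validates the motif", {
  cfg <- genome_sim_config(n_peaks = 30, n_genes = 20, chrom_length = 300000,
                           seed = 9)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(simulate_genome_inputs(cfg)$genome, f1)
  Biostrings::writeXStringSet(simulate_genome_inputs(cfg)$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(genome_sim_config(motif_consensus = strrep("ACGT", 30),
                                 peak_width = 100), "longer")
})

test_that("trace simulator matches its construction", {
  # pure sinusoid: peak displacement equals the amplitude
  cfg <- trace_sim_config(fs = 240, duration = 5, true_frequency = 8,
                          amplitude = 3, noise_sd = 0, drift_slope = 0,
                          seed = 2)
  tr <- simulate_trace(cfg)
  expect_equal(length(tr$displacement), 1200)
  # the sampling grid need not hit the crest exactly: 30 samples per period
  # bounds the miss by amplitude * (1 - cos(pi/30))
  expect_lte(max(abs(tr$displacement)), 3)
  expect_gte(max(abs(tr$displacement)), 3 * cos(pi / 30))
  # 8 Hz at 240 fps: exactly 8 * duration full periods => zero crossings at
  # every period boundary
  expect_equal(tr$displacement[1 + 30 * (0:39)], rep(0, 40), tolerance = 1e-9)

  # moment check: variance ~ amplitude^2/2 + noise_sd^2
  cfg2 <- trace_sim_config(fs = 240, duration = 20, true_frequency = 8,
                           amplitude = 3, noise_sd = 1.5, seed = 3)
  v <- var(simulate_trace(cfg2)$displacement)
  expect_lt(abs(v - (9 / 2 + 2.25)) / (9 / 2 + 2.25), 0.1)

  expect_error(trace_sim_config(true_frequency = 120, fs = 240), "alias")
  expect_error(trace_sim_config(duration = 0.1, fs = 240), "64")
  expect_identical(simulate_trace(cfg)$displacement,
                   simulate_trace(cfg)$displacement)
})
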