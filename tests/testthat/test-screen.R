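test_that("TF universe selection intersects annotation and matrix", {
  mat <- toy_matrix()
  ann <- gene_set_annotation(data.frame(
    gene_id = c("gA", "gB", "gX", "gC"),
    term = c("T1", "T1", "T1", "T2")))
  expect_equal(suppressMessages(select_tf_universe(ann, mat, "T1")),
               c("gA", "gB"))          # gX not in matrix, gC wrong term
  expect_error(suppressMessages(select_tf_universe(ann, mat, "T9")),
               "no gene annotated")
})

test_that("top-expressed ranking uses the maximum per-class mean", {
  # gA: class means basal 1, club 5, ciliated 8 -> max 8
  # gB: flat 2 across classes -> max 2; a high mean in ONE class wins
  mat <- toy_matrix()
  expect_equal(rank_top_expressed(mat, c("gA", "gB"), k = 1), "gA")
  expect_equal(rank_top_expressed(mat, c("gA", "gB"), k = 10), c("gA", "gB"))

  # brute-force oracle on a random 8-gene matrix
  m <- random_matrix(12, 8, seed = 42)
  classes <- unique(m$cell_class)
  score <- vapply(m$gene_ids, function(g) {
    max(vapply(classes, function(cl) {
      mean(as.matrix(m$values)[m$cell_class == cl, g])
    }, numeric(1)))
  }, numeric(1))
  expected <- m$gene_ids[order(-score, m$gene_ids)][1:4]
  expect_equal(rank_top_expressed(m, m$gene_ids, k = 4), expected)
})

test_that("fold changes match hand arithmetic and pseudocount limits", {
  mat <- toy_matrix()
  eps <- 0.01
  # gA: basal mean (0+1+2)/3 = 1, non-basal (4+6+8)/3 = 6
  expect_equal(gene_fold_change(mat, "gA"), (6 + eps) / (1 + eps))
  # gB: identical means -> exactly 1
  expect_equal(gene_fold_change(mat, "gB"), 1)
  # positive fractions: gC positive in 2/3 basal, 1/3 non-basal cells
  expect_equal(gene_fold_change(mat, "gC", mode = "positive_fraction"),
               (1 / 3 + eps) / (2 / 3 + eps))
  # all-zero gene -> eps/eps = 1
  vals <- cbind(as.matrix(mat$values), gZ = 0)
  mat0 <- labeled_matrix(vals, mat$cell_class, "basal")
  expect_equal(gene_fold_change(mat0, "gZ"), 1)
  # ratio of positive fractions 50% vs 25% -> 2 as eps -> 0
  expect_equal(gene_fold_change(mat, "gD", mode = "positive_fraction",
                                pseudocount = 1e-12), 1, tolerance = 1e-9)
  expect_error(gene_fold_change(mat, "nope"), "not in matrix")
})

test_that("combined and aggregated scores equal their naive oracles", {
  mat <- toy_matrix()
  expect_equal(combined_score(mat, c("gA", "gB")),
               naive_combined(mat, c("gA", "gB")))
  expect_equal(aggregated_score(mat, c("gA", "gC")),
               naive_aggregated(mat, c("gA", "gC")))
  expect_equal(aggregated_score(mat, c("gA", "gC"), aggregation = "sum"),
               naive_aggregated(mat, c("gA", "gC"), aggregation = "sum"))
  # fold changes 2 and 4 average to 3
  v <- rbind(c(1, 1), c(1, 1), c(2, 4), c(2, 4))
  dimnames(v) <- list(paste0("c", 1:4), c("g1", "g2"))
  m2 <- labeled_matrix(v, c("b", "b", "o", "o"), "b")
  expect_equal(combined_score(m2, c("g1", "g2"), pseudocount = 1e-12), 3,
               tolerance = 1e-9)
  expect_error(combined_score(mat, character(0)), "empty")
  expect_error(aggregated_score(mat, character(0)), "empty")
})

test_that("interactor capping keeps highest confidences with lexicographic ties", {
  edges <- data.frame(
    gene_a = "tf",
    gene_b = sprintf("g%02d", 1:30),
    confidence = c(rep(0.9, 5), rep(0.5, 20), rep(0.2, 5)))
  net <- interaction_network(edges)
  got <- get_interactors(net, "tf", cap = 10)
  # brute force: sort by (-confidence, gene id), take 10
  ord <- order(-edges$confidence, edges$gene_b)
  expect_equal(got, edges$gene_b[ord][1:10])
  expect_equal(length(get_interactors(net, "tf", cap = 250)), 30)
  expect_equal(get_interactors(net, "tf", min_confidence = 0.6),
               sprintf("g%02d", 1:5))
  expect_warning(out <- get_interactors(net, "absent"), "absent from network")
  expect_length(out, 0)
})

test_that("permutation p-values behave per the add-one estimator", {
  mat <- toy_matrix()
  # observed equals every null score -> p_greater = p_less = 1
  r <- permutation_pvalue(mat, observed_score = 5, n_interactors = 2,
                          score_fn = function(g) 5, n_perm = 50, seed = 1)
  expect_equal(r$p_greater, 1)
  expect_equal(r$p_less, 1)
  # determinism
  a <- permutation_pvalue(mat, 1.2, 2, n_perm = 200, seed = 7)
  b <- permutation_pvalue(mat, 1.2, 2, n_perm = 200, seed = 7)
  expect_identical(a$p, b$p)
  expect_identical(a$null, b$null)
  expect_error(permutation_pvalue(mat, 1, 10, universe = c("gA", "gB")),
               "universe")
})

test_that("Monte-Carlo p converges to the exhaustive enumeration", {
  m <- random_matrix(10, 8, seed = 99)
  universe <- m$gene_ids
  obs_set <- c("g001", "g003")
  obs <- combined_score(m, obs_set)
  exact <- exact_perm_p(m, obs, 2, universe,
                        function(g) combined_score(m, g), "greater")
  mc <- permutation_pvalue(m, obs, 2, universe = universe, n_perm = 4000,
                           seed = 3, alternative = "greater")
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p_greater - exact), 3 * se + 2 / 4001)
})

test_that("scores are invariant to cell and gene permutations", {
  m <- random_matrix(15, 10, seed = 5)
  set.seed(8)
  pc <- sample(nrow(m$values))
  pg <- sample(ncol(m$values))
  m2 <- labeled_matrix(as.matrix(m$values)[pc, pg], m$cell_class[pc], "basal")
  ints <- c("g002", "g005", "g009")
  expect_equal(combined_score(m, ints), combined_score(m2, ints))
  expect_equal(aggregated_score(m, ints), aggregated_score(m2, ints))
})

test_that("planted combined score is monotone in the planted effect size", {
  scores <- vapply(c(0, 0.5, 1, 1.5, 2), function(lfc) {
    sim <- simulate_screen_inputs(screen_sim_config(
      n_cells_per_class = 60, n_genes = 150, planted_interactors = 25,
      planted_log2fc = lfc, background_edges = 400, seed = 77))
    combined_score(sim$matrix, sim$ground_truth$planted_interactors)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("run_screen recovers a planted TF and degrades gracefully", {
  sim <- simulate_screen_inputs(screen_sim_config(
    n_cells_per_class = 100, n_genes = 250, n_tfs = 12,
    planted_interactors = 30, planted_log2fc = 2, background_edges = 600,
    seed = 13))
  res <- suppressMessages(run_screen(
    sim$matrix, sim$annotation, sim$network, n_perm = 499, seed = 2,
    alternative = "greater"))
  expect_s3_class(res, "tf_screen_result")
  expect_equal(res$tf_id[1], sim$ground_truth$planted_tf)
  expect_equal(res$p_combined[1], 1 / 500)
  expect_true(all(res$q_combined >= res$p_combined, na.rm = TRUE))
  expect_true(all(res$p_combined > 0 & res$p_combined <= 1, na.rm = TRUE))

  # empty network: all TFs reported untestable, no p-values
  empty_net <- interaction_network(data.frame(
    gene_a = "x1", gene_b = "x2", confidence = 0.5))
  res0 <- suppressMessages(suppressWarnings(run_screen(
    sim$matrix, sim$annotation, empty_net, n_perm = 9, seed = 1)))
  expect_true(all(res0$n_interactors == 0))
  expect_true(all(is.na(res0$p_combined)))

  # determinism of the whole screen
  res2 <- suppressMessages(run_screen(
    sim$matrix, sim$annotation, sim$network, n_perm = 499, seed = 2,
    alternative = "greater"))
  expect_identical(as.data.frame(res), as.data.frame(res2))
})
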