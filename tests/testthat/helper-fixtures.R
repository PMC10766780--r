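# Shared fixtures and independent oracles. Oracles are written naively
# (explicit loops, no shared code with the package internals) so they can
# vouch for the vectorized implementations.

# Small deterministic labeled matrix: counts laid out by hand.
toy_matrix <- function() {
  vals <- rbind(
    c(0, 2, 4, 1),   # basal
    c(1, 2, 0, 1),   # basal
    c(2, 2, 2, 1),   # basal
    c(4, 2, 0, 3),   # club
    c(6, 2, 8, 3),   # club
    c(8, 2, 0, 3)    # ciliated
  )
  dimnames(vals) <- list(paste0("c", 1:6), c("gA", "gB", "gC", "gD"))
  labeled_matrix(vals, c("basal", "basal", "basal", "club", "club", "ciliated"),
                 "basal")
}

# Random small matrix for property tests.
random_matrix <- function(n_cells, n_genes, seed) {
  set.seed(seed)
  vals <- matrix(rpois(n_cells * n_genes, lambda = 2), n_cells, n_genes)
  # guarantee at least 2 classes with >= 1 cell each
  cls <- c("basal", "other", sample(c("basal", "other", "third"),
                                    n_cells - 2, replace = TRUE))
  dimnames(vals) <- list(sprintf("c%03d", 1:n_cells),
                         sprintf("g%03d", 1:n_genes))
  labeled_matrix(vals, cls, "basal")
}

# Naive per-gene fold change: explicit loops over cells.
naive_fold_change <- function(mat, gene, mode, eps = 0.01) {
  v <- as.matrix(mat$values)[, gene]
  b <- mat$cell_class == mat$basal_label
  if (mode == "positive_fraction") v <- as.numeric(v > 0)
  nb_vals <- v[!b]
  b_vals <- v[b]
  (sum(nb_vals) / length(nb_vals) + eps) / (sum(b_vals) / length(b_vals) + eps)
}

naive_combined <- function(mat, interactors, eps = 0.01) {
  s <- 0
  for (g in interactors) s <- s + naive_fold_change(mat, g, "mean", eps)
  s / length(interactors)
}

naive_aggregated <- function(mat, interactors, eps = 0.01, aggregation = "mean") {
  s <- 0
  for (g in interactors) s <- s + naive_fold_change(mat, g, "positive_fraction", eps)
  if (aggregation == "mean") s / length(interactors) else s
}

# Exhaustive permutation p-value over all size-k subsets of the universe.
exact_perm_p <- function(mat, observed, k, universe, score_fn,
                         alternative = "greater") {
  sets <- utils::combn(universe, k, simplify = FALSE)
  null <- vapply(sets, score_fn, numeric(1))
  pg <- mean(null >= observed)
  pl <- mean(null <= observed)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Hand-built ChIP fixture: 3 genes, 6 peaks at printed offsets.
# gA chr1 +, TSS 100000; gB chr1 -, TSS 200000; gC chr2 +, TSS 50000.
chip_fixture <- function() {
  tx <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(100000, 190001, 50000),
                     end = c(110000, 200000, 60000)),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gB", "gC")
  )
  # summits and intended signed offsets (strand-aware, negative = upstream):
  #  p1 -> gA  -10000 (summit  90000) site
  #  p2 -> gA   +1000 (summit 101000) site   outside window (+1000 > +500)
  #  p3 -> gB   -5000 (summit 205000) site   (gB on -, upstream = larger coord)
  #  p4 -> gB    +200 (summit 199800) site
  #  p5 -> gC  -25000 (summit  25000) site   outside window (< -20000)
  #  p6 -> gC   -1000 (summit  49000) no site
  summit <- c(90000, 101000, 205000, 199800, 25000, 49000)
  chrom <- c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2")
  peaks <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = summit - 50, end = summit + 49),
    name = paste0("p", 1:6), score = 100, summit_offset = 50
  )
  list(tx = tx, peaks = peaks,
       has_site = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
       expected_candidates = c("gA", "gB"),
       expected_offsets = c(-10000, 1000, -5000, 200, -25000, -1000))
}

# Mirror every gene's strand while holding its TSS position fixed (width-1
# gene bodies at the TSS), so signed offsets must negate exactly.
flip_tx_keep_tss <- function(tx) {
  strand <- as.character(GenomicRanges::strand(tx))
  tss <- ifelse(strand == "+", GenomicRanges::start(tx),
                GenomicRanges::end(tx))
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(tx), IRanges::IRanges(tss, tss),
    strand = ifelse(strand == "+", "-", "+"), gene_id = tx$gene_id)
}

# Brute-force motif threshold: enumerate all 4^L words under the background
# with real-valued (undiscretized) log-odds, aggregate by distinct score, and
# take the smallest achievable score whose exact tail is <= p.
brute_force_threshold <- function(m, p, background = m$background) {
  L <- m$length
  words <- expand.grid(rep(list(1:4), L))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    w <- as.integer(words[i, ])
    s <- 0; pr <- 1
    for (j in 1:L) {
      s <- s + m$lodds[w[j], j]
      pr <- pr * background[w[j]]
    }
    scores[i] <- s; probs[i] <- pr
  }
  key <- round(scores, 9)                 # merge float-identical scores
  agg <- tapply(probs, key, sum)
  ord <- order(as.numeric(names(agg)))    # numeric, not lexical, order
  uniq <- as.numeric(names(agg))[ord]
  pr_u <- as.numeric(agg)[ord]
  tail_p <- rev(cumsum(rev(pr_u)))
  ok <- which(tail_p <= p)
  if (length(ok) == 0) stop("p unattainable by brute force")
  list(threshold = uniq[ok[1]], tail = tail_p[ok[1]],
       scores = uniq, tail_p = tail_p)
}

# Naive periodogram argmax (independent of estimate_cbf internals).
naive_dominant_freq <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  freqs <- (0:(n - 1)) * fs / n
  mag <- Mod(stats::fft(x))
  keep <- freqs >= band[1] & freqs <= band[2]
  freqs[keep][which.max(mag[keep])]
}
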