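#' Configuration for the screen-input simulator
#'
#' Defines the study conditions for a labeled single-cell count matrix with a
#' planted differentially expressed interactome: negative-binomial counts
#' with Bernoulli dropout, three airway cell classes (basal reference plus
#' two non-basal classes), one planted TF whose network neighbors carry a
#' multiplicative expression shift in every non-basal cell.
#'
#' @param n_cells_per_class cells per class label (default 200).
#' @param n_genes number of genes (default 500).
#' @param class_labels class labels; the first is the basal reference
#'   (default `c("basal", "secretory", "ciliated")`).
#' @param n_tfs number of genes annotated with the TF term (default 30).
#' @param planted_tf identifier of the planted TF; default the first TF gene.
#' @param planted_interactors number of planted interactors (default 50).
#' @param planted_log2fc log2 fold change applied to planted interactors in
#'   non-basal cells (default 2).
#' @param mean_expression baseline mean count scale; per-gene means are drawn
#'   from an exponential with this mean (floor 0.05) so expression ranking is
#'   non-degenerate (default 2).
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion;
#'   default 0.5).
#' @param dropout_rate probability a count is zeroed (default 0.3).
#' @param background_edges random network edges besides the planted ones
#'   (default 2000).
#' @param term annotation term given to TF genes (default `"GO:0043565"`).
#' @param seed integer seed.
#' @return a validated `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_cells_per_class = 200, n_genes = 500,
                              class_labels = c("basal", "secretory", "ciliated"),
                              n_tfs = 30, planted_tf = NULL,
                              planted_interactors = 50, planted_log2fc = 2,
                              mean_expression = 2, dispersion = 0.5,
                              dropout_rate = 0.3, background_edges = 2000,
                              term = "GO:0043565", seed = 1) {
  cfg <- list(
    n_cells_per_class = check_count(n_cells_per_class, "n_cells_per_class"),
    n_genes = check_count(n_genes, "n_genes"),
    class_labels = as.character(class_labels),
    n_tfs = check_count(n_tfs, "n_tfs"),
    planted_tf = planted_tf,
    planted_interactors = check_count(planted_interactors, "planted_interactors"),
    planted_log2fc = check_number(planted_log2fc, "planted_log2fc"),
    mean_expression = check_number(mean_expression, "mean_expression", min = 1e-6),
    dispersion = check_number(dispersion, "dispersion", min = 1e-9),
    dropout_rate = check_number(dropout_rate, "dropout_rate", 0, 1),
    background_edges = check_count(background_edges, "background_edges", min = 0),
    term = check_string(term, "term"),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(cfg$class_labels) < 2 || anyDuplicated(cfg$class_labels)) {
    stop("'class_labels' needs >= 2 distinct labels (first = basal)", call. = FALSE)
  }
  if (cfg$n_tfs >= cfg$n_genes) {
    stop("'n_tfs' must be smaller than 'n_genes'", call. = FALSE)
  }
  if (cfg$planted_interactors > cfg$n_genes - 1) {
    stop("'planted_interactors' must be <= n_genes - 1", call. = FALSE)
  }
  structure(cfg, class = "screen_sim_config")
}

#' Simulate all inputs of the TF screen
#'
#' Generates a labeled expression matrix (negative-binomial counts with
#' dropout; planted interactors have their mean multiplied by
#' `2^planted_log2fc` in every non-basal cell), a TF annotation table, and an
#' interaction network in which the planted TF is connected to exactly its
#' planted interactors while background edges connect random other genes
#' (duplicate collisions are dropped and counted). Fully reproducible from
#' the config seed.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with `matrix` ([labeled_matrix()]), `annotation`
#'   ([gene_set_annotation()]), `network` ([interaction_network()]) and
#'   `ground_truth` (planted TF, planted interactor ids, TF gene ids, config
#'   echo, number of dropped edge collisions).
#' @export
simulate_screen_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    tf_genes <- sort(sample(genes, cfg$n_tfs))
    planted_tf <- if (is.null(cfg$planted_tf)) tf_genes[1] else cfg$planted_tf
    if (!planted_tf %in% tf_genes) {
      stop("'planted_tf' must be among the TF-annotated genes", call. = FALSE)
    }
    planted <- sort(sample(setdiff(genes, planted_tf), cfg$planted_interactors))

    n_cells <- cfg$n_cells_per_class * length(cfg$class_labels)
    cell_class <- rep(cfg$class_labels, each = cfg$n_cells_per_class)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    basal_label <- cfg$class_labels[1]

    gene_mean <- pmax(stats::rexp(cfg$n_genes, rate = 1 / cfg$mean_expression),
                      0.05)
    names(gene_mean) <- genes
    mu <- matrix(gene_mean, nrow = n_cells, ncol = cfg$n_genes, byrow = TRUE)
    nonbasal <- cell_class != basal_label
    mu[nonbasal, genes %in% planted] <-
      mu[nonbasal, genes %in% planted] * 2^cfg$planted_log2fc
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$dispersion),
      nrow = n_cells
    )
    if (cfg$dropout_rate > 0) {
      counts <- counts * matrix(
        rbinom(length(counts), 1L, 1 - cfg$dropout_rate), nrow = n_cells
      )
    }
    dimnames(counts) <- list(cell_ids, genes)
    mat <- labeled_matrix(counts, cell_class, basal_label)

    ann <- gene_set_annotation(
      data.frame(gene_id = tf_genes, term = cfg$term, stringsAsFactors = FALSE)
    )

    other <- setdiff(genes, planted_tf)   # background edges avoid the planted TF
    bg_a <- sample(other, cfg$background_edges, replace = TRUE)
    bg_b <- sample(other, cfg$background_edges, replace = TRUE)
    edges <- data.frame(
      gene_a = c(rep(planted_tf, cfg$planted_interactors), bg_a),
      gene_b = c(planted, bg_b),
      confidence = c(runif(cfg$planted_interactors, 0.9, 0.999),
                     runif(cfg$background_edges, 0.4, 0.999)),
      stringsAsFactors = FALSE
    )
    net <- interaction_network(edges)

    list(
      matrix = mat, annotation = ann, network = net,
      ground_truth = list(
        planted_tf = planted_tf, planted_interactors = planted,
        tf_genes = tf_genes, class_labels = cfg$class_labels,
        planted_log2fc = cfg$planted_log2fc,
        n_edges_dropped = attr(net, "n_dropped"), seed = cfg$seed
      )
    )
  })
}

#' Write simulated screen inputs to a directory
#'
#' Matrix as MTX + genes/cells TSV (optionally dense TSV), annotation and
#' network as TSV, ground truth as JSON.
#'
#' @param sim output of [simulate_screen_inputs()].
#' @param dir output directory.
#' @param dense also write the dense matrix TSV.
#' @return `dir`, invisibly.
#' @export
write_screen_inputs <- function(sim, dir, dense = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$matrix, dir, dense = dense)
  write_tsv_file(as.data.frame(sim$annotation), file.path(dir, "annotation.tsv"))
  write_network(sim$network, file.path(dir, "network.tsv"))
  write_json_file(sim$ground_truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Configuration for the genome/ChIP simulator
#'
#' @param n_chromosomes number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 2e6).
#' @param n_genes genes placed across the genome (default 150).
#' @param n_peaks ChIP peaks (default 500).
#' @param motif_consensus DNA consensus planted at peak summits (default
#'   `"TGATGCAA"`, an ATF4-like CRE half-site arrangement used for testing).
#' @param planted_site_fraction fraction of peaks receiving an exact
#'   consensus at the summit (default 0.3).
#' @param tss_offset_distribution signed peak-to-TSS offsets: a list with
#'   `type = "normal"` (`mean`, `sd`) or `type = "uniform"` (`min`, `max`);
#'   negative = upstream (default normal, mean -3000, sd 8000).
#' @param peak_width peak width in bp (default 200).
#' @param gc genome GC fraction (default 0.5).
#' @param seed integer seed.
#' @return a validated `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_chromosomes = 2, chrom_length = 2e6,
                              n_genes = 150, n_peaks = 500,
                              motif_consensus = "TGATGCAA",
                              planted_site_fraction = 0.3,
                              tss_offset_distribution =
                                list(type = "normal", mean = -3000, sd = 8000),
                              peak_width = 200, gc = 0.5, seed = 1) {
  cfg <- list(
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chrom_length = check_count(chrom_length, "chrom_length"),
    n_genes = check_count(n_genes, "n_genes"),
    n_peaks = check_count(n_peaks, "n_peaks"),
    motif_consensus = toupper(check_string(motif_consensus, "motif_consensus")),
    planted_site_fraction =
      check_number(planted_site_fraction, "planted_site_fraction", 0, 1),
    tss_offset_distribution = tss_offset_distribution,
    peak_width = check_count(peak_width, "peak_width", min = 10),
    gc = check_number(gc, "gc", 0, 1),
    seed = check_count(seed, "seed", min = 0)
  )
  if (!grepl("^[ACGT]+$", cfg$motif_consensus)) {
    stop("'motif_consensus' must be an A/C/G/T string", call. = FALSE)
  }
  if (nchar(cfg$motif_consensus) > cfg$peak_width) {
    stop("'motif_consensus' is longer than 'peak_width'", call. = FALSE)
  }
  if (cfg$chrom_length < 100000) {
    stop("'chrom_length' must exceed the gene span (>= 1e5)", call. = FALSE)
  }
  d <- cfg$tss_offset_distribution
  if (!is.list(d) || is.null(d$type) ||
      !d$type %in% c("normal", "uniform")) {
    stop("'tss_offset_distribution' must be list(type = 'normal'|'uniform', ...)",
         call. = FALSE)
  }
  structure(cfg, class = "genome_sim_config")
}

sample_offsets <- function(d, n) {
  switch(d$type,
    normal = round(rnorm(n, d$mean, d$sd)),
    uniform = round(runif(n, d$min, d$max))
  )
}

#' Simulate genome, transcript annotation, and ChIP peaks
#'
#' Builds i.i.d. background chromosomes at the configured GC fraction, places
#' genes (random TSS, strand, and 5-20 kb body), draws each peak's summit at
#' a signed, strand-aware offset from a random gene's TSS, and writes the
#' exact motif consensus into the genome at the summit of a configured
#' fraction of peaks. Ground truth records each peak's source gene, realized
#' offset, and whether a site was planted.
#'
#' @param cfg a [genome_sim_config()].
#' @return list with `genome` (`Biostrings::DNAStringSet`), `transcripts`
#'   (`GRanges` with `gene_id`), `peaks` (`GRanges` with `name`,
#'   `summit_offset`), and `ground_truth` (data.frame).
#' @export
simulate_genome_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  motif_len <- nchar(cfg$motif_consensus)
  with_seed(cfg$seed, {
    probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
               G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    seqs <- lapply(chroms, function(ch) {
      Biostrings::DNAString(paste(
        sample(names(probs), cfg$chrom_length, replace = TRUE, prob = probs),
        collapse = ""))
    })
    names(seqs) <- chroms

    margin <- 30000L
    gene_len <- round(runif(cfg$n_genes, 5000, 20000))
    gene_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
    gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    tss <- round(runif(cfg$n_genes, margin, cfg$chrom_length - margin))
    gstart <- ifelse(gene_strand == "+", tss, tss - gene_len + 1)
    gend <- ifelse(gene_strand == "+", tss + gene_len - 1, tss)
    gene_id <- sprintf("gene%03d", seq_len(cfg$n_genes))
    tx <- GenomicRanges::GRanges(
      gene_chrom, IRanges::IRanges(gstart, gend), strand = gene_strand,
      gene_id = gene_id
    )

    half <- cfg$peak_width %/% 2L
    src <- sample.int(cfg$n_genes, cfg$n_peaks, replace = TRUE)
    off <- sample_offsets(cfg$tss_offset_distribution, cfg$n_peaks)
    summit <- ifelse(gene_strand[src] == "+", tss[src] + off, tss[src] - off)
    lo <- half + motif_len + 1L
    hi <- cfg$chrom_length - half - motif_len - 1L
    summit <- pmin(pmax(summit, lo), hi)
    # realized offset after boundary clamping, strand-aware
    off <- ifelse(gene_strand[src] == "+", summit - tss[src], tss[src] - summit)
    pstart <- summit - half
    pend <- pstart + cfg$peak_width - 1L
    peak_id <- sprintf("peak%04d", seq_len(cfg$n_peaks))

    n_planted <- round(cfg$planted_site_fraction * cfg$n_peaks)
    planted <- rep(FALSE, cfg$n_peaks)
    if (n_planted > 0) planted[sample.int(cfg$n_peaks, n_planted)] <- TRUE
    for (i in which(planted)) {
      ch <- gene_chrom[src[i]]
      Biostrings::subseq(seqs[[ch]], summit[i], summit[i] + motif_len - 1L) <-
        Biostrings::DNAString(cfg$motif_consensus)
    }
    genome <- Biostrings::DNAStringSet(seqs)

    peaks <- GenomicRanges::GRanges(
      gene_chrom[src], IRanges::IRanges(pstart, pend), strand = "*",
      name = peak_id, score = round(runif(cfg$n_peaks, 10, 1000)),
      summit_offset = summit - pstart
    )
    list(
      genome = genome, transcripts = tx, peaks = peaks,
      ground_truth = data.frame(
        peak = peak_id, gene_id = gene_id[src], offset = off,
        planted_site = planted, stringsAsFactors = FALSE
      )
    )
  })
}

#' Write simulated genome inputs
#'
#' Genome as FASTA, transcripts as GTF (gene features), peaks as narrowPeak,
#' ground truth as JSON-lines-free TSV plus JSON summary.
#'
#' @param sim output of [simulate_genome_inputs()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_genome_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$transcripts, file.path(dir, "transcripts.gtf"))
  write_narrowpeak(sim$peaks, file.path(dir, "peaks.narrowPeak"))
  write_tsv_file(sim$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Configuration for the bead-trace simulator
#'
#' @param fs sampling rate in frames per second (default 240, the recording
#'   rate of the CBF assay this emulates).
#' @param duration trace length in seconds (default 10).
#' @param true_frequency oscillation frequency in Hz; must be below the
#'   Nyquist frequency `fs/2` (default 8).
#' @param amplitude oscillation amplitude in pixels (default 3).
#' @param noise_sd additive Gaussian noise SD in pixels (default 1).
#' @param drift_slope linear drift in pixels per second (default 0).
#' @param bead_id trace identifier (default "bead1").
#' @param seed integer seed.
#' @return a validated `trace_sim_config` list.
#' @export
trace_sim_config <- function(fs = 240, duration = 10, true_frequency = 8,
                             amplitude = 3, noise_sd = 1, drift_slope = 0,
                             bead_id = "bead1", seed = 1) {
  cfg <- list(
    fs = check_number(fs, "fs", min = 1e-9),
    duration = check_number(duration, "duration", min = 1e-9),
    true_frequency = check_number(true_frequency, "true_frequency", min = 1e-9),
    amplitude = check_number(amplitude, "amplitude", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    drift_slope = check_number(drift_slope, "drift_slope"),
    bead_id = check_string(bead_id, "bead_id"),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$true_frequency >= cfg$fs / 2) {
    stop("'true_frequency' at or above the Nyquist frequency fs/2 would alias",
         call. = FALSE)
  }
  if (round(cfg$duration * cfg$fs) < 64) {
    stop("'duration' x 'fs' must give at least 64 samples", call. = FALSE)
  }
  structure(cfg, class = "trace_sim_config")
}

#' Simulate a bead-displacement trace
#'
#' `amplitude * sin(2 pi f t) + drift_slope * t + N(0, noise_sd^2)` sampled at
#' `fs` for `duration` seconds.
#'
#' @param cfg a [trace_sim_config()].
#' @return a [bead_trace()].
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    x <- cfg$amplitude * sin(2 * pi * cfg$true_frequency * t) +
      cfg$drift_slope * t +
      if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
    bead_trace(x, cfg$fs, cfg$bead_id)
  })
}
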