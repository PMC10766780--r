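# ChIP post-peak-calling computations: TSS profiles, region classification,
# motif site calling in peaks, the candidate-gene filter, and read-depth
# comparison. Peaks and transcripts are GRanges; on disk, peaks are
# BED6/narrowPeak (0-based half-open) and transcripts GTF (1-based closed);
# rtracklayer handles both conversions.

#' Read peaks from BED6 or narrowPeak
#'
#' narrowPeak files (10 columns) yield a `summit_offset` column from the
#' summit field when it is not -1; BED6 peaks get no summit and are anchored
#' at their midpoint downstream.
#'
#' @param path peak file; format chosen by extension (`.narrowPeak` or
#'   anything else = BED).
#' @return `GRanges` with `name`, `score`, and optionally `summit_offset`.
#' @export
read_peaks <- function(path) {
  if (grepl("\\.narrowPeak$", path, ignore.case = TRUE)) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    if (all(gr$peak >= 0)) gr$summit_offset <- gr$peak
    gr$peak <- NULL
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  if (is.null(gr$name) || anyNA(gr$name)) {
    gr$name <- sprintf("peak%04d", seq_along(gr))
  }
  GenomicRanges::strand(gr) <- "*"
  gr
}

#' Write peaks as narrowPeak
#' @param peaks `GRanges` with optional `name`, `score`, `summit_offset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,      # to 0-based half-open
    end = GenomicRanges::end(peaks),
    name = if (is.null(peaks$name)) sprintf("peak%04d", seq_along(peaks)) else peaks$name,
    score = if (is.null(peaks$score)) 0L else as.integer(peaks$score),
    strand = ".",
    signalValue = 0, pValue = -1, qValue = -1,
    peak = if (is.null(peaks$summit_offset)) -1L else as.integer(peaks$summit_offset)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GTF
#'
#' Keeps `gene` features (or all features if none are typed `gene`) and
#' requires a `gene_id` attribute.
#'
#' @param path GTF file.
#' @return `GRanges` with `gene_id`.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes", call. = FALSE)
  gr
}

#' Write gene annotation as GTF
#' @param tx `GRanges` with `gene_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path) {
  lines <- sprintf(
    "%s\tairscreen\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(GenomicRanges::seqnames(tx)),
    GenomicRanges::start(tx), GenomicRanges::end(tx),
    as.character(GenomicRanges::strand(tx)), tx$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

# TSS of each gene: start on +, end on - (1-based).
tss_table <- function(tx) {
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(!strand %in% c("+", "-"))) {
    stop("every gene needs a defined strand", call. = FALSE)
  }
  data.frame(
    gene_id = tx$gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = strand,
    tss = ifelse(strand == "+", GenomicRanges::start(tx),
                 GenomicRanges::end(tx)),
    stringsAsFactors = FALSE
  )
}

# Anchor position of each peak: summit when present, else midpoint.
peak_anchor <- function(peaks) {
  start <- GenomicRanges::start(peaks)
  if (!is.null(peaks$summit_offset) && !anyNA(peaks$summit_offset)) {
    start + as.integer(peaks$summit_offset)
  } else {
    as.integer(floor((start + GenomicRanges::end(peaks)) / 2))
  }
}

#' Signed offsets from peak anchors to the nearest TSS
#'
#' Each peak is anchored at its summit (midpoint if no summit) and assigned
#' the nearest TSS on its chromosome; the offset is signed in the gene's
#' transcriptional orientation (negative = upstream of the TSS). Distance
#' ties go to the lexicographically smaller gene id. Peaks on chromosomes
#' with no annotated TSS are skipped with a warning.
#'
#' @param peaks `GRanges` peaks.
#' @param tx `GRanges` gene annotation with `gene_id`.
#' @return data.frame (`peak`, `gene_id`, `offset`), one row per assignable
#'   peak, in peak order.
#' @export
signed_tss_offsets <- function(peaks, tx) {
  tt <- tss_table(tx)
  anchors <- peak_anchor(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  names <- if (is.null(peaks$name)) as.character(seq_along(peaks)) else peaks$name
  out <- vector("list", length(peaks))
  skipped <- 0L
  for (i in seq_along(peaks)) {
    cand <- tt[tt$chrom == chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) { skipped <- skipped + 1L; next }
    d <- abs(anchors[i] - cand$tss)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(cand$gene_id[best])[1]]
    g <- cand[best, ]
    off <- if (g$strand == "+") anchors[i] - g$tss else g$tss - anchors[i]
    out[[i]] <- data.frame(peak = names[i], gene_id = g$gene_id,
                           offset = off, stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(sprintf("%d peak(s) skipped: no TSS on their chromosome", skipped),
            call. = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Peak density profile around transcription start sites
#'
#' Histograms signed summit-to-nearest-TSS offsets over `[-window, window]`
#' and adds a centered moving average (`smooth_bins` bins, odd).
#'
#' @param peaks `GRanges` peaks.
#' @param tx `GRanges` gene annotation with `gene_id`.
#' @param window half-width of the profile in bp (default 20000).
#' @param bin bin width in bp (default 500).
#' @param smooth_bins odd moving-average width in bins (default 5;
#'   1 = no smoothing).
#' @return data.frame (`bin_center`, `raw`, `smoothed`); the raw counts sum
#'   to the number of peaks whose offset falls within the window.
#' @export
tss_density_profile <- function(peaks, tx, window = 20000, bin = 500,
                                smooth_bins = 5) {
  window <- check_count(window, "window")
  bin <- check_count(bin, "bin")
  smooth_bins <- check_count(smooth_bins, "smooth_bins")
  if (smooth_bins %% 2 == 0) stop("'smooth_bins' must be odd", call. = FALSE)
  off <- signed_tss_offsets(peaks, tx)$offset
  breaks <- seq(-window, window, by = bin)
  if (breaks[length(breaks)] < window) breaks <- c(breaks, window)
  off <- off[off >= -window & off <= window]
  h <- graphics::hist(off, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  raw <- h$counts
  half <- (smooth_bins - 1) / 2
  smoothed <- vapply(seq_along(raw), function(i) {
    lo <- max(1, i - half); hi <- min(length(raw), i + half)
    mean(raw[lo:hi])
  }, numeric(1))
  data.frame(bin_center = h$mids, raw = raw, smoothed = smoothed)
}

#' Classify peaks into genomic regions
#'
#' Labels each peak (anchored at summit/midpoint) by precedence promoter >
#' gene body > distal. A peak is "promoter" when its anchor lies within
#' `promoter_window` of any TSS in the gene's orientation (upstream,
#' downstream), "gene_body" when inside any gene interval, else "distal".
#'
#' @param peaks `GRanges` peaks.
#' @param tx `GRanges` gene annotation with `gene_id`.
#' @param promoter_window c(upstream, downstream) bp, both positive
#'   (default c(2000, 500)).
#' @return list with `labels` (character per peak) and `fractions`
#'   (data.frame region/fraction summing to 1).
#' @export
classify_peak_regions <- function(peaks, tx, promoter_window = c(2000, 500)) {
  if (length(promoter_window) != 2 || any(promoter_window <= 0)) {
    stop("'promoter_window' must be two positive numbers", call. = FALSE)
  }
  tt <- tss_table(tx)
  anchors <- peak_anchor(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  prom_start <- ifelse(tt$strand == "+", tt$tss - promoter_window[1],
                       tt$tss - promoter_window[2])
  prom_end <- ifelse(tt$strand == "+", tt$tss + promoter_window[2],
                     tt$tss + promoter_window[1])
  gstart <- GenomicRanges::start(tx)
  gend <- GenomicRanges::end(tx)
  gchrom <- as.character(GenomicRanges::seqnames(tx))
  labels <- vapply(seq_along(peaks), function(i) {
    on_chrom <- tt$chrom == chrom[i]
    if (any(on_chrom & anchors[i] >= prom_start & anchors[i] <= prom_end)) {
      return("promoter")
    }
    if (any(gchrom == chrom[i] & anchors[i] >= gstart & anchors[i] <= gend)) {
      return("gene_body")
    }
    "distal"
  }, character(1))
  regions <- c("promoter", "gene_body", "distal")
  frac <- vapply(regions, function(r) mean(labels == r), numeric(1))
  list(labels = labels,
       fractions = data.frame(region = regions, fraction = unname(frac)))
}

# Extract peak sequences from a DNAStringSet genome; errors name the peak.
peak_sequences <- function(genome, peaks) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  names <- if (is.null(peaks$name)) as.character(seq_along(peaks)) else peaks$name
  vapply(seq_along(peaks), function(i) {
    if (!chrom[i] %in% names(genome)) {
      stop(sprintf("peak '%s': chromosome '%s' absent from genome",
                   names[i], chrom[i]), call. = FALSE)
    }
    s <- GenomicRanges::start(peaks)[i]
    e <- GenomicRanges::end(peaks)[i]
    if (s < 1 || e > length(genome[[chrom[i]]])) {
      stop(sprintf("peak '%s' outside chromosome bounds", names[i]),
           call. = FALSE)
    }
    as.character(Biostrings::subseq(genome[[chrom[i]]], s, e))
  }, character(1))
}

#' Scan peaks for a motif
#'
#' Scores every offset of every peak on both strands with the motif's
#' log-odds matrix (ambiguous bases contribute 0) and calls a site when the
#' best score reaches the exact-null threshold at the model's `p_threshold`.
#' The null background is, by default, estimated from the scanned peak
#' sequences (0-order); `background = "uniform"` or `"model"` override it.
#'
#' @param peaks `GRanges` peaks.
#' @param genome `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param m a [motif_model()].
#' @param background `"sequence"` (default), `"uniform"`, or `"model"`.
#' @return list with `hits` (data.frame: `peak`, `position` 1-based within
#'   the peak, `strand`, `score`, `has_site`), `threshold` (bits), and
#'   `fraction` (peaks with at least one site / total peaks).
#' @export
scan_peaks_for_motif <- function(peaks, genome, m,
                                 background = c("sequence", "uniform", "model")) {
  background <- match.arg(background)
  stopifnot(inherits(m, "motif_model"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- peak_sequences(genome, peaks)
  bg <- switch(background,
    uniform = rep(0.25, 4),
    model = m$background,
    sequence = {
      tab <- Biostrings::letterFrequency(
        Biostrings::DNAStringSet(seqs), c("A", "C", "G", "T"))
      f <- colSums(tab)
      f <- (f + 1) / (sum(f) + 4)          # +1 smoothing keeps bg positive
      as.numeric(f)
    }
  )
  m_bg <- motif_model(m$pwm, background = bg, p_threshold = m$p_threshold,
                      step = m$step, name = m$name)
  thr <- motif_score_threshold(m_bg, m$p_threshold)
  hits <- lapply(seq_along(seqs), function(i) best_motif_hit(seqs[i], m_bg))
  names <- if (is.null(peaks$name)) as.character(seq_along(peaks)) else peaks$name
  df <- data.frame(
    peak = names,
    position = vapply(hits, function(h) h$position, integer(1)),
    strand = vapply(hits, function(h) if (is.na(h$position)) NA_character_ else h$strand,
                    character(1)),
    score = vapply(hits, function(h) h$score, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$has_site <- is.finite(df$score) & df$score >= as.numeric(thr) - 1e-9
  list(hits = df, threshold = as.numeric(thr),
       attained_p = attr(thr, "attained_p"),
       fraction = mean(df$has_site))
}

#' Select candidate target genes from motif-bearing peaks
#'
#' A gene is a candidate when at least one motif-bearing peak has a signed
#' summit-to-TSS offset inside the window (default upstream -20,000 bp to
#' downstream +500 bp, strand-aware, negative = upstream). A peak can support
#' every gene whose TSS window contains it.
#'
#' @param peaks `GRanges` peaks.
#' @param hits result of [scan_peaks_for_motif()], or a logical vector with
#'   one site call per peak.
#' @param tx `GRanges` gene annotation with `gene_id`.
#' @param window c(upstream, downstream) signed bounds in bp
#'   (default c(-20000, 500)).
#' @param strand_aware if `FALSE`, offsets ignore gene strand (genomic
#'   left = negative).
#' @return list with `candidates` (data.frame: `gene_id`,
#'   `n_supporting_peaks`, `best_offset`, `best_motif_score`) sorted by
#'   gene id, and `support` (one row per supporting peak-gene pair).
#' @export
select_candidate_genes <- function(peaks, hits, tx,
                                   window = c(-20000, 500),
                                   strand_aware = TRUE) {
  if (length(window) != 2 || window[1] > window[2]) {
    stop("'window' must be c(upstream, downstream) with upstream <= downstream",
         call. = FALSE)
  }
  if (is.list(hits) && !is.null(hits$hits)) {
    has_site <- hits$hits$has_site
    site_score <- hits$hits$score
  } else {
    has_site <- as.logical(hits)
    site_score <- rep(NA_real_, length(peaks))
  }
  if (length(has_site) != length(peaks)) {
    stop("'hits' must provide one site call per peak", call. = FALSE)
  }
  tt <- tss_table(tx)
  anchors <- peak_anchor(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  names <- if (is.null(peaks$name)) as.character(seq_along(peaks)) else peaks$name
  rows <- list()
  for (i in which(has_site)) {
    cand <- tt[tt$chrom == chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    off <- if (strand_aware) {
      ifelse(cand$strand == "+", anchors[i] - cand$tss, cand$tss - anchors[i])
    } else {
      anchors[i] - cand$tss
    }
    in_win <- off >= window[1] & off <= window[2]
    if (any(in_win)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cand$gene_id[in_win], peak = names[i],
        offset = off[in_win], motif_score = site_score[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    empty <- data.frame(gene_id = character(0), n_supporting_peaks = integer(0),
                        best_offset = numeric(0), best_motif_score = numeric(0))
    return(list(candidates = empty,
                support = data.frame(gene_id = character(0), peak = character(0),
                                     offset = numeric(0), motif_score = numeric(0)),
                window = window, strand_aware = strand_aware))
  }
  support <- do.call(rbind, rows)
  support <- support[order(support$gene_id, support$peak), , drop = FALSE]
  rownames(support) <- NULL
  candidates <- do.call(rbind, lapply(split(support, support$gene_id), function(s) {
    best <- which.min(abs(s$offset))
    data.frame(gene_id = s$gene_id[1], n_supporting_peaks = nrow(s),
               best_offset = s$offset[best],
               best_motif_score = suppressWarnings(max(s$motif_score)),
               stringsAsFactors = FALSE)
  }))
  candidates <- candidates[order(candidates$gene_id), , drop = FALSE]
  rownames(candidates) <- NULL
  list(candidates = candidates, support = support,
       window = window, strand_aware = strand_aware)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file.
#' @return `GRanges` with `score`.
#' @export
read_coverage <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

# Mean depth of each peak under a coverage track (positions without a
# coverage interval count as depth 0).
peak_mean_depth <- function(cov, peaks) {
  hits <- GenomicRanges::findOverlaps(peaks, cov)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(peaks[q], cov[s])
  contrib <- GenomicRanges::width(ov) * cov$score[s]
  sums <- tapply(contrib, factor(q, levels = seq_along(peaks)), sum)
  sums[is.na(sums)] <- 0
  as.numeric(sums) / GenomicRanges::width(peaks)
}

#' Compare read depth in peaks between two samples
#'
#' Mean per-peak depth in each sample, scaled to depth per million mapped
#' (total base coverage / 1e6 unless explicit totals are given), with a
#' log2(treated/control) density histogram and the median log-ratio. Peaks
#' with zero coverage in both samples are excluded and counted.
#'
#' @param control,treated `GRanges` bedGraph-style coverage with `score`.
#' @param peaks `GRanges` peaks.
#' @param pseudocount added to both normalized depths before the log ratio
#'   (default 0.5).
#' @param control_total,treated_total optional library sizes overriding the
#'   totals computed from the tracks.
#' @param n_breaks histogram bin count (default 50).
#' @return list with `depths` (per-peak data.frame), `median_log2_ratio`,
#'   `histogram` (data.frame mid/count/density), `n_excluded`.
#' @export
compare_peak_depth <- function(control, treated, peaks, pseudocount = 0.5,
                               control_total = NULL, treated_total = NULL,
                               n_breaks = 50) {
  c_depth <- peak_mean_depth(control, peaks)
  t_depth <- peak_mean_depth(treated, peaks)
  if (is.null(control_total)) {
    control_total <- sum(GenomicRanges::width(control) * control$score)
  }
  if (is.null(treated_total)) {
    treated_total <- sum(GenomicRanges::width(treated) * treated$score)
  }
  c_norm <- c_depth / (control_total / 1e6)
  t_norm <- t_depth / (treated_total / 1e6)
  keep <- !(c_depth == 0 & t_depth == 0)
  lr <- log2((t_norm[keep] + pseudocount) / (c_norm[keep] + pseudocount))
  names <- if (is.null(peaks$name)) as.character(seq_along(peaks)) else peaks$name
  h <- graphics::hist(lr, breaks = n_breaks, plot = FALSE)
  list(
    depths = data.frame(peak = names[keep], control = c_norm[keep],
                        treated = t_norm[keep], log2_ratio = lr,
                        stringsAsFactors = FALSE),
    median_log2_ratio = median(lr),
    histogram = data.frame(mid = h$mids, count = h$counts, density = h$density),
    n_excluded = sum(!keep)
  )
}
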