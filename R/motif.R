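#' Position weight matrix motif model
#'
#' A probability PWM over A/C/G/T with a background distribution and a
#' p-value threshold for site calling. Scores are log2 odds (bits) of motif
#' versus background, summed over positions; a site call compares the best
#' scanning score with the exact-null threshold from
#' [motif_score_threshold()].
#'
#' Scores are discretized to a fixed grid (`step` bits) so that scanning and
#' the exact null-distribution convolution operate on identical values; the
#' grid is fine enough (0.01 bits by default) for the rounding to be
#' immaterial in practice.
#'
#' @param pwm 4 x L numeric matrix of per-position letter probabilities, rows
#'   named A, C, G, T; each column must sum to 1 (tolerance 1e-9).
#' @param background length-4 probabilities (A, C, G, T), default uniform.
#' @param p_threshold site-call p-value (default 1e-4).
#' @param step score discretization step in bits (default 0.01).
#' @param name motif name.
#' @return an object of class `motif_model` with the log-odds matrix attached.
#' @export
motif_model <- function(pwm, background = rep(0.25, 4), p_threshold = 1e-4,
                        step = 0.01, name = "motif") {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) stop("'pwm' must have 4 rows (A, C, G, T)", call. = FALSE)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(pwm) < 4) stop("motif length must be >= 4", call. = FALSE)
  if (any(abs(colSums(pwm) - 1) > 1e-9)) {
    stop("each PWM column must sum to 1", call. = FALSE)
  }
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("'background' must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  p_threshold <- check_number(p_threshold, "p_threshold", 1e-300, 1)
  step <- check_number(step, "step", 1e-6, 1)
  # Floor zero probabilities so log odds stay finite; 1e-4 is far below any
  # count-derived estimate and keeps mismatch penalties strong.
  pwm_f <- pmax(pwm, 1e-4)
  pwm_f <- sweep(pwm_f, 2, colSums(pwm_f), "/")
  lodds <- log2(pwm_f / background)
  structure(
    list(pwm = pwm, background = background, lodds = lodds,
         lodds_int = round(lodds / step), step = step,
         length = ncol(pwm), p_threshold = p_threshold, name = name),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': length %d, site p-threshold %g\n",
              x$name, x$length, x$p_threshold))
  invisible(x)
}

#' Build a toy PWM from a consensus string
#'
#' Each position gives `consensus_prob` to the consensus base and splits the
#' remainder over the other three. Useful for tests and simulations; it makes
#' no claim to match any published matrix.
#'
#' @param consensus A/C/G/T string of length >= 4.
#' @param consensus_prob probability of the consensus base (default 0.85).
#' @param ... passed to [motif_model()].
#' @return a [motif_model()].
#' @export
consensus_pwm <- function(consensus, consensus_prob = 0.85, ...) {
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]{4,}$", consensus)) {
    stop("'consensus' must be an A/C/G/T string of length >= 4", call. = FALSE)
  }
  bases <- strsplit(consensus, "")[[1]]
  L <- length(bases)
  pwm <- matrix((1 - consensus_prob) / 3, 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) pwm[bases[j], j] <- consensus_prob
  motif_model(pwm, name = paste0("consensus:", consensus), ...)
}

#' Read a JASPAR-style motif file
#'
#' Plain-text matrix: an optional `>name` header followed by four lines
#' `A [ 10 20 ... ]` (brackets optional). Counts are converted to
#' probabilities with a +0.5 pseudocount per cell.
#'
#' @param path motif text file.
#' @param ... passed to [motif_model()].
#' @return a [motif_model()].
#' @export
read_jaspar_motif <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("motif file needs 4 base rows", call. = FALSE)
  counts <- matrix(0, 4, 0)
  rows <- list()
  for (ln in lines[1:4]) {
    base <- toupper(substr(ln, 1, 1))
    nums <- gsub("[][]", " ", substr(ln, 2, nchar(ln)))
    rows[[base]] <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
  }
  if (!all(c("A", "C", "G", "T") %in% names(rows))) {
    stop("motif file must have A, C, G and T rows", call. = FALSE)
  }
  counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  counts <- counts + 0.5
  pwm <- sweep(counts, 2, colSums(counts), "/")
  motif_model(pwm, name = name, ...)
}

#' Exact-null score threshold for a PWM
#'
#' Smallest achievable log-odds score `s` with `P(score >= s) <= p` when
#' sequence letters are i.i.d. from the background. The null score
#' distribution is computed exactly by position-wise convolution of the
#' per-position score distributions on the model's discretization grid — the
#' same grid [scan_peaks_for_motif()] scores sequences on, so a site call
#' (`best score >= threshold`) carries exactly the stated tail probability.
#'
#' @param m a [motif_model()].
#' @param p tail probability in (0, 1]; default the model's `p_threshold`.
#'   `p = 1` returns the minimum achievable score.
#' @return the threshold score in bits, with the achieved tail probability
#'   attached as attribute `attained_p`.
#' @export
motif_score_threshold <- function(m, p = m$p_threshold) {
  stopifnot(inherits(m, "motif_model"))
  p <- check_number(p, "p", 1e-300, 1)
  ki <- m$lodds_int
  if (p >= 1) {
    # boundary: the minimum achievable score has tail probability 1
    return(structure(sum(apply(ki, 2, min)) * m$step, attained_p = 1))
  }
  bg <- m$background
  lo <- sum(apply(ki, 2, min))
  hi <- sum(apply(ki, 2, max))
  dist <- numeric(hi - lo + 1)            # probability over grid offsets
  dist[1] <- 1
  for (j in seq_len(ncol(ki))) {
    nxt <- numeric(length(dist))
    for (b in 1:4) {
      k <- ki[b, j] - min(ki[, j])
      idx <- which(dist > 0)
      nxt[idx + k] <- nxt[idx + k] + dist[idx] * bg[b]
    }
    dist <- nxt
  }
  # dist[i] = P(grid score == lo + i - 1)
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p & dist > 0)     # smallest achievable score
  if (length(ok) == 0) {
    stop(sprintf(
      "no achievable score has tail probability <= %g; refine the model's 'step' or relax p",
      p), call. = FALSE)
  }
  i <- ok[1]
  structure((lo + i - 1) * m$step, attained_p = tail_p[i])
}

# Integer-code a DNA string: A=1 C=2 G=3 T=4, anything else (N) = 5.
dna_codes <- function(seq_chr) {
  code <- match(strsplit(toupper(seq_chr), "")[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# Log-odds scores of all length-L windows of one strand; N scores 0.
window_scores <- function(codes, lodds) {
  L <- ncol(lodds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  lut <- rbind(lodds, 0)                  # row 5: ambiguous base
  scores <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    scores <- scores + lut[cbind(codes[j:(j + n - L)], j)]
  }
  scores
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

# Best hit of a motif in one sequence over both strands; scores live on the
# model's discretization grid, consistent with motif_score_threshold().
best_motif_hit <- function(seq_chr, m) {
  codes <- dna_codes(seq_chr)
  grid_lodds <- m$lodds_int * m$step
  fw <- window_scores(codes, grid_lodds)
  rv <- window_scores(revcomp_codes(codes), grid_lodds)
  if (length(fw) == 0) {
    return(list(score = -Inf, position = NA_integer_, strand = NA_character_))
  }
  bf <- which.max(fw)
  br <- which.max(rv)
  if (fw[bf] >= rv[br]) {
    list(score = fw[bf], position = bf, strand = "+")
  } else {
    # map reverse-strand window back to forward coordinates (window start)
    list(score = rv[br], position = length(codes) - ncol(m$lodds) + 2L - br,
         strand = "-")
  }
}
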