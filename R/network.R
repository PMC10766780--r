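#' Weighted undirected interaction network
#'
#' STRING-style protein/gene interaction network stored as a canonical edge
#' table. On construction: self-loops are dropped, confidences on a 0-1000
#' scale (any value > 1) are divided by 1000, duplicate edges (in either
#' orientation) keep the maximum confidence, and edges are stored once with
#' `gene_a < gene_b` so the network is symmetric by construction.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @return an object of class `interaction_network` (a data.frame with
#'   attribute `n_dropped`, the number of self-loops and duplicates removed).
#' @export
interaction_network <- function(edges) {
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% names(edges))) {
    stop("network needs 'gene_a', 'gene_b', 'confidence' columns", call. = FALSE)
  }
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  conf <- as.numeric(edges$confidence)
  if (anyNA(conf) || any(conf < 0)) {
    stop("confidences must be non-negative numbers", call. = FALSE)
  }
  n_in <- length(a)
  if (any(conf > 1)) conf <- conf / 1000    # STRING 0-1000 scale
  if (any(conf > 1)) stop("confidences exceed 1 even after 0-1000 rescaling",
                          call. = FALSE)
  keep <- a != b
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  conf <- conf[keep]
  key <- paste(a2, b2, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(conf, key, max)
    pair <- strsplit(names(conf), "\r", fixed = TRUE)
    a2 <- vapply(pair, `[`, "", 1L)
    b2 <- vapply(pair, `[`, "", 2L)
    conf <- as.numeric(conf)
  }
  ord <- order(a2, b2)
  out <- data.frame(gene_a = a2[ord], gene_b = b2[ord],
                    confidence = conf[ord], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_in - nrow(out)
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d edges over %d genes (%d input rows dropped)\n",
              nrow(x), length(unique(c(x$gene_a, x$gene_b))),
              attr(x, "n_dropped")))
  invisible(x)
}

#' Read a network edge list
#'
#' Three-column TSV (gene_a, gene_b, confidence); lines starting with `#`
#' are skipped; a header row is detected from the name `gene_a`.
#'
#' @param path TSV file.
#' @return an [interaction_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  has_header <- length(lines) > 0 && grepl("gene_a", lines[1], fixed = TRUE)
  df <- read.table(text = lines, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("gene_a", "gene_b", "confidence")
  interaction_network(df)
}

#' Write a network edge list
#' @param net an [interaction_network()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  write_tsv_file(as.data.frame(net), path)
}

#' Interactors of a gene
#'
#' Network neighbors of `tf` with confidence at or above `min_confidence`,
#' optionally restricted to a supplied gene universe (e.g., the genes present
#' in an expression matrix). When more than `cap` neighbors qualify, the
#' `cap` highest-confidence ones are kept; confidence ties are broken
#' lexicographically by gene id. The gene itself is never returned.
#'
#' @param net an [interaction_network()].
#' @param tf gene identifier.
#' @param cap maximum number of interactors returned (default 250).
#' @param min_confidence minimum edge confidence in `[0, 1]`.
#' @param genes optional character vector restricting the neighbor universe.
#' @return character vector of interactor gene ids (possibly empty; a gene
#'   absent from the network yields an empty list with a warning so screens
#'   over many TFs can proceed).
#' @export
get_interactors <- function(net, tf, cap = 250, min_confidence = 0,
                            genes = NULL) {
  cap <- check_count(cap, "cap")
  min_confidence <- check_number(min_confidence, "min_confidence", 0, 1)
  hit_a <- net$gene_a == tf
  hit_b <- net$gene_b == tf
  if (!any(hit_a | hit_b)) {
    warning(sprintf("gene '%s' absent from network; returning no interactors", tf),
            call. = FALSE)
    return(character(0))
  }
  nb <- c(net$gene_b[hit_a], net$gene_a[hit_b])
  conf <- c(net$confidence[hit_a], net$confidence[hit_b])
  keep <- conf >= min_confidence & nb != tf
  nb <- nb[keep]; conf <- conf[keep]
  if (!is.null(genes)) {
    keep <- nb %in% genes
    nb <- nb[keep]; conf <- conf[keep]
  }
  ord <- order(-conf, nb)
  nb <- nb[ord]
  if (length(nb) > cap) nb <- nb[seq_len(cap)]
  nb
}
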