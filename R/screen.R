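#' Select the transcription-factor universe
#'
#' Genes carrying a given annotation term (e.g., the sequence-specific
#' DNA-binding term `GO:0043565`) that are also present in the expression
#' matrix, sorted lexicographically.
#'
#' @param ann a [gene_set_annotation()].
#' @param mat a [labeled_matrix()].
#' @param term annotation term identifier.
#' @return character vector of gene ids.
#' @export
select_tf_universe <- function(ann, mat, term) {
  term <- check_string(term, "term")
  universe <- intersect(annotation_genes(ann, term), mat$gene_ids)
  if (length(universe) == 0) {
    stop(sprintf("no gene annotated with '%s' is present in the matrix", term),
         call. = FALSE)
  }
  universe <- sort(universe)
  message(sprintf("TF universe: %d genes annotated '%s' and present in matrix",
                  length(universe), term))
  universe
}

# Per-class mean expression for a gene subset: classes x genes matrix.
class_means <- function(mat, genes) {
  vals <- mat$values[, genes, drop = FALSE]
  classes <- sort(unique(mat$cell_class))
  out <- matrix(0, length(classes), length(genes),
                dimnames = list(classes, genes))
  for (cl in classes) {
    out[cl, ] <- Matrix::colMeans(vals[mat$cell_class == cl, , drop = FALSE])
  }
  out
}

#' Rank genes by expression and keep the top k
#'
#' "Expressed" is scored per gene as the maximum over cell classes of the
#' within-class mean expression, implementing "expressed in at least one
#' class"; `metric = "positive_fraction"` instead uses the maximum per-class
#' fraction of cells with expression > 0. Ties are broken lexicographically.
#'
#' @param mat a [labeled_matrix()].
#' @param genes candidate gene ids (must be present in the matrix).
#' @param k how many to keep; if `length(genes) <= k` all are returned.
#' @param metric ranking statistic, `"mean"` (default) or
#'   `"positive_fraction"`.
#' @return character vector of up to `k` gene ids, best first.
#' @export
rank_top_expressed <- function(mat, genes, k,
                               metric = c("mean", "positive_fraction")) {
  metric <- match.arg(metric)
  k <- check_count(k, "k")
  if (!all(genes %in% mat$gene_ids)) {
    stop("all 'genes' must be present in the matrix", call. = FALSE)
  }
  if (length(genes) == 0) return(character(0))
  vals <- mat$values[, genes, drop = FALSE]
  if (metric == "positive_fraction") vals <- vals > 0
  classes <- unique(mat$cell_class)
  per_class <- vapply(classes, function(cl) {
    Matrix::colMeans(vals[mat$cell_class == cl, , drop = FALSE])
  }, numeric(length(genes)))
  per_class <- matrix(per_class, nrow = length(genes))
  score <- apply(per_class, 1L, max)
  ord <- order(-score, genes)
  genes[ord][seq_len(min(k, length(genes)))]
}

# Fold-change vector for every gene in the matrix, in one pass.
# mode "mean": (mean over non-basal + eps) / (mean over basal + eps)
# mode "positive_fraction": same ratio on fractions of cells with value > 0.
fold_change_vector <- function(mat, mode = c("mean", "positive_fraction"),
                               pseudocount = 0.01) {
  mode <- match.arg(mode)
  pseudocount <- check_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop("'pseudocount' must be > 0", call. = FALSE)
  basal <- is_basal(mat)
  vals <- mat$values
  if (mode == "positive_fraction") vals <- vals > 0
  num <- Matrix::colMeans(vals[!basal, , drop = FALSE])
  den <- Matrix::colMeans(vals[basal, , drop = FALSE])
  fc <- (num + pseudocount) / (den + pseudocount)
  names(fc) <- mat$gene_ids
  fc
}

#' Basal versus non-basal fold change of one gene
#'
#' With `mode = "mean"` the ratio of mean expression in non-basal cells over
#' mean expression in basal cells; with `mode = "positive_fraction"` the same
#' ratio on per-group fractions of cells with expression > 0. A pseudocount
#' is added to numerator and denominator so the ratio is defined (and equals
#' 1) for genes silent in both groups. "Non-basal" pools every cell whose
#' class differs from the matrix's basal label.
#'
#' @param mat a [labeled_matrix()].
#' @param gene gene identifier (must be in the matrix).
#' @param mode `"mean"` or `"positive_fraction"`.
#' @param pseudocount strictly positive stabilizer (default 0.01).
#' @return the fold change (a positive number).
#' @export
gene_fold_change <- function(mat, gene, mode = c("mean", "positive_fraction"),
                             pseudocount = 0.01) {
  mode <- match.arg(mode)
  if (!gene %in% mat$gene_ids) {
    stop(sprintf("gene '%s' not in matrix", gene), call. = FALSE)
  }
  unname(fold_change_vector(mat, mode, pseudocount)[gene])
}

#' Combined score of an interactor set
#'
#' Arithmetic mean, over the interactors of a TF, of the basal/non-basal
#' mean-expression fold change. This is the screen's primary statistic.
#'
#' @inheritParams gene_fold_change
#' @param interactors non-empty character vector of gene ids.
#' @return the combined score.
#' @export
combined_score <- function(mat, interactors, pseudocount = 0.01) {
  if (length(interactors) == 0) {
    stop("combined score undefined for an empty interactor set", call. = FALSE)
  }
  fc <- fold_change_vector(mat, "mean", pseudocount)
  if (!all(interactors %in% names(fc))) {
    stop("all interactors must be present in the matrix", call. = FALSE)
  }
  mean(fc[interactors])
}

#' Aggregated score of an interactor set
#'
#' Same construction as [combined_score()] but on positive-cell fractions
#' (fraction of cells with expression > 0 per group). The default summary is
#' the mean over interactors; `aggregation = "sum"` is also offered.
#'
#' @inheritParams combined_score
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @return the aggregated score.
#' @export
aggregated_score <- function(mat, interactors, aggregation = c("mean", "sum"),
                             pseudocount = 0.01) {
  aggregation <- match.arg(aggregation)
  if (length(interactors) == 0) {
    stop("aggregated score undefined for an empty interactor set", call. = FALSE)
  }
  fc <- fold_change_vector(mat, "positive_fraction", pseudocount)
  if (!all(interactors %in% names(fc))) {
    stop("all interactors must be present in the matrix", call. = FALSE)
  }
  if (aggregation == "mean") mean(fc[interactors]) else sum(fc[interactors])
}

# Draw n_perm index sets of size k without replacement from 1..m.
draw_null_sets <- function(m, k, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(m, k), integer(k))
}

#' Permutation p-value against random gene sets
#'
#' Draws `n_perm` gene sets of the observed size uniformly without
#' replacement from a gene universe (all matrix genes by default), scores
#' each with `score_fn`, and returns add-one permutation p-values:
#' `p_greater = (1 + #\{null >= observed\}) / (1 + n_perm)`, `p_less`
#' analogously, and `two.sided = min(1, 2 min(p_greater, p_less))`.
#'
#' @param mat a [labeled_matrix()] (used for the default universe and the
#'   default score function).
#' @param observed_score the statistic observed for the real interactor set.
#' @param n_interactors size of the random sets.
#' @param universe gene ids to draw from; default all matrix genes.
#' @param score_fn function(character gene set) -> numeric score; defaults to
#'   [combined_score()] on `mat`.
#' @param n_perm number of random sets (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return list with `p`, `p_greater`, `p_less`, `null` (the null scores),
#'   `n_perm`, `alternative`.
#' @export
permutation_pvalue <- function(mat, observed_score, n_interactors,
                               universe = NULL, score_fn = NULL,
                               n_perm = 1000, seed = 1,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n_perm <- check_count(n_perm, "n_perm")
  n_interactors <- check_count(n_interactors, "n_interactors")
  if (is.null(universe)) universe <- mat$gene_ids
  if (n_interactors > length(universe)) {
    stop("'n_interactors' exceeds the size of the universe", call. = FALSE)
  }
  if (is.null(score_fn)) score_fn <- function(genes) combined_score(mat, genes)
  idx <- with_seed(seed, draw_null_sets(length(universe), n_interactors, n_perm))
  null <- vapply(seq_len(n_perm),
                 function(i) score_fn(universe[idx[, i]]), numeric(1))
  ps <- pval_from_null(null, observed_score, alternative)
  list(p = ps$p, p_greater = ps$p_greater, p_less = ps$p_less,
       null = null, n_perm = n_perm, alternative = alternative)
}

#' Run the in-silico TF screen
#'
#' End-to-end screen: select the TF universe by annotation term, keep the
#' top `k` expressed TFs, expand each TF to its capped, confidence-filtered
#' interaction neighborhood, score each neighborhood (combined score on mean
#' expression, aggregated score on positive-cell fractions), attach
#' permutation p-values against random gene sets of matched size, and adjust
#' across tested TFs by Benjamini-Hochberg. TFs with no usable interactor
#' are carried through with `n_interactors = 0` and missing scores.
#'
#' @param mat a [labeled_matrix()].
#' @param ann a [gene_set_annotation()].
#' @param net an [interaction_network()].
#' @param term annotation term defining the TF universe (default
#'   `"GO:0043565"`, sequence-specific DNA binding).
#' @param k number of top-expressed TFs tested (default 100).
#' @param cap interactor cap per TF (default 250).
#' @param min_confidence minimum edge confidence (default 0).
#' @param pseudocount fold-change stabilizer (default 0.01).
#' @param n_perm permutations per TF and score (default 1000).
#' @param seed master seed; per-TF seeds are derived deterministically.
#' @param alternative p-value sidedness (default `"two.sided"`).
#' @param aggregation aggregated-score summary, `"mean"` or `"sum"`.
#' @param positive_universe if `TRUE`, restrict the permutation universe to
#'   genes with at least one positive cell.
#' @return data.frame of class `tf_screen_result`, one row per tested TF
#'   (`tf_id`, `n_interactors`, `combined_score`, `aggregated_score`,
#'   `p_combined`, `p_aggregated`, `q_combined`, `q_aggregated`), sorted by
#'   `p_combined` (ties by tf_id; untestable TFs last). Run parameters are
#'   attached as attribute `metadata`.
#' @export
run_screen <- function(mat, ann, net, term = "GO:0043565", k = 100, cap = 250,
                       min_confidence = 0, pseudocount = 0.01, n_perm = 1000,
                       seed = 1,
                       alternative = c("two.sided", "greater", "less"),
                       aggregation = c("mean", "sum"),
                       positive_universe = FALSE) {
  alternative <- match.arg(alternative)
  aggregation <- match.arg(aggregation)
  universe <- select_tf_universe(ann, mat, term)
  tfs <- rank_top_expressed(mat, universe, k)

  fc_mean <- fold_change_vector(mat, "mean", pseudocount)
  fc_pos <- fold_change_vector(mat, "positive_fraction", pseudocount)
  perm_universe <- mat$gene_ids
  if (positive_universe) {
    perm_universe <- perm_universe[Matrix::colSums(mat$values > 0) > 0]
  }
  agg_fn <- if (aggregation == "mean") mean else sum

  rows <- lapply(seq_along(tfs), function(i) {
    tf <- tfs[i]
    ints <- withCallingHandlers(
      get_interactors(net, tf, cap = cap, min_confidence = min_confidence,
                      genes = mat$gene_ids),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(ints) == 0) {
      return(data.frame(tf_id = tf, n_interactors = 0L,
                        combined_score = NA_real_, aggregated_score = NA_real_,
                        p_combined = NA_real_, p_aggregated = NA_real_,
                        stringsAsFactors = FALSE))
    }
    comb <- mean(fc_mean[ints])
    aggr <- agg_fn(fc_pos[ints])
    # One shared set of null draws scores both statistics, mirroring
    # permutation_pvalue() with the same derived seed.
    idx <- with_seed(derive_seed(seed, i),
                     draw_null_sets(length(perm_universe), length(ints), n_perm))
    gset <- matrix(perm_universe[idx], nrow = length(ints))
    null_comb <- .colMeans(matrix(fc_mean[gset], nrow = length(ints)),
                           length(ints), n_perm)
    fp <- matrix(fc_pos[gset], nrow = length(ints))
    null_aggr <- if (aggregation == "mean") {
      .colMeans(fp, length(ints), n_perm)
    } else {
      .colSums(fp, length(ints), n_perm)
    }
    data.frame(tf_id = tf, n_interactors = length(ints),
               combined_score = comb, aggregated_score = aggr,
               p_combined = pval_from_null(null_comb, comb, alternative)$p,
               p_aggregated = pval_from_null(null_aggr, aggr, alternative)$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_combined <- p.adjust(res$p_combined, method = "BH")
  res$q_aggregated <- p.adjust(res$p_aggregated, method = "BH")
  res <- res[order(res$p_combined, res$tf_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "metadata") <- list(
    term = term, k = k, cap = cap, min_confidence = min_confidence,
    pseudocount = pseudocount, n_perm = n_perm, seed = seed,
    alternative = alternative, aggregation = aggregation,
    positive_universe = positive_universe,
    n_universe = length(universe), n_tested = sum(res$n_interactors > 0)
  )
  class(res) <- c("tf_screen_result", "data.frame")
  res
}

#' Write a screen result table with its metadata sidecar
#'
#' @param res a [run_screen()] result.
#' @param path output TSV; a `<path>.meta.json` sidecar records the
#'   parameters and seed.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(res, path) {
  write_tsv_file(as.data.frame(res), path)
  meta <- attr(res, "metadata")
  meta$package_version <- as.character(utils::packageVersion("airscreen"))
  write_json_file(meta, paste0(path, ".meta.json"))
  invisible(path)
}
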