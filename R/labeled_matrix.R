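#' Labeled expression matrix
#'
#' Container for a cells x genes expression matrix with one class label per
#' cell and a designated "basal" reference class. All fold-change statistics
#' in the TF screen are computed on this object, contrasting the basal class
#' against the pool of all other ("non-basal") cells.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, cells in rows, genes
#'   in columns; must be non-negative. Row/column names are used as cell and
#'   gene identifiers when `cell_ids`/`gene_ids` are not given.
#' @param cell_class character vector, one class label per cell (row).
#' @param basal_label the label treated as the basal reference class.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#'
#' @return An object of class `labeled_matrix` with elements `values`,
#'   `gene_ids`, `cell_ids`, `cell_class`, `basal_label`.
#' @export
labeled_matrix <- function(values, cell_class, basal_label,
                           gene_ids = colnames(values),
                           cell_ids = rownames(values)) {
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("'values' must be a matrix or Matrix", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  cell_class <- as.character(cell_class)
  if (length(gene_ids) != ncol(values)) {
    stop("'gene_ids' length must equal ncol(values)", call. = FALSE)
  }
  if (length(cell_ids) != nrow(values)) {
    stop("'cell_ids' length must equal nrow(values)", call. = FALSE)
  }
  if (length(cell_class) != nrow(values)) {
    stop("'cell_class' must have one label per cell", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique", call. = FALSE)
  if (anyNA(cell_class)) stop("every cell must have a class label", call. = FALSE)
  if (min(values) < 0) stop("'values' must be non-negative", call. = FALSE)
  basal_label <- check_string(basal_label, "basal_label")
  if (!any(cell_class == basal_label)) {
    stop(sprintf("basal label '%s' matches no cell", basal_label), call. = FALSE)
  }
  if (all(cell_class == basal_label)) {
    stop("at least one non-basal cell is required", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_class = cell_class, basal_label = basal_label),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  tab <- table(x$cell_class)
  cat(sprintf("labeled_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  classes: %s (basal = '%s')\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$basal_label))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

is_basal <- function(mat) mat$cell_class == mat$basal_label

#' Read a labeled expression matrix from disk
#'
#' Two layouts are supported: a MatrixMarket triplet (`matrix.mtx` with
#' sidecar `genes.tsv` and `cells.tsv`, the latter carrying `cell_id` and
#' `class` columns), or a single dense TSV whose first two columns are
#' `cell_id` and `class` followed by one column per gene.
#'
#' @param path directory containing `matrix.mtx`/`genes.tsv`/`cells.tsv`, or
#'   a dense TSV file.
#' @param basal_label the class label to treat as basal.
#' @return a [labeled_matrix()].
#' @export
read_expression_matrix <- function(path, basal_label) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- read.table(file.path(path, "genes.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    cells <- read.table(file.path(path, "cells.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    labeled_matrix(as(m, "CsparseMatrix"), cells$class, basal_label,
                   gene_ids = genes$gene_id, cell_ids = cells$cell_id)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    mode(vals) <- "double"
    labeled_matrix(vals, df$class, basal_label,
                   gene_ids = colnames(df)[-(1:2)], cell_ids = df$cell_id)
  }
}

#' Write a labeled expression matrix
#'
#' Writes `matrix.mtx` + `genes.tsv` + `cells.tsv` under `dir`; with
#' `dense = TRUE` additionally writes `matrix_dense.tsv` (cell_id, class,
#' then one column per gene).
#'
#' @param mat a [labeled_matrix()].
#' @param dir output directory (created if needed).
#' @param dense also write the dense TSV form.
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(mat, dir, dense = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(methods::as(mat$values, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  write_tsv_file(data.frame(gene_id = mat$gene_ids), file.path(dir, "genes.tsv"))
  write_tsv_file(data.frame(cell_id = mat$cell_ids, class = mat$cell_class),
                 file.path(dir, "cells.tsv"))
  if (dense) {
    df <- data.frame(cell_id = mat$cell_ids, class = mat$cell_class,
                     as.matrix(mat$values), check.names = FALSE)
    write_tsv_file(df, file.path(dir, "matrix_dense.tsv"))
  }
  invisible(dir)
}

#' Gene-set annotation table
#'
#' A long-format mapping from gene identifiers to annotation term
#' identifiers (GO-style). Lookups for absent genes return the empty set.
#'
#' @param df data.frame with columns `gene_id` and `term`.
#' @return an object of class `gene_set_annotation` (a validated data.frame).
#' @export
gene_set_annotation <- function(df) {
  if (!all(c("gene_id", "term") %in% names(df))) {
    stop("annotation needs 'gene_id' and 'term' columns", call. = FALSE)
  }
  df$gene_id <- as.character(df$gene_id)
  df$term <- as.character(df$term)
  if (any(!nzchar(df$term)) || anyNA(df$term)) {
    stop("term identifiers must be non-empty strings", call. = FALSE)
  }
  df <- unique(df[, c("gene_id", "term")])
  class(df) <- c("gene_set_annotation", "data.frame")
  df
}

#' @rdname gene_set_annotation
#' @param path two-column TSV (gene, term); a header line is optional and
#'   detected from the column names `gene_id`/`term`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  df <- read.table(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("gene_id", "term")
  gene_set_annotation(df)
}

#' Genes annotated with a term
#'
#' @param ann a [gene_set_annotation()].
#' @param term term identifier.
#' @return character vector of gene ids (possibly empty), sorted.
#' @export
annotation_genes <- function(ann, term) {
  sort(unique(ann$gene_id[ann$term == term]))
}
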