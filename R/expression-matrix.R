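#' Expression matrix container
#'
#' A dense nonnegative observations x genes matrix with unique observation and
#' gene identifiers. This is the common currency of the package: the single-cell
#' reference (`obs_kind = "cells"`) and the spatial matrix (`obs_kind = "spots"`)
#' are both `expression_matrix` objects.
#'
#' @param values Numeric matrix, observations in rows, genes in columns. All
#'   entries must be finite and `>= 0`.
#' @param obs_ids Character vector of unique observation identifiers
#'   (cell barcodes or spot identifiers); defaults to existing rownames or
#'   `obs1..obsN`.
#' @param gene_ids Character vector of unique gene symbols; defaults to existing
#'   colnames.
#' @param obs_kind Either `"cells"` or `"spots"`.
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   dimnames set and an `obs_kind` attribute.
#' @export
expression_matrix <- function(values, obs_ids = NULL, gene_ids = NULL,
                              obs_kind = c("cells", "spots")) {
  obs_kind <- match.arg(obs_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(obs_ids)) {
    obs_ids <- rownames(values)
    if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) stop("`gene_ids` required when `values` has no colnames",
                                call. = FALSE)
  }
  if (length(obs_ids) != nrow(values)) {
    stop("length(obs_ids) != nrow(values)", call. = FALSE)
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) != ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(obs_ids)) stop("observation identifiers must be unique", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique", call. = FALSE)
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf("expression values must be finite and >= 0; offending entry [%s, %s] = %s",
                 obs_ids[i[1]], gene_ids[i[2]], format(values[bad[1]])), call. = FALSE)
  }
  dimnames(values) <- list(as.character(obs_ids), as.character(gene_ids))
  structure(values, obs_kind = obs_kind, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %s x %d genes\n",
              nrow(x), attr(x, "obs_kind"), ncol(x)))
  invisible(x)
}

obs_kind <- function(x) attr(x, "obs_kind")

#' Subset an expression matrix keeping class and attributes
#' @noRd
em_subset <- function(x, i = NULL, j = NULL) {
  kind <- obs_kind(x)
  v <- unclass(x)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, obs_kind = kind)
}

#' Read an expression matrix from disk
#'
#' Supported formats: `csv` (observations x genes, header row of gene symbols,
#' first column observation identifiers) and `mtx` (MatrixMarket triplet; genes
#' and observation identifiers in companion single-column files, conventionally
#' `genes.tsv` and `barcodes.tsv` next to the matrix, genes as MTX rows as in
#' the 10x convention).
#'
#' @param path Path to the csv or mtx file.
#' @param format `"csv"` or `"mtx"`.
#' @param obs_kind `"cells"` or `"spots"`.
#' @param genes_path,obs_path Companion identifier files for `mtx`; default to
#'   `genes.tsv` / `barcodes.tsv` in the directory of `path`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("csv", "mtx"),
                            obs_kind = c("cells", "spots"),
                            genes_path = NULL, obs_path = NULL) {
  format <- match.arg(format)
  obs_kind <- match.arg(obs_kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    expression_matrix(m, obs_kind = obs_kind)
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(obs_path)) obs_path <- file.path(dir, "barcodes.tsv")
    for (p in c(genes_path, obs_path)) {
      if (!file.exists(p)) stop(sprintf("companion file not found: %s", p), call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    obs <- readLines(obs_path)
    if (nrow(m) != length(genes) || ncol(m) != length(obs)) {
      stop(sprintf("mtx dimensions %dx%d do not match %d genes x %d observations",
                   nrow(m), ncol(m), length(genes), length(obs)), call. = FALSE)
    }
    expression_matrix(t(m), obs_ids = obs, gene_ids = genes, obs_kind = obs_kind)
  }
}

#' Write an expression matrix to disk
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param format `"csv"` or `"mtx"` (mtx writes `genes.tsv`/`barcodes.tsv`
#'   companions next to it).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expression_matrix"))
  if (format == "csv") {
    df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
    names(df)[1] <- ""
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(t(unclass(x)), sparse = TRUE), path)
    writeLines(colnames(x), file.path(dir, "genes.tsv"))
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Library-size normalize and log-transform
#'
#' Scales every observation (row) to a common total `target_sum`, then applies
#' `log1p`. Rows that are entirely zero are left as zeros. Applied identically
#' to real spots and pseudo-spots so both domains share one expression scale.
#'
#' @param x An [expression_matrix()].
#' @param target_sum Row total before the log transform (default `1e4`).
#' @return A normalized [expression_matrix()].
#' @export
normalize_expression <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "expression_matrix"), target_sum > 0)
  rs <- rowSums(x)
  if (all(rs == 0)) stop("at least one row must be nonzero", call. = FALSE)
  scale <- ifelse(rs > 0, target_sum / rs, 0)
  v <- log1p(unclass(x) * scale)
  expression_matrix(v, obs_kind = obs_kind(x))
}

#' Cell-type labels for a single-cell reference
#'
#' @param labels Character or factor vector, one label per cell.
#' @param type_names Ordered unique cell-type names; defaults to the sorted
#'   unique labels.
#' @return A `cell_type_labels` object (factor with fixed levels).
#' @export
cell_type_labels <- function(labels, type_names = NULL) {
  labels <- as.character(labels)
  if (is.null(type_names)) type_names <- sort(unique(labels))
  if (length(type_names) < 2) stop("at least 2 cell types required", call. = FALSE)
  unknown <- setdiff(unique(labels), type_names)
  if (length(unknown)) {
    stop(sprintf("labels not in type_names: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  structure(factor(labels, levels = type_names), class = c("cell_type_labels", "factor"))
}
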