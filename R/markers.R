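#' Select marker genes by one-vs-rest rank-sum test
#'
#' For each cell type, every gene is scored with a one-vs-rest Wilcoxon
#' rank-sum statistic on the log-normalized reference, standardised to a
#' z-score (positive = higher in the type). The top `n_top` genes per type are
#' retained; ties in the statistic are broken by lexicographic gene identifier
#' so the result is invariant to cell order.
#'
#' @param ref Single-cell reference, an [expression_matrix()] with
#'   `obs_kind = "cells"` (raw counts; log-normalization is applied internally).
#' @param labels A [cell_type_labels()] aligned with `ref` rows.
#' @param n_top Number of genes kept per type (default 200).
#' @return A `marker_gene_set`: list with `per_type` (named list of ordered
#'   gene vectors) and `union` (deduplicated union preserving first occurrence
#'   across types in `type_names` order).
#' @export
select_marker_genes <- function(ref, labels, n_top = 200) {
  stopifnot(inherits(ref, "expression_matrix"), n_top >= 1)
  if (obs_kind(ref) != "cells") stop("`ref` must have obs_kind = 'cells'", call. = FALSE)
  labels <- cell_type_labels(labels, levels(labels))
  if (length(labels) != nrow(ref)) stop("labels length != number of cells", call. = FALSE)
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop(sprintf("cell type(s) with fewer than 2 cells: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  x <- unclass(normalize_expression(ref))
  n <- nrow(x)
  # column-wise mid-ranks once; rank-sum statistic per group follows by sums
  rk <- apply(x, 2, rank, ties.method = "average")
  genes <- colnames(x)
  # tie correction term per gene (type-independent)
  ties <- apply(x, 2, function(col) {
    t_ <- tabulate(match(col, unique(col)))
    sum(t_^3 - t_)
  })
  per_type <- lapply(levels(labels), function(tp) {
    in_tp <- labels == tp
    n1 <- sum(in_tp)
    n2 <- n - n1
    rsum <- colSums(rk[in_tp, , drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
    z <- (rsum - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
    ord <- order(-z, genes)
    genes[ord][seq_len(min(n_top, length(genes)))]
  })
  names(per_type) <- levels(labels)
  union <- unique(unlist(per_type, use.names = FALSE))
  structure(list(per_type = per_type, union = union, n_top = n_top),
            class = "marker_gene_set")
}

#' @export
print.marker_gene_set <- function(x, ...) {
  cat(sprintf("marker_gene_set: %d types, %d genes in union (n_top = %d)\n",
              length(x$per_type), length(x$union), x$n_top))
  invisible(x)
}

#' Restrict spatial and reference matrices to a shared marker panel
#'
#' Both matrices are subset to the genes present in the marker union AND in
#' both gene lists, in the marker-union order. That order is the canonical gene
#' panel for the model downstream.
#'
#' @param st Spatial [expression_matrix()].
#' @param ref Reference [expression_matrix()].
#' @param markers A `marker_gene_set` from [select_marker_genes()].
#' @return List with elements `st` and `ref`, both on the shared panel.
#' @export
intersect_and_subset <- function(st, ref, markers) {
  stopifnot(inherits(st, "expression_matrix"), inherits(ref, "expression_matrix"),
            inherits(markers, "marker_gene_set"))
  panel <- markers$union[markers$union %in% colnames(st) &
                         markers$union %in% colnames(ref)]
  if (length(panel) == 0) {
    stop("no genes shared between the marker union, st and ref", call. = FALSE)
  }
  list(st = em_subset(st, j = panel), ref = em_subset(ref, j = panel))
}
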