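#' Specification for a synthetic deconvolution fixture
#'
#' Defines a fully synthetic single-cell reference plus a matching
#' ground-truth spatial dataset, so the whole pipeline can be exercised and
#' scored offline. Genes get log-normal baseline rates; each cell type
#' elevates its own disjoint block of `markers_per_type` marker genes by the
#' fold factor `signal`; counts are negative-binomial with dispersion `noise`
#' (variance `mu + noise * mu^2`, so `noise -> 0` approaches Poisson).
#'
#' @param K Number of cell types (default 5).
#' @param G Number of genes (default 200). Must satisfy
#'   `K * markers_per_type <= G`.
#' @param markers_per_type Planted markers per type (default 20).
#' @param cells_per_type Reference cells per type (default 200).
#' @param n_spots Ground-truth spatial spots (default 500).
#' @param signal Fold elevation of a type's markers (default 5; 1 = no
#'   signal, types exchangeable).
#' @param noise Negative-binomial dispersion (default 0.25).
#' @param alpha Dirichlet concentration for spot compositions (default 0.5;
#'   smaller = more one-hot spots).
#' @param spatial_pattern `"random"` (i.i.d. Dirichlet spots) or `"blocks"`
#'   (contiguous spot blocks, each enriched for one focal type, providing
#'   region structure for AUC evaluation).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(K = 5, G = 200, markers_per_type = 20,
                         cells_per_type = 200, n_spots = 500, signal = 5,
                         noise = 0.25, alpha = 0.5,
                         spatial_pattern = c("random", "blocks"), seed = 0) {
  spatial_pattern <- match.arg(spatial_pattern)
  stopifnot(K >= 2, G >= 1, K * markers_per_type <= G, markers_per_type >= 1,
            cells_per_type >= 2, n_spots >= 1, signal > 0, noise >= 0, alpha > 0)
  structure(list(K = K, G = G, markers_per_type = markers_per_type,
                 cells_per_type = cells_per_type, n_spots = n_spots,
                 signal = signal, noise = noise, alpha = alpha,
                 spatial_pattern = spatial_pattern, seed = as.integer(seed)),
            class = "fixture_spec")
}

rnbinom_disp <- function(n, mu, disp) {
  if (disp <= 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / disp, mu = mu)
}

#' Simulate a labelled single-cell reference
#'
#' @param spec A [fixture_spec()].
#' @return List with `ref` (an [expression_matrix()] of raw counts, cells x
#'   genes), `labels` (a [cell_type_labels()]), and `markers` (list of planted
#'   marker genes per type).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  G <- spec$G; K <- spec$K
  genes <- sprintf("gene%03d", seq_len(G))
  types <- paste0("type", LETTERS[seq_len(K)])
  base <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
  planted <- lapply(seq_len(K), function(k) {
    genes[(k - 1) * spec$markers_per_type + seq_len(spec$markers_per_type)]
  })
  names(planted) <- types
  n_cells <- K * spec$cells_per_type
  counts <- matrix(0L, n_cells, G)
  lab <- rep(types, each = spec$cells_per_type)
  for (k in seq_len(K)) {
    mu <- base
    mi <- (k - 1) * spec$markers_per_type + seq_len(spec$markers_per_type)
    mu[mi] <- mu[mi] * spec$signal
    rows <- which(lab == types[k])
    for (r in rows) counts[r, ] <- rnbinom_disp(G, mu, spec$noise)
  }
  ref <- expression_matrix(counts * 1.0,
                           obs_ids = sprintf("cell%05d", seq_len(n_cells)),
                           gene_ids = genes, obs_kind = "cells")
  list(ref = ref, labels = cell_type_labels(lab, types), markers = planted)
}

# deterministic per-type half split: first half trains, second half builds
# the ground-truth spots, so no cell is shared between the two roles
split_reference <- function(labels) {
  train <- logical(length(labels))
  for (tp in levels(labels)) {
    idx <- which(labels == tp)
    train[idx[seq_len(ceiling(length(idx) / 2))]] <- TRUE
  }
  train
}

#' Build a ground-truth spatial dataset from a fixture reference
#'
#' Each spot draws a composition from a Dirichlet (block-specific means under
#' the `"blocks"` pattern), converts it to integer cell counts by a
#' multinomial draw of `t ~ round(N(10, 5))` cells clamped to `[2, 30]`, and
#' sums the raw counts of cells sampled with replacement from the held-out
#' half of the reference (cells never exposed to training). The recorded
#' truth is the realised composition `counts / t` — exactly what the spot
#' contains.
#'
#' @param spec A [fixture_spec()].
#' @param ref Reference [expression_matrix()] from [make_reference()].
#' @param labels Matching [cell_type_labels()].
#' @return List with `st` (raw-count spots x genes [expression_matrix()]),
#'   `truth` (spots x K proportion matrix), `regions` (spot block labels;
#'   `NULL` for the random pattern), and `train_cells` (logical mask of
#'   reference cells safe to expose to training).
#' @export
make_ground_truth_st <- function(spec, ref, labels) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(ref, "expression_matrix"))
  set.seed(spec$seed + 1L)
  K <- spec$K
  types <- levels(labels)
  train <- split_reference(labels)
  held <- which(!train)
  held_by_type <- split(held, labels[held])
  n <- spec$n_spots
  regions <- NULL
  alpha_mat <- matrix(spec$alpha, n, K)
  if (spec$spatial_pattern == "blocks") {
    regions <- sort(rep(seq_len(K), length.out = n))
    for (s in seq_len(n)) alpha_mat[s, regions[s]] <- spec$alpha * 10
  }
  refv <- unclass(ref)
  raw <- matrix(0, n, ncol(ref))
  truth <- matrix(0, n, K, dimnames = list(NULL, types))
  for (s in seq_len(n)) {
    g <- stats::rgamma(K, shape = alpha_mat[s, ], rate = 1)
    p <- g / sum(g)
    t_ <- min(max(round(stats::rnorm(1, 10, 5)), 2), 30)
    cnt <- as.integer(stats::rmultinom(1, t_, p))
    row <- numeric(ncol(ref))
    for (k in which(cnt > 0)) {
      pool <- held_by_type[[k]]
      idx <- pool[sample.int(length(pool), cnt[k], replace = TRUE)]
      row <- row + colSums(refv[idx, , drop = FALSE])
    }
    raw[s, ] <- row
    truth[s, ] <- cnt / t_
  }
  st <- expression_matrix(raw, obs_ids = sprintf("spot%04d", seq_len(n)),
                          gene_ids = colnames(ref), obs_kind = "spots")
  list(st = st, truth = truth, regions = regions, train_cells = train)
}

#' One-call synthetic fixture: training reference + ground-truth spots
#'
#' Convenience wrapper: simulates the reference, builds the ground-truth
#' spatial data from the held-out cell half, and returns the training half of
#' the reference alongside.
#'
#' @param spec A [fixture_spec()].
#' @return List with `ref` / `labels` (training half only), `st` (raw spot
#'   counts), `truth`, `regions`, and `markers` (planted markers per type).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  r <- make_reference(spec)
  gt <- make_ground_truth_st(spec, r$ref, r$labels)
  keep <- gt$train_cells
  list(ref = em_subset(r$ref, i = which(keep)),
       labels = cell_type_labels(as.character(r$labels[keep]), levels(r$labels)),
       st = gt$st, truth = gt$truth, regions = gt$regions, markers = r$markers)
}
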