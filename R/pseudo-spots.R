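#' Parameters for pseudo-spot simulation
#'
#' Pseudo-spots are built by mixing reference cells: the number of cells per
#' spot `t` and the number of distinct cell types per spot `c` are drawn from
#' rounded, clamped normal distributions, `t` is partitioned uniformly at
#' random among the `c` chosen types, and cells are sampled with replacement
#' within each type. Defaults emulate Visium-scale spot occupancy.
#'
#' @param n_spots Number of pseudo-spots (default 10000).
#' @param mu_t,sigma_t Mean and sd of cells per spot (default 10, 5).
#' @param t_bounds Integer interval clamping `t` (default `c(2, 30)`).
#' @param mu_c,sigma_c Mean and sd of cell types per spot (default 4, 2).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `pseudo_spot_params` list.
#' @export
pseudo_spot_params <- function(n_spots = 10000, mu_t = 10, sigma_t = 5,
                               t_bounds = c(2, 30), mu_c = 4, sigma_c = 2,
                               seed = 0) {
  stopifnot(n_spots >= 1, length(t_bounds) == 2, t_bounds[1] >= 1,
            t_bounds[1] <= t_bounds[2], sigma_t >= 0, sigma_c >= 0,
            mu_t >= t_bounds[1], mu_t <= t_bounds[2])
  structure(list(n_spots = as.integer(n_spots), mu_t = mu_t, sigma_t = sigma_t,
                 t_bounds = as.integer(t_bounds), mu_c = mu_c, sigma_c = sigma_c,
                 seed = as.integer(seed)),
            class = "pseudo_spot_params")
}

# deterministic per-spot substream so changing n_spots never reshuffles
# earlier spots; 2^31-safe
spot_seed <- function(seed, spot) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(spot)) %% 2147483647)
}

#' Draw one spot's cell-type composition
#'
#' Draws `t = round(N(mu_t, sigma_t))` clamped to `t_bounds` and
#' `c = round(N(mu_c, sigma_c))` clamped to `[1, min(K, t)]`, picks `c`
#' distinct types uniformly, and partitions `t` into `c` positive parts via a
#' uniform random composition (`c - 1` distinct cut points among the `t - 1`
#' gaps).
#'
#' @param params A [pseudo_spot_params()].
#' @param K Number of cell types.
#' @return Named integer vector: positive cell counts for the chosen
#'   type indices (names are type indices as characters).
#' @export
sample_composition <- function(params, K) {
  stopifnot(K >= 1)
  t_ <- round(stats::rnorm(1, params$mu_t, params$sigma_t))
  t_ <- min(max(t_, params$t_bounds[1]), params$t_bounds[2])
  c_ <- round(stats::rnorm(1, params$mu_c, params$sigma_c))
  c_ <- min(max(c_, 1), min(K, t_))
  types <- sample.int(K, c_)
  if (c_ == 1) {
    counts <- t_
  } else {
    cuts <- sort(sample.int(t_ - 1, c_ - 1))
    counts <- diff(c(0L, cuts, t_))
  }
  stats::setNames(as.integer(counts), as.character(types))
}

#' Generate labelled pseudo-spots from a single-cell reference
#'
#' For each spot a composition is drawn with [sample_composition()]; cells are
#' sampled uniformly with replacement within each chosen type and their
#' raw-count rows summed, so a spot aggregates transcripts the way a physical
#' spot does. The summed matrix is then library-size normalized
#' ([normalize_expression()]) with the same `target_sum` used for the real
#' spatial matrix. Labels are the exact rational proportions
#' `count_k / t`.
#'
#' @param ref Reference [expression_matrix()] (raw counts), already subset to
#'   the shared gene panel.
#' @param labels [cell_type_labels()] aligned with `ref` rows.
#' @param params A [pseudo_spot_params()].
#' @param target_sum Normalization target passed to [normalize_expression()].
#' @return A `pseudo_spot_batch`: list with `X_S` (normalized
#'   [expression_matrix()], spots x genes), `Y_r` (spots x K proportion matrix,
#'   rows summing to 1), and `composition` (list of named integer count
#'   vectors).
#' @export
generate_pseudo_spots <- function(ref, labels, params = pseudo_spot_params(),
                                  target_sum = 1e4) {
  stopifnot(inherits(ref, "expression_matrix"), inherits(params, "pseudo_spot_params"))
  labels <- cell_type_labels(labels, levels(labels))
  stopifnot(length(labels) == nrow(ref))
  type_names <- levels(labels)
  K <- length(type_names)
  empty <- type_names[tabulate(labels, K) == 0]
  if (length(empty)) {
    stop(sprintf("cell type(s) with zero cells: %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  }
  cells_by_type <- split(seq_len(nrow(ref)), labels)
  n <- params$n_spots
  raw <- matrix(0, n, ncol(ref))
  Y <- matrix(0, n, K, dimnames = list(NULL, type_names))
  comp <- vector("list", n)
  refv <- unclass(ref)
  for (s in seq_len(n)) {
    set.seed(spot_seed(params$seed, s))
    cc <- sample_composition(params, K)
    t_ <- sum(cc)
    row <- numeric(ncol(ref))
    for (j in seq_along(cc)) {
      k <- as.integer(names(cc)[j])
      pool <- cells_by_type[[k]]
      idx <- pool[sample.int(length(pool), cc[j], replace = TRUE)]
      row <- row + colSums(refv[idx, , drop = FALSE])
    }
    raw[s, ] <- row
    Y[s, as.integer(names(cc))] <- as.numeric(cc) / t_
    comp[[s]] <- cc
  }
  X <- expression_matrix(raw, obs_ids = paste0("pseudo", seq_len(n)),
                         gene_ids = colnames(ref), obs_kind = "spots")
  X <- normalize_expression(X, target_sum)
  rownames(Y) <- rownames(X)
  structure(list(X_S = X, Y_r = Y, composition = comp, type_names = type_names,
                 params = params),
            class = "pseudo_spot_batch")
}

#' @export
print.pseudo_spot_batch <- function(x, ...) {
  cat(sprintf("pseudo_spot_batch: %d spots x %d genes, %d cell types\n",
              nrow(x$X_S), ncol(x$X_S), length(x$type_names)))
  invisible(x)
}
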