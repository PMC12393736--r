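#' Random binary mask over a spot-by-gene matrix
#'
#' Each entry is independently masked (set to 1) with probability `rho`.
#' Entries with value 1 are masked, 0 are visible. Masks are regenerated every
#' training iteration, so each pass reconstructs a fresh random subset of the
#' real spot matrix.
#'
#' @param n_spots,n_genes Mask dimensions.
#' @param rho Masking rate in `[0, 1]` (training default 0.3).
#' @return A `mask` object: binary matrix with a `rho` attribute.
#' @export
generate_mask <- function(n_spots, n_genes, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    stop("`rho` must be a single value in [0, 1]", call. = FALSE)
  }
  M <- matrix(as.numeric(stats::runif(n_spots * n_genes) < rho), n_spots, n_genes)
  structure(M, rho = rho, class = c("mask", "matrix", "array"))
}

#' Apply a mask: masked entries set to zero
#'
#' @param X An [expression_matrix()] or plain matrix.
#' @param mask A [generate_mask()] result of identical shape.
#' @return Same type as `X` with masked entries zeroed.
#' @export
apply_mask <- function(X, mask) {
  if (!all(dim(X) == dim(mask))) {
    stop(sprintf("shape mismatch: X is %dx%d, mask is %dx%d",
                 nrow(X), ncol(X), nrow(mask), ncol(mask)), call. = FALSE)
  }
  out <- unclass(X) * (1 - unclass(mask))
  if (inherits(X, "expression_matrix")) {
    expression_matrix(out, obs_kind = obs_kind(X))
  } else out
}

#' Reconstruction error over masked entries
#'
#' Squared error between reconstruction and original, restricted to masked
#' entries (elementwise product with the mask), divided by the number of
#' masked entries so the loss scale is independent of `rho`. Returns 0 when
#' nothing is masked.
#'
#' @param X_hat Reconstruction matrix.
#' @param X Original matrix.
#' @param mask A [generate_mask()] result.
#' @return Nonnegative scalar.
#' @export
masked_mse <- function(X_hat, X, mask) {
  if (!all(dim(X_hat) == dim(X)) || !all(dim(X) == dim(mask))) {
    stop("X_hat, X and mask must share one shape", call. = FALSE)
  }
  if (!all(is.finite(X_hat)) || !all(is.finite(X))) {
    stop("non-finite values in masked_mse inputs", call. = FALSE)
  }
  nm <- sum(mask)
  if (nm == 0) return(0)
  sum(((unclass(X_hat) - unclass(X)) * unclass(mask))^2) / nm
}
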