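#' Pearson correlation between truth and prediction
#'
#' @param x Ground-truth per-spot values for one cell type.
#' @param x_hat Predicted values.
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either vector is
#'   constant (correlation undefined).
#' @export
pcc <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(x_hat) == 0) {
    warning("pcc undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(x, x_hat)
}

#' Structural similarity between truth and prediction
#'
#' Both vectors are min-max scaled to `[0, 1]` and compared with
#' `(2*mu*mu_hat + C1)(2*cov + C2) / ((mu^2 + mu_hat^2 + C1)(var + var_hat + C2))`
#' using the stabilizing constants `C1 = 0.01`, `C2 = 0.03`. Means, variances
#' and covariance are population (divide-by-n) moments.
#'
#' @inheritParams pcc
#' @param C1,C2 Stabilizing constants.
#' @return Similarity `<= 1`; 1 when the scaled vectors coincide.
#' @export
ssim <- function(x, x_hat, C1 = 0.01, C2 = 0.03) {
  stopifnot(length(x) == length(x_hat), length(x) >= 1)
  minmax <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  a <- minmax(x); b <- minmax(x_hat)
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean(a^2) - mu_a^2
  vb <- mean(b^2) - mu_b^2
  cab <- mean(a * b) - mu_a * mu_b
  (2 * mu_a * mu_b + C1) * (2 * cab + C2) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Root mean squared error
#'
#' @inheritParams pcc
#' @return Nonnegative scalar.
#' @export
rmse <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat), length(x) >= 1)
  sqrt(mean((x - x_hat)^2))
}

#' Jensen-Shannon divergence between two spatial distributions
#'
#' Inputs are nonnegative vectors over spots, each normalized internally to
#' sum 1. The divergence uses base-2 logarithms so the range is `[0, 1]`, with
#' 0 for identical distributions and 1 for disjoint supports. `0 * log(0)`
#' terms contribute 0.
#'
#' @param p Ground-truth spatial distribution (nonnegative).
#' @param p_hat Predicted spatial distribution.
#' @return Divergence in `[0, 1]`.
#' @export
js <- function(p, p_hat) {
  stopifnot(length(p) == length(p_hat))
  if (any(p < 0) || any(p_hat < 0)) stop("distributions must be nonnegative", call. = FALSE)
  if (sum(p) == 0 || sum(p_hat) == 0) stop("a distribution sums to zero", call. = FALSE)
  p <- p / sum(p)
  q <- p_hat / sum(p_hat)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Rank-composite accuracy score across methods
#'
#' Each method is ranked on its mean PCC, SSIM, RMSE and JS: for PCC and SSIM
#' the largest value gets the top rank `N`, for RMSE and JS the smallest error
#' gets the top rank. Ranks are divided by the number of methods `N`, and the
#' accuracy score is the mean of the four normalized ranks, so a method that
#' is strictly best everywhere scores 1 and one strictly worst everywhere
#' scores `1/N`. Ties share the mean of the tied ranks.
#'
#' @param method_metrics data.frame with one row per method and columns
#'   `pcc`, `ssim`, `rmse`, `js` (dataset means); rownames or a `method`
#'   column identify methods.
#' @return Named numeric vector of accuracy scores.
#' @export
accuracy_score <- function(method_metrics) {
  df <- as.data.frame(method_metrics)
  methods <- if ("method" %in% names(df)) df$method else rownames(df)
  need <- c("pcc", "ssim", "rmse", "js")
  for (m in need) {
    if (!m %in% names(df)) stop(sprintf("missing metric column '%s'", m), call. = FALSE)
    bad <- which(!is.finite(df[[m]]))
    if (length(bad)) {
      stop(sprintf("method '%s' is missing metric '%s'", methods[bad[1]], m),
           call. = FALSE)
    }
  }
  if (nrow(df) < 2) stop("accuracy_score needs at least 2 methods", call. = FALSE)
  N <- nrow(df)
  r <- cbind(rank(df$pcc), rank(df$ssim), rank(-df$rmse), rank(-df$js)) / N
  stats::setNames(rowMeans(r), methods)
}

#' Region AUC from cumulative proportion scores
#'
#' Area under the ROC curve for separating spots inside an annotated tissue
#' region from those outside, scored by the summed predicted proportions of
#' the region's constituent cell types. Computed by the rank (Mann-Whitney)
#' formulation; tied scores contribute 1/2.
#'
#' @param scores Per-spot real score.
#' @param region_labels Per-spot binary membership (1 = in region).
#' @return AUC in `[0, 1]`.
#' @export
region_auc <- function(scores, region_labels) {
  stopifnot(length(scores) == length(region_labels))
  y <- as.numeric(region_labels)
  if (!all(y %in% c(0, 1))) stop("region_labels must be binary", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise cell-type correlation of inferred proportions
#'
#' Pearson correlation between every pair of cell-type abundance columns
#' across spots; symmetric with unit diagonal. A constant column yields `NA`
#' entries (flagged with a warning) rather than an error.
#'
#' @param Y Proportion matrix (spots x cell types).
#' @return K x K correlation matrix.
#' @export
celltype_correlation <- function(Y) {
  stopifnot(nrow(Y) >= 2)
  const <- apply(Y, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("constant proportion column(s): %s; correlations flagged NA",
                    paste(colnames(Y)[const], collapse = ", ")))
  }
  suppressWarnings(R <- stats::cor(Y))
  R[const, ] <- NA_real_
  R[, const] <- NA_real_
  d <- diag(R)
  d[!const] <- 1
  diag(R) <- d
  R
}

#' Full metric report for a prediction against ground truth
#'
#' Computes per-type PCC, SSIM, RMSE and JS between matched columns of the
#' truth and prediction matrices, plus unweighted dataset means over types.
#' Degenerate (constant) truth or prediction columns give `NA` for PCC and are
#' excluded from the mean.
#'
#' @param truth Ground-truth proportion matrix (spots x types).
#' @param pred Predicted proportion matrix with the same dimensions and
#'   column order.
#' @return List with `per_type` (data.frame) and `means` (named vector of
#'   mean_pcc, mean_ssim, mean_rmse, mean_js).
#' @export
evaluate_deconvolution <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  K <- ncol(truth)
  per <- data.frame(type = colnames(truth) %||% paste0("type", seq_len(K)),
                    pcc = NA_real_, ssim = NA_real_, rmse = NA_real_, js = NA_real_)
  for (k in seq_len(K)) {
    x <- truth[, k]; xh <- pred[, k]
    per$pcc[k] <- if (stats::sd(x) == 0 || stats::sd(xh) == 0) NA_real_ else stats::cor(x, xh)
    per$ssim[k] <- ssim(x, xh)
    per$rmse[k] <- rmse(x, xh)
    per$js[k] <- if (sum(x) == 0 || sum(xh) == 0) NA_real_ else js(x, xh)
  }
  means <- c(mean_pcc = mean(per$pcc, na.rm = TRUE),
             mean_ssim = mean(per$ssim, na.rm = TRUE),
             mean_rmse = mean(per$rmse, na.rm = TRUE),
             mean_js = mean(per$js, na.rm = TRUE))
  list(per_type = per, means = means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
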