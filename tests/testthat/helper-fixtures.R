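# Shared small objects and independent brute-force oracles used across tests.

tiny_expr <- function(values, kind = "cells") {
  expression_matrix(values,
                    obs_ids = paste0("o", seq_len(nrow(values))),
                    gene_ids = paste0("g", seq_len(ncol(values))),
                    obs_kind = kind)
}

random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# --- independent loss transcriptions (double loops, no shared code paths) ---

brute_masked_mse <- function(X_hat, X, M) {
  s <- 0; nm <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    s <- s + ((X_hat[i, j] - X[i, j]) * M[i, j])^2
    nm <- nm + M[i, j]
  }
  if (nm == 0) 0 else s / nm
}

brute_bce <- function(y, p, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
  }
  -s / length(y)
}

brute_predictor_loss <- function(Y, Yr) {
  s <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
    s <- s + (Y[i, j] - Yr[i, j])^2
  }
  s / nrow(Y)
}

# --- independent metric transcriptions ---

brute_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_ssim <- function(x, y, C1 = 0.01, C2 = 0.03) {
  sc <- function(v) if (max(v) == min(v)) rep(0, length(v)) else (v - min(v)) / (max(v) - min(v))
  x <- sc(x); y <- sc(y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + C1) * (2 * cxy + C2) / ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

brute_js <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

brute_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# prepared small training problem shared by training/acceptance tests
small_problem <- function(seed = 101, n_pseudo = 300, K = 3, G = 60) {
  fx <- make_fixture(fixture_spec(K = K, G = G, markers_per_type = 10,
                                  cells_per_type = 40, n_spots = 80, seed = seed))
  mk <- select_marker_genes(fx$ref, fx$labels, n_top = 20)
  sub <- intersect_and_subset(fx$st, fx$ref, mk)
  pseudo <- generate_pseudo_spots(sub$ref, fx$labels,
                                  pseudo_spot_params(n_spots = n_pseudo, seed = seed + 1))
  list(stn = normalize_expression(sub$st), pseudo = pseudo, truth = fx$truth,
       labels = fx$labels)
}

small_config <- function(seed = 7, epochs = 3, ...) {
  training_config(epochs = epochs, batch_size = 128, seed = seed,
                  latent_dim = 32, hidden_enc = 64, hidden_dec = c(32, 48),
                  hidden_adv = 16, hidden_pred = 16, ...)
}

# flatten a model's trainable parameters for bitwise comparisons
model_params <- function(model, which) {
  p <- spadama:::nn_collect_params(model$nets)
  p[grep(paste0("^(", which, ")\\."), names(p))]
}
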