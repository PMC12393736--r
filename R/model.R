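#' Construct an untrained deconvolution model
#'
#' Five fully connected components share one latent space of even width `d`:
#' \describe{
#'   \item{encoder}{genes -> `hidden_enc` -> BN -> LeakyReLU -> `d` (two
#'     stacked linear layers).}
#'   \item{decoder}{`d` -> 256 -> 512 -> genes, three linear layers mirroring
#'     the encoder style, reconstructing expression from the latent code.}
#'   \item{classifier}{first `d/2` latent columns -> 64 -> 1, sigmoid output;
#'     trained to tell real from pseudo spots.}
#'   \item{discriminator}{remaining `d/2` columns -> 64 -> 1, sigmoid output;
#'     trained with flipped domain labels, the adversarial branch.}
#'   \item{predictor}{full latent -> 64 -> K with BN + LeakyReLU, softmax
#'     output on the cell-type simplex.}
#' }
#'
#' @param n_genes Size of the shared gene panel.
#' @param n_types Number of cell types K.
#' @param latent_dim Even latent width `d` (default 128; halves of `d/2` feed
#'   the classifier and discriminator under the default 1:1 split).
#' @param latent_split Allocation of latent columns between the classifier and
#'   discriminator branches: `"1:1"` (default; the validated choice), `"1:3"`
#'   or `"3:1"`. `latent_dim` must be divisible by the implied denominator.
#' @param hidden_enc Encoder hidden width (default 512).
#' @param hidden_dec Decoder hidden widths (default `c(256, 512)`).
#' @param hidden_adv Classifier/discriminator hidden width (default 64).
#' @param hidden_pred Predictor hidden width (default 64).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param gene_panel,type_names Identifier vectors stamped into the model.
#' @param seed Integer seed for weight initialization.
#' @return A `spadama_model`.
#' @export
spadama_model <- function(n_genes, n_types, latent_dim = 128, hidden_enc = 512,
                          hidden_dec = c(256, 512), hidden_adv = 64,
                          hidden_pred = 64, leaky_slope = 0.01,
                          latent_split = c("1:1", "1:3", "3:1"),
                          gene_panel = NULL, type_names = NULL, seed = 0) {
  latent_split <- match.arg(latent_split)
  stopifnot(latent_dim %% 2 == 0, n_genes >= 1, n_types >= 2)
  ratio <- as.integer(strsplit(latent_split, ":")[[1]])
  if (latent_dim %% sum(ratio) != 0) {
    stop(sprintf("latent_dim must be divisible by %d for a %s split",
                 sum(ratio), latent_split), call. = FALSE)
  }
  split_index <- latent_dim * ratio[1] / sum(ratio)
  set.seed(seed)
  enc <- list(layers = list(nn_linear(n_genes, hidden_enc), nn_bn(hidden_enc),
                            nn_lrelu(leaky_slope), nn_linear(hidden_enc, latent_dim)))
  dec_sizes <- c(latent_dim, hidden_dec, n_genes)
  dec_layers <- list()
  for (i in seq_len(length(dec_sizes) - 1)) {
    dec_layers <- c(dec_layers, list(nn_linear(dec_sizes[i], dec_sizes[i + 1])))
    if (i < length(dec_sizes) - 1) {
      dec_layers <- c(dec_layers, list(nn_bn(dec_sizes[i + 1]), nn_lrelu(leaky_slope)))
    }
  }
  adv <- function(n_in) list(layers = list(nn_linear(n_in, hidden_adv),
                                           nn_lrelu(leaky_slope),
                                           nn_linear(hidden_adv, 1), nn_sigmoid()))
  pred <- list(layers = list(nn_linear(latent_dim, hidden_pred), nn_bn(hidden_pred),
                             nn_lrelu(leaky_slope), nn_linear(hidden_pred, n_types),
                             nn_softmax()))
  structure(list(
    nets = list(encoder = enc, decoder = list(layers = dec_layers),
                classifier = adv(split_index),
                discriminator = adv(latent_dim - split_index),
                predictor = pred),
    latent_dim = latent_dim, split_index = split_index,
    n_genes = n_genes, n_types = n_types, leaky_slope = leaky_slope,
    gene_panel = gene_panel, type_names = type_names, seed = seed),
    class = "spadama_model")
}

#' @export
print.spadama_model <- function(x, ...) {
  cat(sprintf("spadama_model: %d genes -> latent %d -> %d cell types\n",
              x$n_genes, x$latent_dim, x$n_types))
  invisible(x)
}

check_width <- function(X, expected, what) {
  if (ncol(X) != expected) {
    stop(sprintf("%s expects %d input columns, got %d", what, expected, ncol(X)),
         call. = FALSE)
  }
}

#' Encode expression into the latent space
#'
#' @param X Normalized matrix on the model's gene panel.
#' @param model A [spadama_model()].
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch-norm.
#' @return Latent matrix H of shape `nrow(X)` x `latent_dim`. Columns
#'   `1:(d/2)` are the classifier half, the rest the discriminator half.
#' @export
encode <- function(X, model, training = FALSE) {
  check_width(X, model$n_genes, "encoder")
  nn_forward(model$nets$encoder, unclass(X), training = training)$out
}

#' Decode a latent matrix back to expression space
#' @param H Latent matrix of width `latent_dim`.
#' @inheritParams encode
#' @return Reconstruction of shape `nrow(H)` x `n_genes`.
#' @export
decode <- function(H, model, training = FALSE) {
  check_width(H, model$latent_dim, "decoder")
  nn_forward(model$nets$decoder, H, training = training)$out
}

#' Domain probability from the classifier share of the latent code
#' @param H1 First latent block (`split_index` columns wide).
#' @inheritParams encode
#' @return Column vector of probabilities in (0, 1).
#' @export
classify <- function(H1, model, training = FALSE) {
  check_width(H1, model$split_index, "classifier")
  nn_forward(model$nets$classifier, H1, training = training)$out
}

#' Domain probability from the discriminator share of the latent code
#' @param H2 Remaining latent block (`latent_dim - split_index` columns wide).
#' @inheritParams encode
#' @return Column vector of probabilities in (0, 1).
#' @export
discriminate <- function(H2, model, training = FALSE) {
  check_width(H2, model$latent_dim - model$split_index, "discriminator")
  nn_forward(model$nets$discriminator, H2, training = training)$out
}

#' Predict cell-type proportions from the latent code
#' @param H Full latent matrix.
#' @inheritParams encode
#' @return Proportion matrix (rows on the simplex).
#' @export
predict_proportions <- function(H, model, training = FALSE) {
  check_width(H, model$latent_dim, "predictor")
  nn_forward(model$nets$predictor, H, training = training)$out
}

latent_halves <- function(H, model) {
  si <- model$split_index
  list(H1 = H[, seq_len(si), drop = FALSE],
       H2 = H[, (si + 1):ncol(H), drop = FALSE])
}

#' Binary cross-entropy
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]` with predictions clipped to
#' `[eps, 1 - eps]`.
#'
#' @param y Binary target vector.
#' @param y_hat Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return Nonnegative scalar.
#' @export
bce <- function(y, y_hat, eps = 1e-7) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("length mismatch in bce", call. = FALSE)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradient of bce w.r.t. y_hat (pre-clip values inside the clip range)
bce_grad <- function(y, y_hat, eps = 1e-7) {
  p <- pmin(pmax(as.numeric(y_hat), eps), 1 - eps)
  matrix((-(y / p) + (1 - y) / (1 - p)) / length(y), ncol = 1)
}

#' Classifier loss: correct domain labels
#'
#' `bce(real outputs, 1) + bce(pseudo outputs, 0)` — the classifier is
#' rewarded for telling real spots (label 1) from pseudo-spots (label 0).
#'
#' @param O_CR Classifier outputs on real spots.
#' @param O_CS Classifier outputs on pseudo-spots.
#' @return Nonnegative scalar.
#' @export
classifier_loss <- function(O_CR, O_CS) {
  bce(rep(1, length(O_CR)), O_CR) + bce(rep(0, length(O_CS)), O_CS)
}

#' Discriminator loss: flipped domain labels
#'
#' `bce(real outputs, 0) + bce(pseudo outputs, 1)` — the adversarial branch is
#' trained against the true labels, pushing the encoder toward
#' domain-indistinguishable features.
#'
#' @param O_DR Discriminator outputs on real spots.
#' @param O_DS Discriminator outputs on pseudo-spots.
#' @return Nonnegative scalar.
#' @export
discriminator_loss <- function(O_DR, O_DS) {
  bce(rep(0, length(O_DR)), O_DR) + bce(rep(1, length(O_DS)), O_DS)
}

#' Supervised proportion loss
#'
#' Mean over spots of the squared Euclidean distance between predicted and
#' ground-truth proportion rows.
#'
#' @param Y Predicted proportion matrix.
#' @param Y_r Ground-truth proportion matrix.
#' @return Nonnegative scalar.
#' @export
predictor_loss <- function(Y, Y_r) {
  if (!all(dim(Y) == dim(Y_r))) stop("shape mismatch in predictor_loss", call. = FALSE)
  sum((Y - Y_r)^2) / nrow(Y)
}

#' Save a trained model to a checkpoint file
#'
#' The checkpoint stores all parameter tensors together with the gene panel,
#' cell-type names and a configuration hash.
#'
#' @param model A trained [spadama_model()].
#' @param path Output file.
#' @param config_hash Optional hash string stamped into the checkpoint.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, config_hash = NULL) {
  model$config_hash <- config_hash
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file from [save_model()].
#' @param expect_genes Optional gene panel to validate against; loading fails
#'   with the missing genes listed if the panels differ.
#' @return A `spadama_model`.
#' @export
load_model <- function(path, expect_genes = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "spadama_model")) stop("not a model checkpoint", call. = FALSE)
  if (!is.null(expect_genes) && !identical(model$gene_panel, expect_genes)) {
    missing <- setdiff(model$gene_panel, expect_genes)
    stop(sprintf("gene panel mismatch; %d panel genes absent from query: %s",
                 length(missing), paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  model
}
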