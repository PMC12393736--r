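#' Training configuration
#'
#' Defaults follow the published experiment settings: 200 epochs, batch size
#' 2048, learning rate 0.01, masking rate `rho = 0.3` and loss weight
#' `lambda = 0.5`. Network widths are package defaults sized for panels of a
#' few hundred to a few thousand genes.
#'
#' @param epochs Number of passes over the pseudo-spots (default 200).
#' @param batch_size Mini-batch size over pseudo-spots (default 2048). When
#'   the real matrix has fewer spots than `batch_size`, every iteration uses
#'   the full real matrix with a fresh mask.
#' @param learning_rate Adam learning rate for all three sub-steps
#'   (default 0.01).
#' @param rho Masking rate in `[0, 1]` (default 0.3); the mask is resampled
#'   every iteration.
#' @param lambda Weight in `[0, 1]` balancing reconstruction against the
#'   domain losses in sub-step 1 and classifier against discriminator in
#'   sub-step 2 (default 0.5).
#' @param seed Integer seed; the full run is reproducible from it.
#' @param latent_split Allocation of latent columns between classifier and
#'   discriminator: `"1:1"` (default, the validated choice), `"1:3"` or
#'   `"3:1"`.
#' @param adversarial If `FALSE`, the domain branches are disabled: sub-step 1
#'   is pure masked reconstruction and sub-step 2 is skipped (ablation
#'   switch).
#' @param clip_grad Global gradient-norm ceiling per sub-step (default 5);
#'   `NULL` disables clipping.
#' @param latent_dim,hidden_enc,hidden_dec,hidden_adv,hidden_pred Network
#'   widths, passed to [spadama_model()].
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 200, batch_size = 2048, learning_rate = 0.01,
                            rho = 0.3, lambda = 0.5, seed = 0,
                            latent_split = c("1:1", "1:3", "3:1"),
                            adversarial = TRUE, clip_grad = 5,
                            latent_dim = 128, hidden_enc = 512,
                            hidden_dec = c(256, 512), hidden_adv = 64,
                            hidden_pred = 64) {
  latent_split <- match.arg(latent_split)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            rho >= 0, rho <= 1, lambda >= 0, lambda <= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho, lambda = lambda,
                 seed = as.integer(seed), latent_split = latent_split,
                 adversarial = isTRUE(adversarial), clip_grad = clip_grad,
                 latent_dim = latent_dim, hidden_enc = hidden_enc,
                 hidden_dec = hidden_dec, hidden_adv = hidden_adv,
                 hidden_pred = hidden_pred),
            class = "training_config")
}

check_finite_loss <- function(value, stage) {
  if (!is.finite(value)) {
    stop(sprintf("non-finite loss in training sub-step %s", stage), call. = FALSE)
  }
  value
}

#' One training iteration: the three alternating sub-steps
#'
#' Sub-step 1 trains the masked autoencoder: on a freshly masked real batch and
#' a pseudo batch it minimises
#' `lambda * L_MSE + (1 - lambda) * (L_C + L_D)` with respect to the encoder
#' and decoder only. Sub-step 2 recomputes the domain losses with a fresh
#' forward pass and minimises `lambda * L_C + (1 - lambda) * L_D` with respect
#' to the classifier and discriminator only. Sub-step 3 passes the pseudo
#' batch through the encoder and predictor and minimises the proportion loss
#' with respect to the encoder and predictor only. Parameters outside each
#' sub-step's named set are bitwise untouched.
#'
#' @param real Normalized real-spot matrix batch (rows x gene panel).
#' @param pseudo_X Normalized pseudo-spot matrix batch.
#' @param pseudo_Y Matching ground-truth proportion rows.
#' @param model A [spadama_model()].
#' @param config A [training_config()].
#' @param opts List of the three Adam states (created by [train()];
#'   see source for layout).
#' @return List with updated `model`, `opts`, and `record` (named losses).
#' @export
training_iteration <- function(real, pseudo_X, pseudo_Y, model, config, opts) {
  lam <- config$lambda
  Xr <- unclass(real)
  Xs <- unclass(pseudo_X)
  n_r <- nrow(Xr); n_s <- nrow(Xs)
  ones_r <- rep(1, n_r); zeros_r <- rep(0, n_r)
  ones_s <- rep(1, n_s); zeros_s <- rep(0, n_s)

  ## ---- sub-step 1: masked autoencoder (+ domain terms), update enc + dec
  mask <- generate_mask(n_r, ncol(Xr), config$rho)
  Xrm <- Xr * (1 - unclass(mask))
  # batch-norm running statistics track unmasked inputs only: inference runs
  # on the unmasked matrix, and a masked batch (rho of entries zeroed) would
  # bias the running means far from anything the model sees at inference
  fe_r <- nn_forward(model$nets$encoder, Xrm, training = TRUE,
                     update_running = FALSE)
  fe_s <- nn_forward(model$nets$encoder, Xs, training = TRUE)
  model$nets$encoder <- fe_s$net
  fd <- nn_forward(model$nets$decoder, fe_r$out, training = TRUE)
  model$nets$decoder <- fd$net
  nm <- sum(mask)
  L_mse <- masked_mse(fd$out, Xr, mask)

  hr <- latent_halves(fe_r$out, model)
  hs <- latent_halves(fe_s$out, model)
  if (config$adversarial) {
    fc_r <- nn_forward(model$nets$classifier, hr$H1, training = TRUE)
    fc_s <- nn_forward(model$nets$classifier, hs$H1, training = TRUE)
    fd_r <- nn_forward(model$nets$discriminator, hr$H2, training = TRUE)
    fd_s <- nn_forward(model$nets$discriminator, hs$H2, training = TRUE)
    L_c <- classifier_loss(fc_r$out, fc_s$out)
    L_d <- discriminator_loss(fd_r$out, fd_s$out)
  } else {
    L_c <- 0; L_d <- 0
  }
  L_stage1 <- check_finite_loss(lam * L_mse + (1 - lam) * (L_c + L_d), "1")

  dXhat <- if (nm > 0) lam * 2 * (fd$out - Xr) * unclass(mask) / nm else 0 * fd$out
  bd <- nn_backward(model$nets$decoder, fd$caches, dXhat)
  dH_r <- bd$dX
  dH_s <- matrix(0, n_s, model$latent_dim)
  if (config$adversarial) {
    w <- 1 - lam
    b_cr <- nn_backward(model$nets$classifier, fc_r$caches, w * bce_grad(ones_r, fc_r$out))
    b_cs <- nn_backward(model$nets$classifier, fc_s$caches, w * bce_grad(zeros_s, fc_s$out))
    b_dr <- nn_backward(model$nets$discriminator, fd_r$caches, w * bce_grad(zeros_r, fd_r$out))
    b_ds <- nn_backward(model$nets$discriminator, fd_s$caches, w * bce_grad(ones_s, fd_s$out))
    si <- model$split_index
    dH_r[, seq_len(si)] <- dH_r[, seq_len(si)] + b_cr$dX
    dH_r[, (si + 1):model$latent_dim] <- dH_r[, (si + 1):model$latent_dim] + b_dr$dX
    dH_s[, seq_len(si)] <- b_cs$dX
    dH_s[, (si + 1):model$latent_dim] <- b_ds$dX
  }
  be_r <- nn_backward(model$nets$encoder, fe_r$caches, dH_r)
  be_s <- nn_backward(model$nets$encoder, fe_s$caches, dH_s)
  g1 <- grads_add(nn_key_grads("encoder", model$nets$encoder, be_r$grads),
                  nn_key_grads("encoder", model$nets$encoder, be_s$grads))
  g1 <- grads_add(g1, nn_key_grads("decoder", model$nets$decoder, bd$grads))
  st1 <- adam_step(opts$mae, model$nets, g1, config$clip_grad)
  opts$mae <- st1$opt
  model$nets <- st1$nets

  ## ---- sub-step 2: adversarial branches, update classifier + discriminator
  L_stage2 <- NA_real_
  if (config$adversarial) {
    fe_r2 <- nn_forward(model$nets$encoder, Xrm, training = TRUE, update_running = FALSE)
    fe_s2 <- nn_forward(model$nets$encoder, Xs, training = TRUE, update_running = FALSE)
    hr2 <- latent_halves(fe_r2$out, model)
    hs2 <- latent_halves(fe_s2$out, model)
    fc_r2 <- nn_forward(model$nets$classifier, hr2$H1, training = TRUE)
    fc_s2 <- nn_forward(model$nets$classifier, hs2$H1, training = TRUE)
    fd_r2 <- nn_forward(model$nets$discriminator, hr2$H2, training = TRUE)
    fd_s2 <- nn_forward(model$nets$discriminator, hs2$H2, training = TRUE)
    L_c2 <- classifier_loss(fc_r2$out, fc_s2$out)
    L_d2 <- discriminator_loss(fd_r2$out, fd_s2$out)
    L_stage2 <- check_finite_loss(lam * L_c2 + (1 - lam) * L_d2, "2")
    g2 <- grads_add(
      nn_key_grads("classifier", model$nets$classifier,
                   nn_backward(model$nets$classifier, fc_r2$caches,
                               lam * bce_grad(ones_r, fc_r2$out))$grads),
      nn_key_grads("classifier", model$nets$classifier,
                   nn_backward(model$nets$classifier, fc_s2$caches,
                               lam * bce_grad(zeros_s, fc_s2$out))$grads))
    g2 <- grads_add(g2,
      nn_key_grads("discriminator", model$nets$discriminator,
                   nn_backward(model$nets$discriminator, fd_r2$caches,
                               (1 - lam) * bce_grad(zeros_r, fd_r2$out))$grads))
    g2 <- grads_add(g2,
      nn_key_grads("discriminator", model$nets$discriminator,
                   nn_backward(model$nets$discriminator, fd_s2$caches,
                               (1 - lam) * bce_grad(ones_s, fd_s2$out))$grads))
    st2 <- adam_step(opts$adv, model$nets, g2, config$clip_grad)
    opts$adv <- st2$opt
    model$nets <- st2$nets
  }

  ## ---- sub-step 3: supervised proportions, update encoder + predictor
  fe_s3 <- nn_forward(model$nets$encoder, Xs, training = TRUE)
  model$nets$encoder <- fe_s3$net
  fp <- nn_forward(model$nets$predictor, fe_s3$out, training = TRUE)
  model$nets$predictor <- fp$net
  L_p <- check_finite_loss(predictor_loss(fp$out, pseudo_Y), "3")
  dY <- 2 * (fp$out - pseudo_Y) / n_s
  bp <- nn_backward(model$nets$predictor, fp$caches, dY)
  be3 <- nn_backward(model$nets$encoder, fe_s3$caches, bp$dX)
  g3 <- grads_add(nn_key_grads("encoder", model$nets$encoder, be3$grads),
                  nn_key_grads("predictor", model$nets$predictor, bp$grads))
  st3 <- adam_step(opts$sup, model$nets, g3, config$clip_grad)
  opts$sup <- st3$opt
  model$nets <- st3$nets

  list(model = model, opts = opts,
       record = c(L_stage1 = L_stage1, L_MSE = L_mse, L_C = L_c, L_D = L_d,
                  L_stage2 = L_stage2, L_P = L_p))
}

#' Train the deconvolution model
#'
#' Alternates the three sub-steps of [training_iteration()] over
#' `config$epochs` passes through the shuffled pseudo-spots. Each mini-batch
#' of pseudo-spots is paired with a real-spot batch (the full real matrix when
#' it is smaller than `batch_size`, a fresh random subset otherwise) carrying
#' a freshly sampled mask. The run is reproducible from `config$seed`.
#'
#' @param st Normalized real-spot [expression_matrix()] on the shared gene
#'   panel.
#' @param pseudo A `pseudo_spot_batch` from [generate_pseudo_spots()] on the
#'   same panel.
#' @param config A [training_config()].
#' @return List with `model` (trained [spadama_model()]) and `trace`
#'   (data.frame: epoch, iteration, L_stage1, L_MSE, L_C, L_D, L_stage2, L_P).
#' @export
train <- function(st, pseudo, config = training_config()) {
  stopifnot(inherits(st, "expression_matrix"), inherits(pseudo, "pseudo_spot_batch"),
            inherits(config, "training_config"))
  if (!identical(colnames(st), colnames(pseudo$X_S))) {
    stop("st and pseudo must share one gene panel (same genes, same order)",
         call. = FALSE)
  }
  n_s <- nrow(pseudo$X_S)
  n_r <- nrow(st)
  if (n_s < 1 || n_r < 1) stop("empty input", call. = FALSE)
  set.seed(config$seed)
  model <- spadama_model(n_genes = ncol(st), n_types = length(pseudo$type_names),
                         latent_dim = config$latent_dim,
                         hidden_enc = config$hidden_enc,
                         hidden_dec = config$hidden_dec,
                         hidden_adv = config$hidden_adv,
                         hidden_pred = config$hidden_pred,
                         latent_split = config$latent_split,
                         gene_panel = colnames(st),
                         type_names = pseudo$type_names,
                         seed = config$seed)
  params <- nn_collect_params(model$nets)
  pick <- function(which) params[grep(paste0("^(", which, ")\\."), names(params))]
  opts <- list(mae = adam_init(pick("encoder|decoder"), lr = config$learning_rate),
               adv = adam_init(pick("classifier|discriminator"), lr = config$learning_rate),
               sup = adam_init(pick("encoder|predictor"), lr = config$learning_rate))
  bs <- min(config$batch_size, n_s)
  Xr_all <- unclass(st)
  trace <- list()
  row_i <- 0
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n_s)
    starts <- seq(1, n_s, by = bs)
    for (it in seq_along(starts)) {
      idx <- perm[starts[it]:min(starts[it] + bs - 1, n_s)]
      ridx <- if (n_r <= config$batch_size) seq_len(n_r)
              else sample.int(n_r, config$batch_size)
      step <- training_iteration(Xr_all[ridx, , drop = FALSE],
                                 unclass(pseudo$X_S)[idx, , drop = FALSE],
                                 pseudo$Y_r[idx, , drop = FALSE],
                                 model, config, opts)
      model <- step$model
      opts <- step$opts
      row_i <- row_i + 1
      trace[[row_i]] <- c(epoch = epoch, iteration = it, step$record)
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))
  list(model = model, trace = trace)
}

#' Infer cell-type proportions for real spots
#'
#' Runs the trained encoder and predictor in inference mode (running
#' batch-norm statistics, no masking) on the normalized real matrix.
#'
#' @param st Normalized [expression_matrix()] on the model's gene panel.
#' @param model A trained [spadama_model()].
#' @return Proportion matrix (spots x cell types), rows on the simplex, with
#'   spot and type names.
#' @export
infer <- function(st, model) {
  if (!is.null(model$gene_panel) && !identical(colnames(st), model$gene_panel)) {
    missing <- setdiff(model$gene_panel, colnames(st))
    stop(sprintf("gene panel mismatch; missing from query: %s",
                 paste(utils::head(missing, 10), collapse = ", ")), call. = FALSE)
  }
  H <- encode(st, model, training = FALSE)
  Y <- predict_proportions(H, model, training = FALSE)
  dimnames(Y) <- list(rownames(st), model$type_names)
  Y
}
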