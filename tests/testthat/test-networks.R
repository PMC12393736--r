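toy_model <- function(seed = 1) {
  spadama_model(n_genes = 4, n_types = 3, latent_dim = 8, hidden_enc = 6,
                hidden_dec = c(5, 7), hidden_adv = 4, hidden_pred = 4,
                seed = seed)
}

test_that("component shapes and inference-mode determinism", {
  m <- toy_model()
  X <- matrix(abs(rnorm(12)), 3, 4)
  H <- encode(X, m)
  expect_equal(dim(H), c(3, 8))
  expect_identical(H, encode(X, m))
  Xh <- decode(H, m)
  expect_equal(dim(Xh), c(3, 4))
  expect_identical(Xh, decode(H, m))
  h <- H[, 1:4, drop = FALSE]
  p <- classify(h, m)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, classify(h, m))
  q <- discriminate(H[, 5:8, drop = FALSE], m)
  expect_true(all(q > 0 & q < 1))
  Y <- predict_proportions(H, m)
  expect_equal(dim(Y), c(3, 3))
  expect_equal(rowSums(Y), rep(1, 3), tolerance = 1e-6)
  expect_true(all(Y >= 0))
  expect_error(encode(matrix(1, 2, 5), m), "4 input columns")
  expect_error(decode(matrix(1, 2, 7), m), "8 input columns")
  expect_error(classify(H, m), "4 input columns")
})

test_that("zero-parameter classifier outputs exactly 0.5", {
  m <- toy_model()
  for (i in seq_along(m$nets$classifier$layers)) {
    ly <- m$nets$classifier$layers[[i]]
    if (ly$type == "linear") {
      m$nets$classifier$layers[[i]]$W <- ly$W * 0
      m$nets$classifier$layers[[i]]$b <- ly$b * 0
    }
  }
  expect_equal(as.numeric(classify(matrix(rnorm(8), 2, 4), m)), c(0.5, 0.5))
})

test_that("softmax head is shift-invariant and uniform at zero logits", {
  m <- toy_model()
  # zero the final predictor linear layer -> zero logits -> uniform rows
  n <- length(m$nets$predictor$layers)
  li_ <- NULL
  for (i in seq_len(n)) {
    if (m$nets$predictor$layers[[i]]$type == "linear") li_ <- i
  }
  m$nets$predictor$layers[[li_]]$W <- m$nets$predictor$layers[[li_]]$W * 0
  m$nets$predictor$layers[[li_]]$b <- m$nets$predictor$layers[[li_]]$b * 0
  Y <- predict_proportions(matrix(rnorm(16), 2, 8), m)
  expect_equal(Y, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  # shifting all logits of a row leaves softmax unchanged
  m2 <- toy_model()
  m2$nets$predictor$layers[[li_]]$b <- m2$nets$predictor$layers[[li_]]$b + 5
  m1 <- toy_model()
  H <- matrix(rnorm(16), 2, 8)
  expect_equal(predict_proportions(H, m1), predict_proportions(H, m2),
               tolerance = 1e-9)
})

test_that("encoder and branch gradients match central finite differences", {
  set.seed(3)
  m <- toy_model(3)
  X <- matrix(abs(rnorm(12)), 3, 4)
  Tgt <- matrix(rnorm(24), 3, 8)
  loss_enc <- function(model) {
    H <- spadama:::nn_forward(model$nets$encoder, X, training = TRUE,
                              update_running = FALSE)$out
    sum((H - Tgt)^2)
  }
  fw <- spadama:::nn_forward(m$nets$encoder, X, training = TRUE, update_running = FALSE)
  bk <- spadama:::nn_backward(m$nets$encoder, fw$caches, 2 * (fw$out - Tgt))
  W0 <- m$nets$encoder$layers[[1]]$W
  eps <- 1e-5
  idx <- cbind(c(1, 2, 4), c(1, 3, 6))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    mp <- m; mp$nets$encoder$layers[[1]]$W[i, j] <- W0[i, j] + eps
    mm <- m; mm$nets$encoder$layers[[1]]$W[i, j] <- W0[i, j] - eps
    numeric_grad <- (loss_enc(mp) - loss_enc(mm)) / (2 * eps)
    expect_equal(bk$grads[[1]]$W[i, j], numeric_grad, tolerance = 1e-4)
  }

  # classifier gradient vs finite differences through sigmoid + bce
  h <- matrix(rnorm(8), 2, 4)
  y <- c(1, 0)
  loss_cls <- function(model) {
    bce(y, spadama:::nn_forward(model$nets$classifier, h)$out)
  }
  fc <- spadama:::nn_forward(m$nets$classifier, h)
  bc <- spadama:::nn_backward(m$nets$classifier, fc$caches,
                              spadama:::bce_grad(y, fc$out))
  Wc <- m$nets$classifier$layers[[1]]$W
  mp <- m; mp$nets$classifier$layers[[1]]$W[2, 3] <- Wc[2, 3] + eps
  mm <- m; mm$nets$classifier$layers[[1]]$W[2, 3] <- Wc[2, 3] - eps
  expect_equal(bc$grads[[1]]$W[2, 3], (loss_cls(mp) - loss_cls(mm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("encode-decode is row-permutation equivariant", {
  m <- toy_model(4)
  X <- matrix(abs(rnorm(16)), 4, 4)
  perm <- c(3, 1, 4, 2)
  out1 <- decode(encode(X, m), m)
  out2 <- decode(encode(X[perm, ], m), m)
  expect_equal(out2, out1[perm, ], tolerance = 1e-12)
})

test_that("bce closed forms and symmetry", {
  eps <- 1e-7
  expect_equal(bce(1, 1 - eps), -log(1 - eps), tolerance = 1e-12)
  expect_lt(bce(1, 1 - eps), 1e-6)
  expect_equal(bce(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(8)
  y <- rbinom(10, 1, 0.5)
  p <- runif(10)
  expect_equal(bce(y, p), bce(1 - y, 1 - p), tolerance = 1e-12)
  expect_error(bce(c(1, 0), 0.5), "length")
})

test_that("classifier and discriminator losses follow their label conventions", {
  half <- rep(0.5, 4)
  expect_equal(classifier_loss(half, half), 2 * log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(half, half), 2 * log(2), tolerance = 1e-12)
  eps <- 1e-7
  good_r <- rep(1 - eps, 4); good_s <- rep(eps, 4)
  expect_lt(classifier_loss(good_r, good_s), 1e-5)
  expect_gt(discriminator_loss(good_r, good_s), 10)
  # swapping the label assignment turns one loss into the other
  set.seed(2)
  or <- runif(5); os <- runif(5)
  expect_equal(classifier_loss(or, os), discriminator_loss(os, or), tolerance = 1e-12)
})

test_that("predictor loss closed forms and simplex bound", {
  Y <- matrix(c(1, 0), 1, 2)
  Yr <- matrix(c(0, 1), 1, 2)
  expect_equal(predictor_loss(Y, Yr), 2)
  expect_equal(predictor_loss(Yr, Yr), 0)
  set.seed(13)
  A <- random_simplex(50, 4)
  B <- random_simplex(50, 4)
  per_row <- rowSums((A - B)^2)
  expect_true(all(per_row <= 2 + 1e-12))
  expect_error(predictor_loss(A, B[1:10, ]), "shape")
})
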