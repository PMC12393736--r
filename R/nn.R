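# Minimal dense-network engine: linear / batch-norm / LeakyReLU / sigmoid /
# softmax layers with explicit forward caching and hand-derived backward
# passes, plus Adam. Written for the small fully connected components this
# model needs (hundreds of units, thousands of rows); all heavy lifting is
# BLAS matrix multiplication. Everything is deterministic given R's RNG state.

nn_linear <- function(n_in, n_out) {
  # Kaiming-style uniform fan-in init
  bound <- sqrt(6 / n_in)
  W <- matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
  b <- matrix(stats::runif(n_out, -1 / sqrt(n_in), 1 / sqrt(n_in)), 1, n_out)
  list(type = "linear", W = W, b = b)
}

nn_bn <- function(n, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, n), beta = rep(0, n),
       running_mean = rep(0, n), running_var = rep(1, n),
       momentum = momentum, eps = eps)
}

nn_lrelu <- function(slope = 0.01) list(type = "lrelu", slope = slope)
nn_sigmoid <- function() list(type = "sigmoid")
nn_softmax <- function() list(type = "softmax")

# forward pass; returns list(out, caches). training = TRUE uses batch
# statistics in batch-norm layers; update_running additionally refreshes the
# running statistics (kept FALSE when the owning component is frozen).
nn_forward <- function(net, X, training = FALSE, update_running = training) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      caches[[i]] <- list(X = X)
      X <- X %*% ly$W + matrix(ly$b, nrow(X), length(ly$b), byrow = TRUE)
    } else if (ly$type == "bn") {
      if (training) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        if (update_running) {
          net$layers[[i]]$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
          net$layers[[i]]$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
        }
      } else {
        mu <- ly$running_mean
        v <- ly$running_var
      }
      std <- sqrt(v + ly$eps)
      centered <- sweep(X, 2, mu)
      xhat <- sweep(centered, 2, std, "/")
      caches[[i]] <- list(xhat = xhat, std = std, centered = centered,
                          training = training)
      X <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else if (ly$type == "lrelu") {
      caches[[i]] <- list(pos = X > 0)
      X <- ifelse(X > 0, X, ly$slope * X)
    } else if (ly$type == "sigmoid") {
      X <- 1 / (1 + exp(-X))
      caches[[i]] <- list(out = X)
    } else if (ly$type == "softmax") {
      Xs <- X - apply(X, 1, max)
      e <- exp(Xs)
      X <- e / rowSums(e)
      caches[[i]] <- list(out = X)
    }
  }
  list(out = X, caches = caches, net = net)
}

# backward pass; returns list(grads, dX). grads[[i]] mirrors layer i's
# parameter tensors (NULL for parameter-free layers).
nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dX <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "linear") {
      grads[[i]] <- list(W = crossprod(ch$X, dX), b = matrix(colSums(dX), 1))
      dX <- tcrossprod(dX, ly$W)
    } else if (ly$type == "bn") {
      dgamma <- colSums(dX * ch$xhat)
      dbeta <- colSums(dX)
      dxhat <- sweep(dX, 2, ly$gamma, "*")
      if (ch$training) {
        N <- nrow(dX)
        dvar <- colSums(dxhat * ch$centered) * (-0.5) / ch$std^3
        dmu <- colSums(sweep(dxhat, 2, -1 / ch$std, "*")) +
          dvar * colMeans(-2 * ch$centered)
        dX <- sweep(dxhat, 2, ch$std, "/") +
          sweep(ch$centered, 2, 2 * dvar / N, "*") +
          matrix(dmu / N, N, length(dmu), byrow = TRUE)
      } else {
        dX <- sweep(dxhat, 2, ch$std, "/")
      }
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$type == "lrelu") {
      dX <- dX * ifelse(ch$pos, 1, ly$slope)
    } else if (ly$type == "sigmoid") {
      dX <- dX * ch$out * (1 - ch$out)
    } else if (ly$type == "softmax") {
      dX <- ch$out * (dX - rowSums(dX * ch$out))
    }
  }
  list(grads = grads, dX = dX)
}

nn_param_names <- c(linear = "W b", bn = "gamma beta")

# flatten trainable parameters of a named list of nets into one list
nn_collect_params <- function(nets) {
  out <- list()
  for (nm in names(nets)) {
    for (i in seq_along(nets[[nm]]$layers)) {
      ly <- nets[[nm]]$layers[[i]]
      pn <- nn_param_names[ly$type]
      if (is.na(pn)) next
      for (p in strsplit(pn, " ")[[1]]) {
        out[[paste(nm, i, p, sep = ".")]] <- ly[[p]]
      }
    }
  }
  out
}

nn_zero_like <- function(params) lapply(params, function(p) p * 0)

# Adam optimizer over a fixed parameter-key set
adam_init <- function(params, lr = 0.01, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = nn_zero_like(params), v = nn_zero_like(params))
}

# applies one Adam step to the nets named in `grads` (same key scheme as
# nn_collect_params); optional global-norm gradient clipping
adam_step <- function(opt, nets, grads, clip_norm = NULL) {
  if (!is.null(clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(gn) && gn > clip_norm) {
      grads <- lapply(grads, function(g) g * (clip_norm / gn))
    }
  }
  opt$t <- opt$t + 1
  for (key in names(grads)) {
    g <- grads[[key]]
    opt$m[[key]] <- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
    opt$v[[key]] <- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[key]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[key]] / (1 - opt$beta2^opt$t)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    nm <- parts[1]; i <- as.integer(parts[2]); p <- parts[3]
    old <- nets[[nm]]$layers[[i]][[p]]
    new <- old - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    dimnames(new) <- dimnames(old)
    names(new) <- names(old)
    nets[[nm]]$layers[[i]][[p]] <- new
  }
  list(opt = opt, nets = nets)
}

# grads keyed like nn_collect_params from a single net's nn_backward output
nn_key_grads <- function(name, net, grads) {
  out <- list()
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      out[[paste(name, i, p, sep = ".")]] <- grads[[i]][[p]]
    }
  }
  out
}

# elementwise addition of two keyed grad lists (union of keys)
grads_add <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.null(a[[k]])) b[[k]] else a[[k]] + b[[k]]
  }
  a
}
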