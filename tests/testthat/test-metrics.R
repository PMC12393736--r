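test_that("pcc endpoints and agreement with the direct covariance formula", {
  x <- c(0.1, 0.2, 0.7)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x + 1), -1)
  xh <- c(0.2, 0.2, 0.6)
  expect_equal(pcc(x, xh), brute_pcc(x, xh), tolerance = 1e-12)
  expect_warning(v <- pcc(c(1, 1, 1), x), "constant")
  expect_true(is.na(v))
})

test_that("ssim endpoints, constants, and oracle agreement", {
  x <- c(0.1, 0.5, 0.4, 0.9)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  # defaults are the published stabilizing constants
  expect_identical(formals(ssim)$C1, 0.01)
  expect_identical(formals(ssim)$C2, 0.03)
  set.seed(4)
  for (i in 1:25) {
    a <- runif(8); b <- runif(8)
    expect_equal(ssim(a, b), brute_ssim(a, b), tolerance = 1e-12)
    expect_lte(ssim(a, b), 1 + 1e-12)
  }
})

test_that("rmse closed forms and positive-scale equivariance", {
  expect_equal(rmse(c(0, 1), c(0, 1)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  set.seed(5)
  x <- runif(10); y <- runif(10)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)
})

test_that("js is a symmetric base-2 divergence in [0, 1]", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js(p, p), 0)
  expect_equal(js(c(1, 0), c(0, 1)), 1)  # disjoint supports hit the base-2 max
  set.seed(6)
  for (i in 1:25) {
    a <- rexp(6); b <- rexp(6)
    expect_equal(js(a, b), js(b, a), tolerance = 1e-12)
    expect_equal(js(a, b), brute_js(a, b), tolerance = 1e-12)
    expect_gte(js(a, b), 0)
    expect_lte(js(a, b), 1)
  }
  expect_error(js(c(0, 0), c(1, 1)), "zero")
})

test_that("accuracy score rewards dominance and splits ties", {
  mm <- data.frame(method = c("best", "mid", "worst"),
                   pcc = c(0.9, 0.8, 0.2), ssim = c(0.9, 0.7, 0.3),
                   rmse = c(0.05, 0.1, 0.4), js = c(0.1, 0.2, 0.6))
  as_ <- accuracy_score(mm)
  expect_equal(unname(as_["best"]), 1)
  expect_equal(unname(as_["worst"]), 1 / 3)
  # two methods, all metrics tied -> both (1 + 2)/2 / 2 = 0.75
  tied <- data.frame(method = c("a", "b"), pcc = c(0.5, 0.5), ssim = c(0.5, 0.5),
                     rmse = c(0.1, 0.1), js = c(0.2, 0.2))
  expect_equal(unname(accuracy_score(tied)), c(0.75, 0.75))
  # invariant to method order
  expect_equal(sort(accuracy_score(mm[c(3, 1, 2), ])), sort(as_))
  expect_error(accuracy_score(mm[, -2]), "pcc")
  mm$js[2] <- NA
  expect_error(accuracy_score(mm), "mid")
})

test_that("region AUC follows the Mann-Whitney rank formulation with ties", {
  expect_equal(region_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(region_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(region_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  set.seed(7)
  for (i in 1:20) {
    s <- round(runif(12), 1)  # rounded scores force ties
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(region_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(region_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("cell-type correlation matrix is symmetric with unit diagonal", {
  set.seed(8)
  Y <- random_simplex(30, 4)
  colnames(Y) <- paste0("t", 1:4)
  R <- celltype_correlation(Y)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  # brute-force transcription of the pairwise correlation formula
  for (i in 1:4) for (j in 1:4) {
    expect_equal(R[i, j], brute_pcc(Y[, i], Y[, j]), tolerance = 1e-12)
  }
  Yc <- cbind(Y[, 1:2], const = 0.25)
  expect_warning(Rc <- celltype_correlation(Yc), "const")
  expect_true(all(is.na(Rc["const", ])))
})

test_that("metric outputs stay in range on random simplex matrices", {
  set.seed(9)
  for (rep in 1:50) {
    truth <- random_simplex(20, 5)
    pred <- random_simplex(20, 5)
    colnames(truth) <- colnames(pred) <- paste0("t", 1:5)
    ev <- evaluate_deconvolution(truth, pred)
    ok <- stats::complete.cases(ev$per_type[, c("pcc", "ssim", "rmse", "js")])
    expect_true(all(abs(ev$per_type$pcc[ok]) <= 1 + 1e-12))
    expect_true(all(ev$per_type$ssim <= 1 + 1e-12))
    expect_true(all(ev$per_type$rmse >= 0))
    expect_true(all(ev$per_type$js >= 0 & ev$per_type$js <= 1))
  }
})

test_that("pcc is affine-invariant but ssim is not scale-invariant pre-scaling", {
  set.seed(10)
  x <- runif(15); y <- runif(15)
  expect_equal(pcc(2 * x + 1, y), pcc(x, y), tolerance = 1e-12)
  # min-max scaling inside ssim makes common positive rescaling a no-op,
  # but a shift of one vector changes nothing only when ranges align
  expect_equal(ssim(2 * x, 2 * y), ssim(x, y), tolerance = 1e-12)
})
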