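test_that("fit_ols reproduces exact and oracle-checked fits", {
  # perfect fit (summary.lm warns about it; the statistics are still exact)
  x <- matrix(1:10, dimnames = list(NULL, "x"))
  m <- suppressWarnings(fit_ols(x, as.numeric(1:10)))
  expect_equal(unname(m$B), 1)
  expect_equal(unname(m$beta), 1)
  expect_equal(m$R2, 1)

  # random design vs normal-equations oracle
  set.seed(17)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(10)
  m <- fit_ols(X, y)
  oracle <- ne_ols(X, y)
  expect_equal(unname(c(m$intercept, m$B)), unname(oracle),
               tolerance = 1e-8)

  # exact collinearity is refused
  X2 <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(X2, y), "singular")
})

test_that("model statistics satisfy their defining identities", {
  set.seed(23)
  for (k in 1:3) {
    n <- 25
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("x", 1:k)))
    y <- rowSums(X) + rnorm(n)
    m <- fit_ols(X, y)
    expect_equal(m$adj_R2, 1 - (1 - m$R2) * (n - 1) / (n - k - 1),
                 tolerance = 1e-10)
    expect_equal(m$F, (m$R2 / k) / ((1 - m$R2) / (n - k - 1)),
                 tolerance = 1e-10)
    expect_true(all(m$VIF >= 1))
    expect_true(all(diff(m$CI) >= 0) && all(m$CI >= 1))
    expect_length(m$CI, k + 1)
  }
})

test_that("vif matches its closed form and flags collinearity", {
  # orthogonal columns
  X <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(vif(X)), c(1, 1))
  # sample correlation exactly 0.6: VIF = 1/(1 - 0.36) = 1.5625
  Xr <- make_correlated_pair(30, 0.6)
  expect_equal(unname(vif(Xr)), rep(1 / (1 - 0.36), 2), tolerance = 1e-10)
  # single column: exactly 1
  expect_equal(unname(vif(Xr[, 1, drop = FALSE])), 1)
  # exact collinearity: infinite, not an error
  Xc <- cbind(a = 1:10, b = 2 * (1:10))
  expect_true(all(is.infinite(vif(Xc))))
  # agreement with the standard implementation on a random design
  set.seed(3)
  X3 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  fit <- lm(y ~ a + b + c, data = data.frame(X3, y = y))
  expect_equal(unname(vif(X3)), unname(car::vif(fit)), tolerance = 1e-10)
})

test_that("condition indices follow the scaled-uncentered-SVD convention", {
  set.seed(29)
  X <- matrix(rnorm(60), 20, 3)
  ci <- condition_indices(X)
  # independent oracle: direct SVD of the unit-scaled design
  Xd <- cbind(1, X)
  Xs <- sweep(Xd, 2, sqrt(colSums(Xd^2)), "/")
  sv <- svd(Xs)$d
  expect_equal(ci, sort(max(sv) / sv), tolerance = 1e-8)
  expect_equal(ci[1], 1)

  # duplicated predictor: rank deficiency shows as a huge index
  Xdup <- cbind(X[, 1], X[, 1])
  expect_gt(max(condition_indices(Xdup)), 1e6)

  expect_error(condition_indices(cbind(rep(0, 5))), "zero column")
})

test_that("coefficients are scale-equivariant and diagnostics scale-free", {
  set.seed(41)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5) + rnorm(20)
  m1 <- fit_ols(X, y)
  Xs <- X; Xs[, 2] <- X[, 2] * 100
  m2 <- fit_ols(Xs, y)
  expect_equal(m2$B[["b"]], m1$B[["b"]] / 100, tolerance = 1e-10)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-10)
  expect_equal(m2$R2, m1$R2, tolerance = 1e-12)
  expect_equal(m2$F, m1$F, tolerance = 1e-10)
  expect_equal(m2$VIF, m1$VIF, tolerance = 1e-10)
  expect_equal(m2$CI, m1$CI, tolerance = 1e-8)  # CI on unit-scaled columns
})

test_that("stepwise selection enters by partial p and removes weak predictors", {
  set.seed(53)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n); noise <- matrix(rnorm(3 * n), n, 3)
  X <- cbind(s1 = x1, s2 = x2, n1 = noise[, 1], n2 = noise[, 2],
             n3 = noise[, 3])
  y <- 2 * x1 - 1.5 * x2 + rnorm(n)
  res <- stepwise_regression(X, y)
  expect_setequal(res$final$predictors, c("s1", "s2"))
  # path grows one predictor per accepted forward step
  sizes <- vapply(res$path, function(m) length(m$predictors), 0L)
  expect_true(all(abs(diff(c(0L, sizes))) == 1L))

  # nothing enters on pure noise with a strict threshold
  res0 <- stepwise_regression(noise, rnorm(n), p_enter = 1e-6,
                              p_remove = 1e-5)
  expect_length(res0$path, 0)
  expect_length(res0$final$predictors, 0)
})

test_that("first-entry behaviour matches the correlation-test oracle on noise", {
  set.seed(67)
  hits_step <- hits_oracle <- logical(120)
  for (r in seq_along(hits_step)) {
    X <- matrix(rnorm(32 * 5), 32, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- rnorm(32)
    res <- stepwise_regression(X, y)
    hits_step[r] <- length(res$path) > 0
    # oracle: with no included predictors, entry happens iff the smallest
    # simple-correlation p-value beats the threshold
    pmin_ <- min(vapply(1:5, function(j) cor.test(X[, j], y)$p.value, 0))
    hits_oracle[r] <- pmin_ < 0.05
  }
  expect_identical(hits_step, hits_oracle)
  # rate is near the multiplicity-inflated alpha, 1 - 0.95^5 ~ 0.23
  expect_gt(mean(hits_step), 0.08)
  expect_lt(mean(hits_step), 0.40)
})

test_that("select_final adopts the largest screened model", {
  set.seed(71)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(a = x1, b = x2)
  y <- x1 + x2 + rnorm(n, sd = 0.5)
  res <- stepwise_regression(X, y)
  expect_equal(length(select_final(res)$predictors), 2)

  # a collinear pair: the two-predictor model fails the VIF screen, the
  # one-predictor model is adopted instead
  Xc <- make_correlated_pair(n, 0.95)
  colnames(Xc) <- c("a", "b")
  yc <- Xc[, 1] + 0.8 * Xc[, 2] + rnorm(n, sd = 0.4)
  resc <- stepwise_regression(Xc, yc)
  if (length(resc$path) > 1) {
    fin <- select_final(resc, vif_limit = 2, ci_limit = 20)
    expect_equal(length(fin$predictors), 1)
  }
  # impossible screens give a named error
  expect_error(select_final(res, vif_limit = 1, ci_limit = 1), "screens")
  expect_error(select_final(list(path = list())), "empty")
})
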