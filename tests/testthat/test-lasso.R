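test_that("soft threshold follows its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-2.5, 1.5), -1)
  expect_equal(soft_threshold(c(-3, 0, 3), 0), c(-3, 0, 3))
  expect_error(soft_threshold(1, -0.1), "lambda")
})

test_that("lambda path is geometric with the requested endpoints", {
  expect_equal(lambda_path(2, 1), 2)
  expect_equal(lambda_path(2, 3, 0.01), c(2, 0.2, 0.02), tolerance = 1e-12)
  expect_true(all(diff(lambda_path(1, 30, 0.05)) < 0))
  expect_warning(p <- lambda_path(0, 10), "degenerate")
  expect_equal(p, 0)
})

test_that("above lambda_max everything is zero and the intercept is the weighted mean", {
  set.seed(2)
  n <- 60
  X <- cbind(1, matrix(rnorm(n * 5), n))
  z <- rnorm(n, sd = 2)
  w <- runif(n, 0.5, 2)
  wn <- w / mean(w)
  zbar <- sum(wn * z) / sum(wn)
  lmax <- max(abs(crossprod(X[, -1], wn * (z - zbar)))) / n
  fit <- weighted_lasso(X, z, w, lambda = lmax * 1.0001,
                        penalty_factor = c(0, rep(1, 5)))
  expect_equal(fit$beta[-1], rep(0, 5))
  expect_equal(fit$beta[1], zbar, tolerance = 1e-8)
  # just below lambda_max at least one coefficient enters
  fit2 <- weighted_lasso(X, z, w, lambda = lmax * 0.98,
                         penalty_factor = c(0, rep(1, 5)))
  expect_gt(sum(fit2$beta[-1] != 0), 0)
})

test_that("lambda = 0 reproduces the weighted least-squares oracle", {
  set.seed(4)
  n <- 50
  X <- cbind(1, matrix(rnorm(n * 3), n))
  z <- X %*% c(1, 2, -1, 0.5) + rnorm(n)
  w <- runif(n, 0.2, 3)
  fit <- weighted_lasso(X, z, w, lambda = 0,
                        penalty_factor = c(0, 1, 1, 1))
  expect_equal(fit$beta, as.vector(wls_oracle(X, z, w)), tolerance = 1e-6)
})

test_that("orthonormal designs give the soft-threshold closed form", {
  set.seed(5)
  n <- 80
  A <- matrix(rnorm(n * 2), n)
  Q <- qr.Q(qr(A)) * sqrt(n)   # columns orthonormal under (1/n) X'X
  z <- rnorm(n, sd = 1.5)
  for (lam in c(0.05, 0.2, 1)) {
    fit <- weighted_lasso(Q, z, lambda = lam)
    rho <- crossprod(Q, z) / n
    expect_equal(fit$beta, as.vector(soft_threshold(rho, lam)),
                 tolerance = 1e-6)
  }
})

test_that("KKT conditions hold at every reported solution", {
  set.seed(6)
  n <- 60; p <- 12
  X <- cbind(1, matrix(rnorm(n * p), n))
  z <- rnorm(n)
  w <- runif(n, 0.5, 2)
  pfac <- c(0, rep(1, p))
  for (lam in c(0.02, 0.1, 0.4)) {
    beta <- weighted_lasso(X, z, w, lam, penalty_factor = pfac)$beta
    g <- lasso_gradient(X, z, w, beta)
    active <- beta != 0
    expect_true(all(abs(g[active] + lam * pfac[active] * sign(beta[active]))
                    < 1e-6))
    expect_true(all(abs(g[!active]) <= lam * pfac[!active] + 1e-6))
  }
})

test_that("the solution is invariant to column order", {
  set.seed(7)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n)
  z <- X[, 1] * 2 + rnorm(n)
  perm <- sample(p)
  b1 <- weighted_lasso(X, z, lambda = 0.1)$beta
  b2 <- weighted_lasso(X[, perm], z, lambda = 0.1)$beta
  expect_equal(b2[order(perm)], b1, tolerance = 1e-8)
})

test_that("warm starts along the path match cold starts", {
  set.seed(8)
  n <- 50; p <- 20
  X <- cbind(1, matrix(rnorm(n * p), n))
  z <- X[, 2:4] %*% c(2, -1.5, 1) + rnorm(n)
  pfac <- c(0, rep(1, p))
  lams <- lambda_path(max(abs(crossprod(X[, -1], z - mean(z)))) / n, 8, 0.05)
  warm <- rep(0, p + 1)
  for (lam in lams) {
    warm <- weighted_lasso(X, z, lambda = lam, penalty_factor = pfac,
                           beta_init = warm)$beta
    cold <- weighted_lasso(X, z, lambda = lam, penalty_factor = pfac)$beta
    expect_equal(warm, cold, tolerance = 1e-6)
  }
  # sparsity grows from the top to the bottom of the path
  nz_top <- sum(weighted_lasso(X, z, lambda = lams[1],
                               penalty_factor = pfac)$beta[-1] != 0)
  expect_gte(sum(warm[-1] != 0), nz_top)
})

test_that("the penalized fit matches glmnet where objectives coincide", {
  skip_if_not_installed("glmnet")
  # gaussian/identity: both minimize (1/2n) RSS + lambda * ||b||_1 exactly
  set.seed(9)
  n <- 120; p <- 10
  X <- matrix(rnorm(n * p), n)
  y <- as.vector(X[, 1] * 1.2 - X[, 5] * 0.8 + rnorm(n))
  fam <- qtl_family("gaussian")
  for (lam in c(0.3, 0.1, 0.02)) {
    ours <- qtlasso:::pirls_one(cbind(1, X), y, fam, 1, lam, rep(0, p + 1),
                                pf = rep(1, p), irls_tol = 1e-10,
                                irls_maxit = 100, cd_tol = 1e-14)
    gn <- glmnet::glmnet(X, y, family = "gaussian", lambda = lam,
                         standardize = FALSE, thresh = 1e-14)
    expect_equal(ours$beta[-1], as.vector(gn$beta), tolerance = 1e-5)
    expect_equal(ours$beta[1], as.vector(gn$a0), tolerance = 1e-5)
  }
  # binomial: our lambda applies to mean-one-normalized IRLS weights, so the
  # glmnet-equivalent penalty is lambda / mean(w) with w = mu (1 - mu)
  set.seed(10)
  yb <- rbinom(n, 1, plogis(X[, 1] * 1.2 - X[, 5] * 0.8))
  famb <- qtl_family("binomial", "logit")
  lam <- 0.03
  gnb <- glmnet::glmnet(X, yb, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
  mu_gn <- plogis(as.vector(gnb$a0) + as.vector(X %*% gnb$beta))
  ourb <- qtlasso:::pirls_one(cbind(1, X), yb, famb, 1,
                              lam / mean(mu_gn * (1 - mu_gn)),
                              rep(0, p + 1), pf = rep(1, p),
                              irls_tol = 1e-10, irls_maxit = 100,
                              cd_tol = 1e-14)
  expect_equal(ourb$beta[-1], as.vector(gnb$beta), tolerance = 0.05)
})

test_that("cross-validation is deterministic and sane on pure noise", {
  set.seed(10)
  n <- 80; p <- 30
  X <- matrix(rnorm(n * p), n)
  y <- rbinom(n, 1, 0.5)
  fam <- qtl_family("binomial", "logit")
  cv1 <- cv_lambda(cbind(1, X), y, fam, folds = 4, seed = 3)
  cv2 <- cv_lambda(cbind(1, X), y, fam, folds = 4, seed = 3)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$mean_deviance, cv2$mean_deviance)
  expect_true(all(diff(cv1$lambda) < 0))
  expect_true(cv1$lambda_min %in% cv1$lambda)
  # pure noise: chosen lambda keeps the model very sparse most of the time
  b <- cv1$full_path$beta[, match(cv1$lambda_min, cv1$lambda)]
  expect_lte(sum(b[-1] != 0), 8)
})

test_that("cross-validation recovers a single strong predictor", {
  fam <- qtl_family("binomial", "logit")
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 200; p <- 15
    X <- matrix(rnorm(n * p), n)
    y <- rbinom(n, 1, plogis(2 * X[, 7]))
    cv <- cv_lambda(cbind(1, X), y, fam, folds = 4, seed = s)
    b <- cv$full_path$beta[, match(cv$lambda_min, cv$lambda)]
    if (b[8] != 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
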