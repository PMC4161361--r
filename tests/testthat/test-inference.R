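# minimal synthetic fit carrying just what prune_selected needs
fake_fit <- function(b, grid) {
  structure(list(coefficients = c(0, b),
                 regressors = list(grid = grid),
                 design = list(locus = seq_len(nrow(grid)),
                               type = rep("add", nrow(grid)))),
            class = "irlasso")
}

test_that("pruning keeps one locus per marker interval", {
  grid <- locus_grid(tiny_map(), 1)
  b <- rep(0, nrow(grid))
  # effects in distinct, well-separated intervals: unchanged
  i1 <- which(grid$pos_cM == 5); i2 <- which(grid$pos_cM == 25)
  b[c(i1, i2)] <- c(0.5, -0.7)
  expect_equal(prune_selected(fake_fit(b, grid)), sort(c(i1, i2)))
  # two loci in one interval: larger wins
  b <- rep(0, nrow(grid));
  j1 <- which(grid$pos_cM == 12); j2 <- which(grid$pos_cM == 18)
  b[c(j1, j2)] <- c(0.4, 0.9)
  expect_equal(prune_selected(fake_fit(b, grid)), j2)
  # exact tie: the smaller position is kept
  b[c(j1, j2)] <- c(0.4, 0.4)
  expect_equal(prune_selected(fake_fit(b, grid)), j1)
  # no nonzero effects
  expect_equal(prune_selected(fake_fit(rep(0, nrow(grid)), grid)), integer())
  # kept loci are never closer than one marker interval
  set.seed(19)
  for (rep in 1:10) {
    b <- ifelse(runif(nrow(grid)) < 0.3, rnorm(nrow(grid)), 0)
    kept <- prune_selected(fake_fit(b, grid))
    if (length(kept) > 1)
      expect_true(all(diff(grid$pos_cM[kept]) >= 10))
  }
})

test_that("gaussian refit reproduces the weighted least-squares oracle", {
  set.seed(20)
  n <- 100
  X <- matrix(rnorm(n * 2), n)
  y <- 1 + X %*% c(0.8, -0.5) + rnorm(n)
  fam <- qtl_family("gaussian")
  rf <- refit_glm(as.vector(y), X, matrix(0, n, 2), fam)
  ols <- lm(y ~ X)
  expect_equal(rf$beta, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(rf$se, unname(sqrt(diag(vcov(ols)))) *
                 sqrt((n - 3) / (n - 3)), tolerance = 1e-3)
  expect_equal(rf$t, unname(coef(summary(ols))[, "t value"]), tolerance = 1e-3)
})

test_that("binomial refit matches glm() when there is no genotype uncertainty", {
  set.seed(21)
  n <- 150
  X <- matrix(sample(c(-1, 1), n * 2, replace = TRUE), n)
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(1, -0.6)))
  fam <- qtl_family("binomial", "logit")
  rf <- refit_glm(y, X, matrix(0, n, 2), fam)
  gl <- glm(y ~ X, family = binomial())
  expect_equal(rf$beta, unname(coef(gl)), tolerance = 1e-5)
  expect_equal(rf$se, unname(sqrt(diag(vcov(gl)))), tolerance = 1e-4)
})

test_that("intercept-only refit returns the link of the mean response", {
  set.seed(22)
  y <- rbinom(80, 1, 0.3)
  fam <- qtl_family("binomial", "logit")
  rf <- refit_glm(y, matrix(numeric(0), 80, 0), matrix(numeric(0), 80, 0), fam)
  expect_equal(rf$beta, fam$linkfun(mean(y)), tolerance = 1e-8)
})

test_that("refit p-values are approximately uniform under the null", {
  set.seed(23)
  fam <- qtl_family("binomial", "logit")
  pvals <- vapply(1:400, function(r) {
    y <- rbinom(100, 1, 0.5)
    x <- matrix(sample(c(-1, 1), 100, replace = TRUE), 100)
    refit_glm(y, x, matrix(0, 100, 1), fam)$p[2]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("collinear refit columns are dropped with a warning", {
  set.seed(24)
  n <- 60
  x <- rnorm(n)
  X <- cbind(x, x)
  y <- rbinom(n, 1, plogis(x))
  fam <- qtl_family("binomial", "logit")
  expect_warning(rf <- refit_glm(y, X, matrix(0, n, 2), fam), "collinear")
  expect_equal(length(rf$beta), 2)
  expect_equal(rf$kept, 1L)
})

test_that("heritability partitions latent variance and respects coding scale", {
  expect_equal(heritability(numeric(), numeric(), 1), numeric())
  expect_equal(heritability(0, 1, 1), 0)
  # single probit locus, b = 1, Var(x) = 1: h2 = 1 / (1 + 1)
  expect_equal(heritability(1, 1, 1), 0.5)
  # invariant to rescaling the coding (b and x scale inversely)
  h1 <- heritability(c(1.2, -0.5), c(1, 0.8), pi^2 / 3)
  h2 <- heritability(c(1.2, -0.5) / 2, c(1, 0.8) * 4, pi^2 / 3)
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_true(all(h1 >= 0 & h1 < 1))
})

test_that("thresholds are the documented order statistic and deterministic", {
  map <- toy_map()
  spec <- sim_spec(map = map, family = "binomial", n = 60)
  thr <- qtl_threshold(spec, "null_sim", n_replicates = 30, level = 0.1,
                       seed = 5, grid_step = 10, lambda_rule = "ratio")
  expect_s3_class(thr, "qtl_threshold")
  expect_equal(thr$critical_value,
               sort(thr$maxima)[ceiling(0.9 * length(thr$maxima))])
  thr2 <- qtl_threshold(spec, "null_sim", n_replicates = 30, level = 0.1,
                        seed = 5, grid_step = 10, lambda_rule = "ratio")
  expect_identical(thr$maxima, thr2$maxima)
  expect_true(all(thr$maxima >= 0))
})

test_that("permutation thresholds run on an observed dataset", {
  map <- toy_map()
  spec <- sim_spec(map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 30, effect = 1),
                   family = "binomial", n = 80)
  sc <- simulate_cross(spec, seed = 26)
  rs <- build_regressors(sc$marker_geno, locus_grid(map, 10), "backcross")
  thr <- qtl_threshold(list(pheno = sc$pheno, regressors = rs,
                            family = "binomial", link = "logit", trials = 1),
                       "permutation", n_replicates = 25, level = 0.05,
                       seed = 6, lambda_rule = "ratio")
  expect_equal(thr$method, "permutation")
  expect_true(is.finite(thr$critical_value))
})

test_that("QTL calls are exactly the loci above the critical value", {
  spec <- backcross_10qtl_spec("binary", 150)
  sc <- simulate_cross(spec, seed = 27)
  rs <- build_regressors(sc$marker_geno, locus_grid(spec$map, 2), "backcross")
  fit <- irlasso(sc$pheno, rs, "binomial", lambda_rule = "bic")
  s0 <- summary(fit, threshold = Inf)
  expect_equal(nrow(s0$calls), 0)
  s <- summary(fit, threshold = 0)
  expect_equal(nrow(s$calls), nrow(s$table))
  crit <- median(s$table$neglog10p)
  expect_equal(call_qtls(s, crit),
               s$table[s$table$neglog10p >= crit, ])
})

test_that("power experiment output has the documented schema", {
  map <- toy_map()
  spec <- sim_spec(map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 30, effect = 2),
                   family = "binomial", n = 100)
  pw <- power_experiment(spec, threshold = 1, n_replicates = 2,
                         methods = c("IRglmnet", "UWglmnet"),
                         grid_step = 5, seed = 7, lambda_rule = "ratio")
  expect_equal(nrow(pw), 2)   # 1 QTL x 2 methods
  expect_true(all(pw$power %in% c(0, 50, 100)))
  expect_true(all(c("power", "mean_pos", "sd_pos", "mean_effect",
                    "sd_effect") %in% names(pw)))
})
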