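test_that("flanking probabilities match Markov-chain closed forms", {
  # observed marker at the locus: point mass
  expect_equal(flanking_genotype_probs(2, 2, 0, 0.1, "backcross"), c(0, 1))
  expect_equal(flanking_genotype_probs(1, 2, 0, 0.1, "backcross"), c(1, 0))
  # midpoint of discordant flanks: symmetric
  expect_equal(flanking_genotype_probs(1, 2, 0.1, 0.1, "backcross"),
               c(0.5, 0.5))
  # concordant heterozygous flanks, r = 0.1 each side:
  # P = 0.9 * 0.9 / (0.9 * 0.9 + 0.1 * 0.1) = 0.81 / 0.82
  p <- flanking_genotype_probs(2, 2, 0.1, 0.1, "backcross")
  expect_equal(p[2], 0.81 / 0.82, tolerance = 1e-12)
  expect_equal(round(p[2], 5), 0.98780)
  # one-sided conditioning (missing right flank)
  expect_equal(flanking_genotype_probs(2, NA, 0.1, NA, "backcross"),
               c(0.1, 0.9))
  # both missing: design prior
  expect_equal(flanking_genotype_probs(NA, NA, NA, NA, "f2"),
               c(0.25, 0.5, 0.25))
  expect_error(flanking_genotype_probs(3, 1, 0.1, 0.1, "backcross"),
               "invalid genotype")
})

test_that("indicator moments are the exact first two moments", {
  expect_equal(unname(indicator_moments(c(1, 0), c(-1, 1))), c(-1, 0))
  expect_equal(unname(indicator_moments(c(0.5, 0.5), c(-1, 1))), c(0, 1))
  m <- indicator_moments(c(0.01220, 0.98780), c(-1, 1))
  expect_equal(unname(round(m, 5)), c(0.97561, 0.04819), tolerance = 1e-4)
  # against direct computation on a random distribution
  set.seed(3)
  p <- runif(2); p <- p / sum(p)
  m2 <- indicator_moments(p, c(-1, 1))
  x <- c(-1, 1)
  expect_equal(unname(m2["d"]), sum(p * x))
  expect_equal(unname(m2["c"]), sum(p * x^2) - sum(p * x)^2)
})

test_that("F2 additive/dominance moments follow the coding", {
  expect_equal(unname(f2_indicator_moments(c(1, 0, 0))), c(1, 0, 0, 0))
  expect_equal(unname(f2_indicator_moments(c(0, 1, 0))), c(0, 0, 1, 0))
  expect_equal(unname(f2_indicator_moments(c(0.25, 0.5, 0.25))),
               c(0, 0.5, 0.5, 0.25))
})

test_that("regressors reproduce coded genotypes exactly at observed markers", {
  map <- tiny_map()
  spec <- sim_spec(map = map, family = "binomial", n = 30)
  sc <- simulate_cross(spec, seed = 5)
  grid <- locus_grid(map, 100)   # marker loci only
  rs <- build_regressors(sc$marker_geno, grid, "backcross")
  expect_equal(rs$d, matrix(c(-1, 1)[sc$marker_geno], 30, 5,
                            dimnames = dimnames(rs$d)))
  expect_true(all(rs$c == 0))
})

test_that("an individual with no genotypes gets the prior everywhere", {
  map <- tiny_map()
  geno <- matrix(2L, 3, 5)
  geno[2, ] <- NA_integer_
  grid <- locus_grid(map, 5)
  expect_warning(rs <- build_regressors(geno, grid, "backcross"),
                 "no observed marker")
  expect_equal(unname(rs$d[2, ]), rep(0, nrow(grid)))
  expect_equal(unname(rs$c[2, ]), rep(1, nrow(grid)))
  # fully heterozygous individuals: d = +1, c = 0 at markers
  expect_equal(unname(rs$d[1, grid$at_marker]), rep(1, 5))
})

test_that("regressor cells match the brute-force chain enumeration", {
  map <- tiny_map()
  set.seed(11)
  geno <- matrix(sample(c(1L, 2L, NA), 5 * 5, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), 5, 5)
  geno[4, ] <- NA_integer_  # fully missing individual
  grid <- locus_grid(map, 3)
  rs <- suppressWarnings(build_regressors(geno, grid, "backcross"))
  for (i in 1:5) for (j in seq_len(nrow(grid))) {
    p <- enum_cond_prob(geno[i, ], map$pos_cM, grid$pos_cM[j])
    m <- indicator_moments(p, c(-1, 1))
    expect_equal(unname(rs$d[i, j]), unname(m["d"]), tolerance = 1e-10)
    expect_equal(unname(rs$c[i, j]), unname(m["c"]), tolerance = 1e-10)
  }
})

test_that("conditional variance is bounded and d, c are continuous in position", {
  map <- tiny_map()
  spec <- sim_spec(map = map, family = "binomial", n = 40)
  sc <- simulate_cross(spec, seed = 6)
  grid <- locus_grid(map, 0.01)
  rs <- build_regressors(sc$marker_geno, grid, "backcross")
  expect_true(all(rs$c >= 0 & rs$c <= 1))
  expect_true(all(abs(rs$d) <= 1))
  expect_true(all(rs$d^2 + rs$c <= 1 + 1e-12))
  expect_true(all(rs$c[, grid$at_marker] == 0))
  # no jumps between adjacent 0.01 cM grid points
  expect_lt(max(abs(diff(t(rs$d)))), 0.005)
  expect_lt(max(abs(diff(t(rs$c)))), 0.005)
})

test_that("law of total variance holds at interior loci on simulated data", {
  map <- genetic_map(c("a", "b"), "c1", c(0, 20))
  spec <- sim_spec(map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 8, effect = 0),
                   family = "binomial", n = 10000)
  sc <- simulate_cross(spec, seed = 8)
  grid <- locus_grid(map, 4)
  rs <- build_regressors(sc$marker_geno, grid, "backcross")
  x <- c(-1, 1)[sc$qtl_geno[, 1]]
  j <- which(grid$pos_cM == 8)
  expect_equal(var(rs$d[, j]) + mean(rs$c[, j]), var(x), tolerance = 0.05)
  # and the regressor is an unbiased predictor of the true indicator
  expect_equal(mean(rs$d[, j] - x), 0, tolerance = 0.03)
})

test_that("F2 regressors give Mendelian moments when uninformative", {
  map <- genetic_map(c("a", "b"), "c1", c(0, 200))  # ~unlinked flanks
  geno <- matrix(NA_integer_, 2, 2)
  grid <- locus_grid(map, 100)
  rs <- suppressWarnings(build_regressors(geno, grid, "f2"))
  j <- which(grid$pos_cM == 100)
  expect_equal(unname(rs$d[1, j]), 0, tolerance = 1e-12)
  expect_equal(unname(rs$c[1, j]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rs$d_dom[1, j]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rs$c_dom[1, j]), 0.25, tolerance = 1e-12)
})
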