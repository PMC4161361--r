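test_that("the benchmark scenario encodes the 10-QTL backcross design", {
  sp <- backcross_10qtl_spec("binary", 200)
  expect_equal(nrow(sp$map), 66)
  expect_equal(length(chrom_lengths(sp$map)), 6)
  expect_equal(unname(chrom_lengths(sp$map)), rep(100, 6))
  expect_equal(nrow(sp$qtl), 10)
  expect_equal(sp$qtl$effect[2], 2.0)
  expect_equal(sp$qtl$effect,
               c(1.5, 2.0, 0.72, 1.1, -0.22, 0.70, -0.65, 1.25, 0.35, -0.80))
  gp <- cumulative_position(sp$map, sp$qtl$chrom, sp$qtl$pos_cM)
  expect_equal(gp, c(23, 56, 148, 193, 267, 332, 390, 478, 522, 574))
  # Q10 at genome 574 lives on chromosome 6 at 74 cM
  expect_equal(sp$qtl$chrom[10], "chr6")
  expect_equal(sp$qtl$pos_cM[10], 74)
  expect_equal(sp$mu0, 0)
  expect_identical(sp$link, "probit")
  expect_identical(backcross_10qtl_spec("poisson", 200)$link, "log")
})

test_that("completely linked loci always share a genotype", {
  map <- genetic_map(c("a", "b"), "c1", c(0, 30))
  spec <- sim_spec(map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 0, effect = 1),
                   family = "binomial", n = 200)
  set.seed(1)
  g <- simulate_genotypes(spec)
  expect_equal(g$qtl_geno[, 1], unname(g$marker_geno[, "a"]))
})

test_that("recombination frequencies match Haldane expectations", {
  map <- genetic_map(paste0("m", 1:4), c(1, 1, 2, 2), c(0, 10, 0, 50))
  spec <- sim_spec(map = map, family = "binomial", n = 10000)
  set.seed(2)
  g <- simulate_genotypes(spec)$marker_geno
  # linked pair 10 cM apart: recombinant fraction ~ 0.0906
  rhat <- mean(g[, 1] != g[, 2])
  r <- map_distance_to_recomb(10)
  se <- sqrt(r * (1 - r) / 10000)
  expect_lt(abs(rhat - r), 4 * se)
  # unlinked pair: correlation of codes ~ 0
  x1 <- c(-1, 1)[g[, 1]]; x3 <- c(-1, 1)[g[, 3]]
  expect_lt(abs(cor(x1, x3)), 4 / sqrt(10000))
  # marginal class frequencies ~ 1/2 (chi-square at alpha = 0.001)
  for (j in 1:4)
    expect_gt(chisq.test(table(g[, j]), p = c(0.5, 0.5))$p.value, 0.001)
  # linkage decay: correlation decreases with distance (0, 10, 50 cM apart)
  x2 <- c(-1, 1)[g[, 2]]; x4 <- c(-1, 1)[g[, 4]]
  expect_gt(cor(x1, x2), cor(x3, x4))
  expect_gt(cor(x3, x4), cor(x1, x4))
})

test_that("phenotypes follow the family under null and single-QTL models", {
  map <- tiny_map()
  # null binary logit: Bernoulli(1/2)
  spec0 <- sim_spec(map = map, family = "binomial", n = 10000)
  sc0 <- simulate_cross(spec0, seed = 3)
  expect_lt(abs(mean(sc0$pheno) - 0.5), 4 * 0.005)
  # null poisson log: mean 1, variance ~ mean
  specp <- sim_spec(map = map, family = "poisson", n = 10000)
  scp <- simulate_cross(specp, seed = 4)
  expect_lt(abs(mean(scp$pheno) - 1), 4 * 0.01)
  expect_gt(var(scp$pheno) / mean(scp$pheno), 0.9)
  expect_lt(var(scp$pheno) / mean(scp$pheno), 1.1)
  # single QTL, effect 2, binary logit: group means logistic(+-2)
  spec1 <- sim_spec(map = map,
                    qtl = data.frame(chrom = "c1", pos_cM = 20, effect = 2),
                    family = "binomial", n = 20000)
  sc1 <- simulate_cross(spec1, seed = 5)
  x <- c(-1, 1)[sc1$qtl_geno[, 1]]
  p_hi <- mean(sc1$pheno[x == 1]); p_lo <- mean(sc1$pheno[x == -1])
  se <- sqrt(0.12 * 0.88 / 10000)
  expect_lt(abs(p_hi - plogis(2)), 4 * se)
  expect_lt(abs(p_lo - plogis(-2)), 4 * se)
})

test_that("simulation is reproducible and seeds differentiate replicates", {
  spec <- backcross_10qtl_spec("binary", 50)
  a <- simulate_cross(spec, seed = 9)
  b <- simulate_cross(spec, seed = 9)
  expect_identical(a$marker_geno, b$marker_geno)
  expect_identical(a$pheno, b$pheno)
  phenos <- vapply(1:100, function(s)
    paste(simulate_cross(spec, seed = s)$pheno, collapse = ""), "")
  expect_equal(anyDuplicated(phenos), 0)
})

test_that("null simulation has zero effects and the family mean", {
  sc <- simulate_null(tiny_map(), "backcross", "binomial", n = 5000,
                      seed = 10)
  expect_equal(nrow(sc$spec$qtl), 0)
  expect_lt(abs(mean(sc$pheno) - 0.5), 4 * sqrt(0.25 / 5000))
})

test_that("invalid simulation settings are rejected", {
  map <- tiny_map()
  expect_error(sim_spec(map = map,
                        qtl = data.frame(chrom = "c1", pos_cM = 99, effect = 1),
                        family = "binomial", n = 10),
               "outside")
  expect_error(sim_spec(map = map,
                        qtl = data.frame(chrom = "c1", pos_cM = 5, effect = 1,
                                         dom_effect = 0.5),
                        design = "backcross", family = "binomial", n = 10),
               "dominance")
  # identity-link poisson with a mean forced negative
  spec <- sim_spec(map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 5, effect = 3),
                   family = "poisson", link = "identity", mu0 = 1, n = 50)
  set.seed(11)
  g <- simulate_genotypes(spec)
  expect_error(simulate_phenotypes(g$qtl_geno, spec), "domain|individual")
})

test_that("F2 genotypes segregate 1:2:1 and carry dominance effects", {
  map <- tiny_map()
  spec <- sim_spec(design = "f2", map = map,
                   qtl = data.frame(chrom = "c1", pos_cM = 20, effect = 0,
                                    dom_effect = 1),
                   family = "binomial", n = 8000)
  sc <- simulate_cross(spec, seed = 12)
  tab <- table(sc$marker_geno[, 3])
  expect_gt(chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  het <- sc$qtl_geno[, 1] == 2
  expect_gt(mean(sc$pheno[het]), mean(sc$pheno[!het]))
})
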