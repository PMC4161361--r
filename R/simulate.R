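#' Specify a cross/phenotype simulation
#'
#' Bundles everything needed to draw a mapping population: the design, the
#' genetic map, QTL positions and effects, the trait family/link, the
#' population intercept on the link scale, and the sample size.
#'
#' @param design `"backcross"`, `"dh"`, `"ril"` or `"f2"`.
#' @param map A `"genmap"` object.
#' @param qtl Data frame with columns `chrom`, `pos_cM`, `effect`
#'   (additive, link scale) and optionally `dom_effect` (F2 only); may have
#'   zero rows for a null model.
#' @param family,link Trait family and link (see [qtl_family()]).
#' @param mu0 Population intercept on the link scale (default 0).
#' @param n Number of individuals.
#' @param trials Binomial denominator per individual (default 1 = binary).
#' @param coding Genotype indicator coding for two-class designs
#'   (`"pm1"` = -1/+1, default).
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(design = "backcross", map, qtl = NULL,
                     family = "binomial", link = NULL, mu0 = 0, n,
                     trials = 1, coding = "pm1") {
  design <- match.arg(design, c("backcross", "dh", "ril", "f2"))
  stopifnot(inherits(map, "genmap"), n >= 1, trials >= 1)
  if (is.null(qtl)) qtl <- data.frame(chrom = character(), pos_cM = numeric(),
                                      effect = numeric())
  qtl <- as.data.frame(qtl)
  stopifnot(all(c("chrom", "pos_cM", "effect") %in% names(qtl)))
  if (!is.null(qtl$dom_effect) && design != "f2" && any(qtl$dom_effect != 0))
    stop("dominance effects are only allowed for the F2 design")
  len <- chrom_lengths(map)
  if (nrow(qtl)) {
    qtl$chrom <- as.character(qtl$chrom)
    bad <- !(qtl$chrom %in% names(len)) | qtl$pos_cM < 0 |
      qtl$pos_cM > len[qtl$chrom]
    if (any(bad)) stop("QTL position outside its chromosome")
  }
  fam <- qtl_family(family, link)
  out <- list(design = design, map = map, qtl = qtl, family = fam$family,
              link = fam$link, mu0 = mu0, n = as.integer(n),
              trials = as.integer(trials), coding = coding)
  class(out) <- "sim_spec"
  out
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Cross simulation spec: ", x$design, ", n = ", x$n, ", ",
      x$family, "(", x$link, "), ", nrow(x$qtl), " QTL\n", sep = "")
  invisible(x)
}

# simulate genotype class indices (1/2 for two-class designs, 1/2/3 for F2)
# at the given ordered positions of one chromosome, as a first-order Markov
# chain with Haldane transition probabilities
sim_chrom_genotypes <- function(n, pos, design) {
  m <- length(pos)
  r <- map_distance_to_recomb(diff(pos))
  if (design == "ril") r <- 2 * r / (1 + 2 * r)
  if (design == "f2") {
    # two independent gametes, each a two-state chain
    g1 <- sim_gamete(n, r)
    g2 <- sim_gamete(n, r)
    return(g1 + g2 - 1L)  # 1=AA, 2=AB, 3=BB
  }
  sim_gamete(n, r)
}

# one two-state chain: matrix n x (length(r)+1) of classes 1/2
sim_gamete <- function(n, r) {
  m <- length(r) + 1L
  g <- matrix(1L, n, m)
  g[, 1] <- sample.int(2L, n, replace = TRUE)
  for (j in seq_along(r)) {
    switch_ <- stats::runif(n) < r[j]
    g[, j + 1] <- ifelse(switch_, 3L - g[, j], g[, j])
  }
  g
}

#' Simulate genotypes for a cross
#'
#' Draws marker and QTL genotypes jointly along each chromosome as a
#' first-order Markov chain whose locus-to-locus switch probability is the
#' Haldane recombination fraction of the inter-locus distance (with map
#' expansion for RIL; two independent meioses for F2).
#'
#' @param spec A `"sim_spec"`.
#' @return List with `marker_geno` (n x markers integer class matrix,
#'   columns named per map) and `qtl_geno` (n x nQTL class matrix).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  map <- spec$map
  n <- spec$n
  nq <- nrow(spec$qtl)
  marker_geno <- matrix(NA_integer_, n, nrow(map),
                        dimnames = list(NULL, map$marker))
  qtl_geno <- matrix(NA_integer_, n, nq)
  for (ch in unique(map$chrom)) {
    mrows <- which(map$chrom == ch)
    qrows <- if (nq) which(spec$qtl$chrom == ch) else integer()
    pos <- c(map$pos_cM[mrows], spec$qtl$pos_cM[qrows])
    kind <- c(rep("m", length(mrows)), rep("q", length(qrows)))
    ord <- order(pos, kind)  # markers first at exact ties
    g <- sim_chrom_genotypes(n, pos[ord], spec$design)
    # at zero distance the chain keeps the genotype, so ties are consistent
    back <- order(ord)
    marker_geno[, mrows] <- g[, back[seq_along(mrows)], drop = FALSE]
    if (length(qrows))
      qtl_geno[, qrows] <- g[, back[length(mrows) + seq_along(qrows)], drop = FALSE]
  }
  list(marker_geno = marker_geno, qtl_geno = qtl_geno)
}

# coded indicator matrix from class indices
code_genotypes <- function(gcls, design, coding) {
  codes <- design_codings(design, coding)
  matrix(codes$add[gcls], nrow(gcls), ncol(gcls))
}

#' Simulate phenotypes given QTL genotypes
#'
#' Forms the linear predictor eta = mu0 + sum_j x_ij b_j from the coded QTL
#' genotypes, maps it through the inverse link, and draws each phenotype from
#' the trait family with that mean.
#'
#' @param qtl_geno n x nQTL genotype class matrix (from
#'   [simulate_genotypes()]).
#' @param spec A `"sim_spec"`.
#' @return Numeric phenotype vector (counts of successes for binomial with
#'   `trials > 1`).
#' @export
simulate_phenotypes <- function(qtl_geno, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n
  eta <- rep(spec$mu0, n)
  if (nrow(spec$qtl)) {
    X <- code_genotypes(qtl_geno, spec$design, spec$coding)
    eta <- eta + as.vector(X %*% spec$qtl$effect)
    if (!is.null(spec$qtl$dom_effect) && spec$design == "f2") {
      H <- matrix(c(0, 1, 0)[qtl_geno], n, ncol(qtl_geno))
      eta <- eta + as.vector(H %*% spec$qtl$dom_effect)
    }
  }
  fam <- qtl_family(spec$family, spec$link)
  mu <- fam$linkinv_raw(eta)   # unclipped: domain violations must surface
  bad <- !is.finite(mu) |
    (spec$family == "poisson" & mu < 0) |
    (spec$family == "binomial" & (mu < 0 | mu > 1))
  if (any(bad))
    stop("mean outside the ", spec$family, " domain under the ", spec$link,
         " link for individual(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  switch(spec$family,
         gaussian = stats::rnorm(n, mu, 1),
         poisson = stats::rpois(n, mu),
         binomial = stats::rbinom(n, spec$trials, mu))
}

#' Simulate a full mapping dataset
#'
#' @param spec A `"sim_spec"`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"sim_cross"`: list with `marker_geno`
#'   (class indices), `qtl_geno` (withheld truth), `pheno`, and `spec`.
#' @examples
#' sc <- simulate_cross(backcross_10qtl_spec("binary", n = 100), seed = 1)
#' table(sc$pheno)
#' @export
simulate_cross <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g$qtl_geno, spec)
  out <- list(marker_geno = g$marker_geno, qtl_geno = g$qtl_geno,
              pheno = y, spec = spec)
  class(out) <- "sim_cross"
  out
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("Simulated ", x$spec$design, " cross: n = ", x$spec$n, ", ",
      ncol(x$marker_geno), " markers, ", nrow(x$spec$qtl), " QTL, ",
      x$spec$family, " phenotype\n", sep = "")
  invisible(x)
}

#' Simulate a dataset under the null model (zero genetic effects)
#'
#' @param map A `"genmap"`.
#' @param design Cross design.
#' @param family,link Trait family and link.
#' @param n Sample size.
#' @param mu0 Intercept on the link scale.
#' @param trials Binomial denominator.
#' @param seed Optional seed.
#' @return A `"sim_cross"` with zero-effect QTL list.
#' @export
simulate_null <- function(map, design = "backcross", family = "binomial",
                          link = NULL, n, mu0 = 0, trials = 1, seed = NULL) {
  spec <- sim_spec(design = design, map = map, qtl = NULL, family = family,
                   link = link, mu0 = mu0, n = n, trials = trials)
  simulate_cross(spec, seed = seed)
}

#' The benchmark 10-QTL backcross scenario
#'
#' A backcross with six 100 cM chromosomes carrying 11 evenly spaced
#' co-dominant markers each (10 cM spacing, 66 markers), and ten QTL at
#' genome-wide positions 23, 56, 148, 193, 267, 332, 390, 478, 522 and
#' 574 cM with additive effects 1.5, 2.0, 0.72, 1.1, -0.22, 0.70, -0.65,
#' 1.25, 0.35 and -0.80 on the link scale; population intercept 0.  Binary
#' traits use the probit link (the threshold-model interpretation of a
#' binary trait: the effects act on a latent liability), count traits the
#' log link.
#'
#' @param trait `"binary"` or `"poisson"`.
#' @param n Sample size (200 and 400 are the benchmark sizes).
#' @return A `"sim_spec"`.
#' @examples
#' sp <- backcross_10qtl_spec("binary", 200)
#' sp$qtl
#' @export
backcross_10qtl_spec <- function(trait = c("binary", "poisson"), n) {
  trait <- match.arg(trait)
  map <- genetic_map(
    marker = paste0("m", seq_len(66)),
    chrom = rep(paste0("chr", 1:6), each = 11),
    pos_cM = rep(seq(0, 100, by = 10), times = 6))
  genome_pos <- c(23, 56, 148, 193, 267, 332, 390, 478, 522, 574)
  effects <- c(1.5, 2.0, 0.72, 1.1, -0.22, 0.70, -0.65, 1.25, 0.35, -0.80)
  loc <- genome_to_local(map, genome_pos)
  qtl <- data.frame(chrom = loc$chrom, pos_cM = loc$pos_cM, effect = effects)
  family <- if (trait == "binary") "binomial" else "poisson"
  link <- if (trait == "binary") "probit" else "log"
  sim_spec(design = "backcross", map = map, qtl = qtl, family = family,
           link = link, mu0 = 0, n = n)
}
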