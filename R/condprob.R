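#' Conditional genotype-class probabilities given flanking markers
#'
#' Probability distribution of the genotype at a putative locus given the
#' nearest informative flanking marker genotypes, under a no-interference
#' (Haldane) Markov model along the chromosome.  Two genotype classes for
#' backcross/DH/RIL, three (AA, AB, BB) for F2.
#'
#' Either flank may be `NA` (missing), in which case the locus is conditioned
#' on the remaining side only; with both missing the prior for the design is
#' returned.
#'
#' @param left_geno,right_geno Flanking genotype class index (1-based; 1/2
#'   for backcross-type designs, 1/2/3 = AA/AB/BB for F2) or `NA`.
#' @param r_left,r_right Recombination fractions between the locus and the
#'   left/right flanking marker, in \[0, 0.5\].
#' @param design `"backcross"`, `"dh"`, `"ril"` or `"f2"`.
#' @return Numeric probability vector over the genotype classes (sums to 1).
#' @examples
#' flanking_genotype_probs(2, 2, 0.1, 0.1, "backcross")  # c(0.01220, 0.98780)
#' @export
flanking_genotype_probs <- function(left_geno, right_geno, r_left, r_right,
                                    design = c("backcross", "dh", "ril", "f2")) {
  design <- match.arg(design)
  ncls <- if (design == "f2") 3L else 2L
  rr <- c(if (!is.na(left_geno)) r_left, if (!is.na(right_geno)) r_right)
  if (any(rr < 0 | rr > 0.5))
    stop("recombination fractions must lie in [0, 0.5]")
  prior <- if (design == "f2") c(0.25, 0.5, 0.25) else c(0.5, 0.5)
  p <- prior
  if (!is.na(left_geno)) {
    check_class(left_geno, ncls)
    p <- p * transition_matrix(r_left, design)[left_geno, ]
  }
  if (!is.na(right_geno)) {
    check_class(right_geno, ncls)
    p <- p * transition_matrix(r_right, design)[, right_geno]
  }
  # with both flanks present the prior cancels except in F2, where the
  # stationary distribution is not uniform; chain reversibility makes
  # prior * T_L[gL,] * T_R[,gR] proportional to the exact conditional
  if (!is.na(left_geno)) p <- p / prior
  p / sum(p)
}

check_class <- function(g, ncls) {
  if (!g %in% seq_len(ncls))
    stop("invalid genotype class code: ", g)
}

# locus-to-locus genotype transition matrix at recombination fraction r
transition_matrix <- function(r, design) {
  if (design == "ril") r <- 2 * r / (1 + 2 * r)  # map expansion, selfed RIL
  if (design %in% c("backcross", "dh", "ril")) {
    matrix(c(1 - r, r, r, 1 - r), 2, 2)
  } else {
    # F2: two independent meioses, classes AA, AB, BB
    matrix(c((1 - r)^2,       2 * r * (1 - r),     r^2,
             r * (1 - r),     (1 - r)^2 + r^2,     r * (1 - r),
             r^2,             2 * r * (1 - r),     (1 - r)^2),
           3, 3, byrow = TRUE)
  }
}

#' First two moments of the coded genotype indicator
#'
#' Given class probabilities and a numeric coding, returns the conditional
#' expectation d and conditional variance c of the indicator; these are the
#' Haley-Knott regressor and the variance that drives over-dispersion.
#'
#' @param probs Probability vector over genotype classes.
#' @param coding Numeric code per class (same length as `probs`).
#' @return Named numeric vector `c(d = ..., c = ...)`.
#' @examples
#' indicator_moments(c(0.5, 0.5), c(-1, 1))  # d = 0, c = 1
#' @export
indicator_moments <- function(probs, coding) {
  stopifnot(length(probs) == length(coding),
            all(probs >= -1e-12), abs(sum(probs) - 1) < 1e-8)
  d <- sum(probs * coding)
  c(d = d, c = max(sum(probs * coding^2) - d^2, 0))
}

#' Additive and dominance indicator moments for an F2 locus
#'
#' Additive coding +1/0/-1 for AA/AB/BB; dominance coding 0/1/0
#' (1 for the heterozygote).
#'
#' @param probs Length-3 probability vector over (AA, AB, BB).
#' @return Named vector `c(d_add, c_add, d_dom, c_dom)`.
#' @export
f2_indicator_moments <- function(probs) {
  stopifnot(length(probs) == 3, abs(sum(probs) - 1) < 1e-8)
  d_add <- probs[1] - probs[3]
  c_add <- max(probs[1] + probs[3] - d_add^2, 0)
  d_dom <- probs[2]
  c_dom <- max(d_dom * (1 - d_dom), 0)
  c(d_add = d_add, c_add = c_add, d_dom = unname(d_dom), c_dom = c_dom)
}

design_codings <- function(design, coding = c("pm1", "01")) {
  coding <- match.arg(coding)
  if (design == "f2") list(add = c(1, 0, -1), dom = c(0, 1, 0))
  else if (coding == "pm1") list(add = c(-1, 1))
  else list(add = c(0, 1))
}

#' Build Haley-Knott regressors at every grid locus
#'
#' For each individual and each putative locus computes the conditional
#' expectation `d` and conditional variance `c` of the coded genotype
#' indicator given the nearest informative flanking markers (F2 designs
#' additionally get dominance columns `d_dom`, `c_dom`).  At an observed
#' marker the regressor equals the coded genotype exactly and `c = 0`;
#' individuals with no informative marker on one side are conditioned on the
#' other side only, and with none on the chromosome get the design prior
#' (with a warning).
#'
#' @param geno Integer matrix (n x markers) of genotype class indices
#'   (1-based; `NA` = missing), columns ordered as in `map`.
#' @param grid A `"locus_grid"` built from the same map.
#' @param design Cross design.
#' @param coding `"pm1"` (-1/+1, default) or `"01"` for two-class designs.
#' @param map_function Passed to [map_distance_to_recomb()].
#' @return An object of class `"regressor_set"`: list with matrices `d`, `c`
#'   (n x loci), optionally `d_dom`, `c_dom`, plus `grid`, `design`, `coding`.
#' @export
build_regressors <- function(geno, grid, design = c("backcross", "dh", "ril", "f2"),
                             coding = c("pm1", "01"),
                             map_function = "haldane") {
  design <- match.arg(design)
  coding <- match.arg(coding)
  map <- attr(grid, "map")
  stopifnot(inherits(grid, "locus_grid"), ncol(geno) == nrow(map))
  geno <- as.matrix(geno)
  ncls <- if (design == "f2") 3L else 2L
  if (any(!is.na(geno) & !(geno %in% seq_len(ncls))))
    stop("genotype matrix contains invalid class codes for design ", design)
  n <- nrow(geno)
  k <- nrow(grid)
  codes <- design_codings(design, coding)
  prior <- if (design == "f2") c(0.25, 0.5, 0.25) else c(0.5, 0.5)
  d <- matrix(0, n, k); cc <- matrix(0, n, k)
  if (design == "f2") { dd <- matrix(0, n, k); cd <- matrix(0, n, k) }

  all_missing_warned <- FALSE
  for (ch in unique(grid$chrom)) {
    mrows <- which(map$chrom == ch)
    mpos <- map$pos_cM[mrows]
    G <- geno[, mrows, drop = FALSE]
    if (any(rowSums(!is.na(G)) == 0)) all_missing_warned <- TRUE
    # per individual: nearest observed marker at or left of / at or right of slot j
    m <- length(mrows)
    obs <- !is.na(G)
    left_near <- t(apply(obs, 1, function(o) cummax_idx(o)))
    right_near <- t(apply(obs, 1, function(o) rev(cummax_idx(rev(o)))))
    right_near[right_near > 0] <- m + 1L - right_near[right_near > 0]
    glocs <- which(grid$chrom == ch)
    for (j in glocs) {
      pos <- grid$pos_cM[j]
      li <- match(grid$left_marker[j], mrows)
      ri <- match(grid$right_marker[j], mrows)
      Lidx <- left_near[, li]              # nearest observed marker <= pos
      Ridx <- right_near[, ri]             # nearest observed marker >= pos
      mom <- locus_moments(G, Lidx, Ridx, mpos, pos, design, codes, prior,
                           map_function)
      d[, j] <- mom$d; cc[, j] <- mom$c
      if (design == "f2") { dd[, j] <- mom$d_dom; cd[, j] <- mom$c_dom }
    }
  }
  if (all_missing_warned)
    warning("some individuals have no observed marker on a chromosome; ",
            "design prior used there")
  colnames(d) <- colnames(cc) <- locus_labels(grid)
  out <- list(d = d, c = cc, grid = grid, design = design, coding = coding)
  if (design == "f2") {
    colnames(dd) <- colnames(cd) <- locus_labels(grid)
    out$d_dom <- dd; out$c_dom <- cd
  }
  class(out) <- "regressor_set"
  out
}

locus_labels <- function(grid) paste0(grid$chrom, "@", grid$pos_cM)

# index of last TRUE at or before each position; 0 if none
cummax_idx <- function(o) cummax(ifelse(o, seq_along(o), 0L))

# vectorized over individuals: conditional moments at one locus.
# Lidx/Ridx index the nearest observed marker at-or-left / at-or-right of the
# locus (0 = none on that side); the class likelihoods are assembled from the
# Markov transition probabilities without forming per-individual matrices.
locus_moments <- function(G, Lidx, Ridx, mpos, pos, design, codes, prior,
                          map_function) {
  n <- nrow(G)
  ncls <- length(prior)
  hasL <- Lidx > 0L
  hasR <- Ridx > 0L
  rL <- rep(NA_real_, n); rR <- rep(NA_real_, n)
  gL <- rep(NA_integer_, n); gR <- rep(NA_integer_, n)
  if (any(hasL)) {
    rL[hasL] <- map_distance_to_recomb(pos - mpos[Lidx[hasL]], map_function)
    gL[hasL] <- G[cbind(which(hasL), Lidx[hasL])]
  }
  if (any(hasR)) {
    rR[hasR] <- map_distance_to_recomb(mpos[Ridx[hasR]] - pos, map_function)
    gR[hasR] <- G[cbind(which(hasR), Ridx[hasR])]
  }
  if (design == "ril") {
    rL <- 2 * rL / (1 + 2 * rL)
    rR <- 2 * rR / (1 + 2 * rR)
  }
  if (ncls == 2L) {
    # P(locus = class 2 | left flank) and P(right flank | locus = class 2)
    a2 <- ifelse(hasL, ifelse(gL == 2L, 1 - rL, rL), 0.5)
    b2 <- ifelse(hasR, ifelse(gR == 2L, 1 - rR, rR), 0.5)
    w2 <- a2 * b2
    w1 <- (1 - a2) * (1 - b2)
    p2 <- w2 / (w1 + w2)
    code <- codes$add
    d <- code[1] + (code[2] - code[1]) * p2
    cc <- pmax((code[2] - code[1])^2 * p2 * (1 - p2), 0)
    return(list(d = d, c = cc))
  }
  # F2: P(x | gL, gR) proportional to P(x | gL) * P(gR | x); rows lacking a
  # left flank fall back to the Mendelian prior in place of P(x | gL)
  A <- f2_class_lik(gL, rL, hasL, from = TRUE, prior)
  B <- f2_class_lik(gR, rR, hasR, from = FALSE, prior)
  A[!hasL, ] <- matrix(prior, sum(!hasL), 3, byrow = TRUE)
  P <- A * B
  P <- P / rowSums(P)
  code <- codes$add
  d <- as.vector(P %*% code)
  cc <- pmax(as.vector(P %*% code^2) - d^2, 0)
  list(d = d, c = cc, d_dom = P[, 2], c_dom = pmax(P[, 2] * (1 - P[, 2]), 0))
}

# n x 3 matrix of P(locus class | flank) (from = TRUE) or
# P(flank | locus class) (from = FALSE); rows with no flank are all-ones so
# they drop out of the product (the prior is applied by the caller).
f2_class_lik <- function(g, r, has, from, prior) {
  n <- length(g)
  M <- matrix(1, n, 3)
  if (!any(has)) return(M)
  r <- r[has]; g <- g[has]
  # transition rows for F2 (two independent meioses); the matrix is symmetric
  # in (from, to) for classes 1<->3 and the conditional P(class|flank) equals
  # T[flank, class] by chain construction, while P(flank|class) = T[class, flank];
  # since T is reversible wrt the Mendelian prior, use T[g, ] scaled when needed
  row_of <- function(gi, ri) {
    switch(gi,
           cbind((1 - ri)^2, 2 * ri * (1 - ri), ri^2),
           cbind(ri * (1 - ri), (1 - ri)^2 + ri^2, ri * (1 - ri)),
           cbind(ri^2, 2 * ri * (1 - ri), (1 - ri)^2))
  }
  L <- matrix(NA_real_, sum(has), 3)
  for (gi in 1:3) {
    m <- g == gi
    if (any(m)) L[m, ] <- row_of(gi, r[m])
  }
  if (from) {
    M[has, ] <- L
  } else {
    # P(flank g | locus class) = T[class, g]: column g of T as function of class
    Tg <- matrix(NA_real_, sum(has), 3)
    for (gi in 1:3) {
      m <- g == gi
      if (any(m)) {
        ri <- r[m]
        Tg[m, ] <- switch(gi,
          cbind((1 - ri)^2, ri * (1 - ri), ri^2),
          cbind(2 * ri * (1 - ri), (1 - ri)^2 + ri^2, 2 * ri * (1 - ri)),
          cbind(ri^2, ri * (1 - ri), (1 - ri)^2))
      }
    }
    M[has, ] <- Tg
  }
  M
}

#' @export
print.regressor_set <- function(x, ...) {
  cat("Haley-Knott regressor set:", nrow(x$d), "individuals x", ncol(x$d),
      "loci (", x$design, ", ", x$coding, " coding)\n", sep = "")
  invisible(x)
}
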