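#' Prune nonzero effects to one locus per marker interval
#'
#' The LASSO spreads one QTL's signal over a few nearby grid loci; the
#' redundancy is removed by allowing at most one locus per marker-interval
#' width: nonzero loci are visited in decreasing order of absolute effect
#' (ties break toward the smaller position) and a locus is kept only when no
#' already-kept locus of the same effect type lies within one marker
#' interval of it on the same chromosome.  This guarantees at most one kept
#' locus per marker interval.  Additive and dominance columns (F2) are
#' pruned separately.
#'
#' @param fit An `"irlasso"` object.
#' @param min_sep_cM Minimum separation between kept loci; `NULL` (default)
#'   uses the local marker-interval width around each locus.
#' @return Integer vector of design-column indices (possibly empty).
#' @export
prune_selected <- function(fit, min_sep_cM = NULL) {
  stopifnot(inherits(fit, "irlasso"))
  b <- fit$coefficients[-1]
  nz <- which(b != 0)
  if (!length(nz)) return(integer())
  grid <- fit$regressors$grid
  map <- attr(grid, "map")
  loc <- fit$design$locus[nz]
  sep <- if (is.null(min_sep_cM)) {
    # width of the marker interval containing each locus (at a marker: the
    # wider of the two adjacent intervals)
    vapply(loc, function(i) {
      rows <- which(map$chrom == grid$chrom[i])
      w <- diff(map$pos_cM[rows])
      k <- findInterval(grid$pos_cM[i], map$pos_cM[rows],
                        all.inside = TRUE)
      max(w[max(k - 1, 1):min(k, length(w))])
    }, numeric(1))
  } else rep(min_sep_cM, length(loc))
  ord <- order(-abs(b[nz]), grid$pos_cM[loc])
  keep <- logical(length(nz))
  for (i in ord) {
    prev <- which(keep & fit$design$type[nz] == fit$design$type[nz[i]] &
                    grid$chrom[loc] == grid$chrom[loc[i]])
    if (!length(prev) ||
        all(abs(grid$pos_cM[loc[prev]] - grid$pos_cM[loc[i]]) >=
              pmax(sep[prev], sep[i])))
      keep[i] <- TRUE
  }
  sort(nz[keep])
}

# latent-scale residual variance per family/link, used for heritability
residual_latent_variance <- function(fam, mu, dispersion = 1) {
  if (fam$family == "gaussian") return(dispersion)
  if (fam$family == "binomial") {
    return(switch(fam$link,
                  logit = pi^2 / 3,
                  probit = 1,
                  cloglog = pi^2 / 6,
                  log = mean((1 - mu) / mu)))
  }
  # poisson: delta-method variance of y on the link scale
  switch(fam$link,
         log = mean(1 / mu),
         identity = mean(mu),
         sqrt = 0.25)
}

#' QTL heritability from effect sizes and regressor variances
#'
#' Proportion of latent-scale phenotypic variance attributed to each locus:
#' `h2_j = b_j^2 v_j / (sum_l b_l^2 v_l + sigma2_res)`, where `v_j` is the
#' genotype-indicator variance at locus j and `sigma2_res` the residual
#' variance on the link (liability) scale: `pi^2/3` for logit, 1 for probit,
#' `pi^2/6` for cloglog, the estimated dispersion for gaussian, and a
#' delta-method value based on the fitted means for Poisson.
#'
#' @param effect Effect estimates (vector).
#' @param regressor_variance Indicator variance per locus
#'   (`Var(d) + mean(c)` by the law of total variance).
#' @param residual_variance Residual variance on the link scale.
#' @return Heritability per locus, each in \[0, 1).
#' @export
heritability <- function(effect, regressor_variance, residual_variance) {
  stopifnot(length(effect) == length(regressor_variance),
            all(regressor_variance >= 0), residual_variance > 0)
  gen <- effect^2 * regressor_variance
  gen / (sum(gen) + residual_variance)
}

#' Post-selection GLM refit
#'
#' Unpenalized IRLS fit of the selected loci (plus intercept) on the
#' psi-standardized design; the covariance of the estimates is the inverse
#' weighted information matrix.  `psi` starts from the over-dispersion state
#' reached by the penalized fit (whose shrunken effects understate it) and is
#' refreshed from the unpenalized estimates between IRLS rounds until the
#' two stabilize (at most `psi_updates` refreshes).  The alternation undoes
#' the attenuation that genotype-imputation variance causes on the link
#' scale; with the probit link the latent-liability algebra makes the fixed
#' point the natural estimate.
#'
#' @param y Phenotype vector (counts for binomial).
#' @param X Indicator matrix of selected columns (n x s).
#' @param C Conditional-variance matrix of the same columns.
#' @param fam A `"qtl_family"`.
#' @param trials Binomial denominator.
#' @param weighted Use over-dispersion standardization (default) or hold
#'   `psi = 1` (the unweighted variant).
#' @param psi Starting over-dispersion vector (pass the penalized fit
#'   state; default all 1).
#' @param psi_updates Maximum number of psi refreshes from the refit
#'   estimates (0 holds `psi` fixed; the default iterates to the
#'   alternation fixed point).
#' @param maxit,tol IRLS controls.
#' @return List with `beta` (intercept first), `cov`, `se`, `t`, `p`,
#'   `neglog10p`, `psi`, `df`, `dispersion`, `mu`, `kept` (columns retained
#'   after any rank-deficiency drop).
#' @export
refit_glm <- function(y, X, C, fam, trials = 1, weighted = TRUE,
                      psi = NULL, psi_updates = 25,
                      maxit = 100, tol = 1e-8) {
  n <- length(y)
  X <- as.matrix(X)
  s <- ncol(X)
  if (s >= n) stop("more selected loci than individuals")
  trials <- rep(trials, length.out = n)
  yy <- if (fam$family == "binomial") y / trials else y
  kept <- seq_len(s)
  if (s > 0) {
    qrX <- qr(cbind(1, X))
    if (qrX$rank < s + 1) {
      drop_cols <- sort(qrX$pivot[-seq_len(qrX$rank)]) - 1L
      warning("dropping ", length(drop_cols), " collinear column(s) from refit")
      kept <- setdiff(kept, drop_cols)
      X <- X[, kept, drop = FALSE]
      C <- C[, kept, drop = FALSE]
      s <- ncol(X)
    }
  }
  beta <- c(intercept_fit(rep(1, n), yy, fam, trials), rep(0, s))
  if (is.null(psi) || !weighted) psi <- rep(1, n)
  XWX <- NULL
  # contraction guard for the psi alternation: when a refresh moves the
  # coefficients more than the previous one did, the fixed-point map is
  # diverging (psi and the effects inflate each other without bound, which
  # happens in data-sparse fits); revert to the last contracting iterate
  delta_prev <- Inf
  beta_prev <- beta
  psi_prev <- psi
  for (outer in seq_len(psi_updates + 1)) {
    Xs <- standardized_design(cbind(1, X), psi)
    # IRLS to convergence at fixed psi, with step-halving on divergence
    dev_old <- Inf
    for (it in seq_len(maxit)) {
      eta <- as.vector(Xs %*% beta)
      wq <- working_quantities(yy, eta, fam, trials)
      XW <- Xs * wq$w
      XWX <- crossprod(XW, Xs)
      bnew <- tryCatch(solve(XWX, crossprod(XW, wq$z)),
                       error = function(e) NULL)
      if (is.null(bnew)) stop("singular information matrix in refit")
      bnew <- as.vector(bnew)
      dev <- fam$deviance(yy, fam$linkinv(as.vector(Xs %*% bnew)), trials)
      halved <- 0
      while (!is.finite(dev) || dev > dev_old + 1e-8) {
        if (halved >= 20) break
        bnew <- (bnew + beta) / 2
        dev <- fam$deviance(yy, fam$linkinv(as.vector(Xs %*% bnew)), trials)
        halved <- halved + 1
      }
      if (!is.finite(dev)) stop("IRLS diverged in refit")
      delta <- max(abs(bnew - beta))
      beta <- bnew
      dev_old <- dev
      if (delta < tol) break
    }
    if (!weighted || s == 0 || outer > psi_updates) break
    delta_round <- max(abs(beta - beta_prev))
    if (outer > 1 && delta_round > delta_prev) {
      beta <- beta_prev
      psi <- psi_prev
      break
    }
    delta_prev <- delta_round
    beta_prev <- beta
    psi_prev <- psi
    psi_new <- overdispersion(beta[-1], C)
    if (max(abs(psi_new - psi)) < 1e-6) { psi <- psi_new; break }
    psi <- psi_new
  }
  Xs <- standardized_design(cbind(1, X), psi)
  eta <- as.vector(Xs %*% beta)
  wq <- working_quantities(yy, eta, fam, trials)
  XWX <- crossprod(Xs * wq$w, Xs)
  dispersion <- if (fam$family == "gaussian") {
    sum(wq$w * (yy - wq$mu)^2) / max(n - s - 1, 1)
  } else 1
  cov <- solve(XWX) * dispersion
  cov <- (cov + t(cov)) / 2
  se <- sqrt(pmax(diag(cov), 0))
  tval <- beta / se
  df <- max(n - s - 1, 1)
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, cov = cov, se = se, t = tval, p = pval,
       neglog10p = -log10(pmax(pval, 1e-300)), psi = psi, df = df,
       dispersion = dispersion, mu = wq$mu, kept = kept)
}

#' Summarize an `irlasso` fit: prune, refit, test
#'
#' Prunes the nonzero effects to one locus per marker interval, refits the
#' selected loci by an unpenalized GLM with over-dispersion alternation, and
#' reports effects, standard errors, t statistics, -log10 p-values and
#' heritabilities; with a `threshold`, loci exceeding the genome-wide
#' critical value are flagged as QTL calls.
#'
#' @param object An `"irlasso"` object.
#' @param threshold Optional `"qtl_threshold"` (or a numeric critical value
#'   on the -log10 p scale).
#' @param prune Apply the one-locus-per-interval rule (default `TRUE`).
#' @param ... Unused.
#' @return An object of class `"summary.irlasso"` with components `table`
#'   (one row per selected locus), `refit`, `threshold`, `calls`
#'   (rows of `table` exceeding the threshold), `intercept`.
#' @export
summary.irlasso <- function(object, threshold = NULL, prune = TRUE, ...) {
  sel <- if (prune) prune_selected(object) else
    which(object$coefficients[-1] != 0)
  des <- object$design
  fam <- object$family
  refit <- refit_glm(object$y, des$X[, sel, drop = FALSE],
                     des$C[, sel, drop = FALSE], fam, object$trials,
                     weighted = object$mode == "weighted",
                     psi = object$psi)
  sel <- sel[refit$kept]
  grid <- object$regressors$grid
  loc <- des$locus[sel]
  varx <- apply(des$X[, sel, drop = FALSE], 2, stats::var) +
    colMeans(des$C[, sel, drop = FALSE])
  res_var <- residual_latent_variance(fam, refit$mu, refit$dispersion)
  crit <- if (inherits(threshold, "qtl_threshold")) threshold$critical_value
          else threshold
  tab <- data.frame(
    chrom = grid$chrom[loc],
    pos_cM = grid$pos_cM[loc],
    genome_cM = grid$genome_cM[loc],
    type = des$type[sel],
    effect = refit$beta[-1],
    penalized = unname(object$coefficients[-1][sel]),
    se = refit$se[-1],
    t = refit$t[-1],
    neglog10p = refit$neglog10p[-1],
    h2 = if (length(sel)) heritability(refit$beta[-1], varx, res_var) else numeric(),
    stringsAsFactors = FALSE)
  tab$significant <- if (!is.null(crit)) tab$neglog10p >= crit
                     else rep(NA, nrow(tab))
  out <- list(table = tab, refit = refit, threshold = threshold,
              calls = if (!is.null(crit)) tab[which(tab$significant), , drop = FALSE],
              intercept = refit$beta[1], fit = object)
  class(out) <- "summary.irlasso"
  out
}

#' @export
print.summary.irlasso <- function(x, digits = 3, ...) {
  cat("Post-selection GLM refit:", nrow(x$table), "selected loci, intercept",
      signif(x$intercept, digits), "\n")
  if (nrow(x$table)) {
    tab <- x$table
    tab[] <- lapply(tab, function(col) if (is.numeric(col)) signif(col, digits) else col)
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$threshold)) {
    crit <- if (inherits(x$threshold, "qtl_threshold"))
      x$threshold$critical_value else x$threshold
    cat("Genome-wide -log10(p) threshold:", signif(crit, digits), "->",
        nrow(x$calls), "QTL call(s)\n")
  }
  invisible(x)
}

#' @export
plot.summary.irlasso <- function(x, ...) {
  grid <- x$fit$regressors$grid
  map <- attr(grid, "map")
  graphics::plot(x$table$genome_cM, x$table$neglog10p, type = "h",
                 xlim = c(0, sum(chrom_lengths(map))),
                 xlab = "genome position (cM)", ylab = "-log10(p)", ...)
  if (!is.null(x$threshold)) {
    crit <- if (inherits(x$threshold, "qtl_threshold"))
      x$threshold$critical_value else x$threshold
    graphics::abline(h = crit, lty = 2)
  }
  genome_rules(map)
  invisible(x)
}

# run the full pipeline (fit -> prune -> refit) and return the genome-wide
# maximum -log10 p over selected loci (0 when nothing is selected)
max_neglog10p <- function(y, rs, family, link, trials, ...) {
  fit <- irlasso(y, rs, family = family, link = link, trials = trials, ...)
  summ <- summary(fit)
  if (nrow(summ$table)) max(summ$table$neglog10p) else 0
}

#' Genome-wide significance threshold
#'
#' Critical value on the -log10(p) scale for the genome-wide maximum test
#' statistic, from either (a) repeated simulation under the null model with
#' zero genetic effects, or (b) permutation of the observed phenotypes
#' against whole genotype rows (preserving marker linkage).  Each replicate
#' runs the full pipeline (penalized fit, pruning, refit, t tests) and
#' records the maximum -log10 p; the critical value is the empirical
#' `1 - level` quantile (order statistic `ceiling((1 - level) * R)`).
#'
#' @param x A `"sim_spec"` (method `"null_sim"`; its QTL effects are
#'   ignored) or a list with elements `pheno`, `regressors`, `trials`
#'   (method `"permutation"`).
#' @param method `"null_sim"` or `"permutation"`.
#' @param n_replicates Number of replicates (>= 20).
#' @param level Genome-wide type-I error rate (default 0.05).
#' @param seed Integer seed.
#' @param grid_step Grid step in cM for null-simulation replicates.
#' @param ... Passed to [irlasso()] (e.g. `lambda_rule`, `mode`).
#' @return An object of class `"qtl_threshold"`.
#' @export
qtl_threshold <- function(x, method = c("null_sim", "permutation"),
                          n_replicates = 1000, level = 0.05, seed = 1,
                          grid_step = 1, ...) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 20, level > 0, level < 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  maxima <- rep(NA_real_, n_replicates)
  if (method == "null_sim") {
    stopifnot(inherits(x, "sim_spec"))
    grid <- locus_grid(x$map, grid_step)
    for (r in seq_len(n_replicates)) {
      maxima[r] <- tryCatch({
        sc <- simulate_null(x$map, x$design, x$family, x$link, x$n,
                            mu0 = x$mu0, trials = x$trials,
                            seed = rep_seeds[r])
        rs <- build_regressors(sc$marker_geno, grid, x$design, x$coding)
        max_neglog10p(sc$pheno, rs, x$family, x$link, x$trials,
                      seed = rep_seeds[r], ...)
      }, error = function(e) NA_real_)
    }
  } else {
    stopifnot(!is.null(x$pheno), inherits(x$regressors, "regressor_set"))
    trials <- if (is.null(x$trials)) 1 else x$trials
    fam_name <- x$family
    link <- x$link
    for (r in seq_len(n_replicates)) {
      maxima[r] <- tryCatch({
        set.seed(rep_seeds[r])
        yperm <- sample(x$pheno)
        max_neglog10p(yperm, x$regressors, fam_name, link, trials,
                      seed = rep_seeds[r], ...)
      }, error = function(e) NA_real_)
    }
  }
  dropped <- sum(is.na(maxima))
  if (dropped > 0.05 * n_replicates)
    stop("more than 5% of threshold replicates failed (", dropped, "/",
         n_replicates, ")")
  ok <- maxima[!is.na(maxima)]
  crit <- sort(ok)[ceiling((1 - level) * length(ok))]
  out <- list(level = level, critical_value = crit, method = method,
              n_replicates = length(ok), dropped = dropped, seed = seed,
              maxima = ok)
  class(out) <- "qtl_threshold"
  out
}

#' @export
print.qtl_threshold <- function(x, ...) {
  cat("Genome-wide ", 100 * (1 - x$level), "% threshold (", x$method, ", ",
      x$n_replicates, " replicates): -log10(p) >= ",
      signif(x$critical_value, 4), "\n", sep = "")
  invisible(x)
}

#' Declare QTLs from a summarized fit and a threshold
#'
#' @param summ A `"summary.irlasso"`.
#' @param threshold A `"qtl_threshold"` or numeric critical value.
#' @return Data frame of QTL calls (possibly 0 rows): position, type,
#'   effect, se, t, -log10 p, heritability.
#' @export
call_qtls <- function(summ, threshold) {
  stopifnot(inherits(summ, "summary.irlasso"))
  crit <- if (inherits(threshold, "qtl_threshold")) threshold$critical_value
          else threshold
  summ$table[summ$table$neglog10p >= crit, , drop = FALSE]
}

#' Power and parameter-recovery experiment over simulated replicates
#'
#' Repeatedly simulates the scenario, runs the chosen mapping method(s),
#' and scores each true QTL: a replicate detects a QTL when a significant
#' call of the matching effect type lies within `match_radius_cM` of its true
#' position.  Positions and effects are summarized over detecting replicates;
#' for the unweighted method (`"UWglmnet"`) the reported effect is the raw
#' penalized coefficient, for the weighted method (`"IRglmnet"`) the
#' post-selection refit estimate.
#'
#' @param spec A `"sim_spec"` with true QTLs.
#' @param threshold A `"qtl_threshold"` or numeric critical value.
#' @param n_replicates Number of simulation replicates.
#' @param methods Subset of `c("IRglmnet", "UWglmnet")`.
#' @param match_radius_cM Detection radius (default 10, one marker interval).
#' @param grid_step Grid step in cM.
#' @param seed Integer seed.
#' @param ... Passed to [irlasso()] (e.g. `lambda_rule`).
#' @return An object of class `"qtl_power"`: data frame with one row per
#'   true QTL per method (power in percent, mean/SD of detected position and
#'   effect), with the per-replicate detections in attribute `"detections"`.
#' @export
power_experiment <- function(spec, threshold, n_replicates = 100,
                             methods = c("IRglmnet", "UWglmnet"),
                             match_radius_cM = 10, grid_step = 1, seed = 1,
                             ...) {
  stopifnot(inherits(spec, "sim_spec"), nrow(spec$qtl) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  crit <- if (inherits(threshold, "qtl_threshold")) threshold$critical_value
          else threshold
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  grid <- locus_grid(spec$map, grid_step)
  qpos <- cumulative_position(spec$map, spec$qtl$chrom, spec$qtl$pos_cM)
  nq <- length(qpos)
  rec <- expand.grid(rep = seq_len(n_replicates), qtl = seq_len(nq),
                     method = methods, stringsAsFactors = FALSE)
  rec$detected <- FALSE; rec$pos <- NA_real_; rec$effect <- NA_real_
  for (r in seq_len(n_replicates)) {
    sc <- simulate_cross(spec, seed = rep_seeds[r])
    rs <- build_regressors(sc$marker_geno, grid, spec$design, spec$coding)
    for (m in methods) {
      mode <- if (m == "IRglmnet") "weighted" else "unweighted"
      res <- tryCatch({
        fit <- irlasso(sc$pheno, rs, spec$family, spec$link, spec$trials,
                       mode = mode, seed = rep_seeds[r], ...)
        summary(fit, threshold = crit)
      }, error = function(e) NULL)
      if (is.null(res) || is.null(res$calls) || !nrow(res$calls)) next
      calls <- res$calls[res$calls$type == "add", , drop = FALSE]
      if (!nrow(calls)) next
      for (q in seq_len(nq)) {
        dists <- abs(calls$genome_cM - qpos[q])
        hit <- which.min(dists)
        if (dists[hit] <= match_radius_cM) {
          i <- which(rec$rep == r & rec$qtl == q & rec$method == m)
          rec$detected[i] <- TRUE
          rec$pos[i] <- calls$genome_cM[hit]
          rec$effect[i] <- calls$effect[hit]
        }
      }
    }
  }
  agg <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(seq_len(nq), function(q) {
      d <- rec[rec$method == m & rec$qtl == q, ]
      det <- d[d$detected, ]
      data.frame(qtl = q, method = m,
                 true_pos = qpos[q], true_effect = spec$qtl$effect[q],
                 power = 100 * mean(d$detected),
                 mean_pos = mean(det$pos), sd_pos = stats::sd(det$pos),
                 mean_effect = mean(det$effect),
                 sd_effect = stats::sd(det$effect),
                 n_detected = nrow(det))
    }))
  }))
  rownames(agg) <- NULL
  attr(agg, "detections") <- rec
  attr(agg, "n_replicates") <- n_replicates
  class(agg) <- c("qtl_power", "data.frame")
  agg
}

#' @export
print.qtl_power <- function(x, digits = 3, ...) {
  cat("QTL detection experiment:", attr(x, "n_replicates"), "replicates\n")
  y <- as.data.frame(x)
  y[] <- lapply(y, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(y, row.names = FALSE)
  invisible(x)
}
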