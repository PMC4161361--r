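#' Per-individual over-dispersion from imputed genotypes
#'
#' Replacing unknown QTL genotypes by their conditional expectations leaves
#' residual genotype uncertainty in the model; for individual i it inflates
#' the dispersion to `psi_i = 1 + sum_j b_j^2 c_ij`, where `c_ij` is the
#' conditional variance of the indicator at locus j.
#'
#' @param b Effect vector over the design columns (additive, plus dominance
#'   for F2, in the column order of [regressor_design()]).
#' @param regressors A `"regressor_set"` or the conditional-variance matrix.
#' @return Numeric vector `psi` (>= 1, one per individual).
#' @export
overdispersion <- function(b, regressors) {
  C <- if (inherits(regressors, "regressor_set"))
    regressor_design(regressors)$C else regressors
  stopifnot(ncol(C) == length(b))
  psi <- 1 + as.vector(C %*% (b^2))
  psi
}

#' Row-standardize a design by the over-dispersion
#'
#' Divides row i of the design (intercept column included) by `sqrt(psi_i)`,
#' so the working linear predictor becomes
#' `eta*_i = (mu0 + sum_j d_ij b_j) / sqrt(psi_i)`.
#'
#' @param X Design matrix (intercept column included).
#' @param psi Over-dispersion vector (all >= 1).
#' @return The standardized matrix.
#' @export
standardized_design <- function(X, psi) {
  stopifnot(nrow(X) == length(psi))
  if (any(psi < 1 - 1e-8)) stop("internal invariant violated: psi < 1")
  X / sqrt(psi)
}

#' Assemble the genome-wide design from a regressor set
#'
#' @param rs A `"regressor_set"`.
#' @return List with `X` (expected indicators, n x p), `C` (conditional
#'   variances), `locus` (grid row index per column), `type` (`"add"` or
#'   `"dom"` per column).
#' @export
regressor_design <- function(rs) {
  stopifnot(inherits(rs, "regressor_set"))
  if (is.null(rs$d_dom)) {
    list(X = rs$d, C = rs$c, locus = seq_len(ncol(rs$d)),
         type = rep("add", ncol(rs$d)))
  } else {
    k <- ncol(rs$d)
    X <- cbind(rs$d, rs$d_dom)
    colnames(X) <- c(paste0(colnames(rs$d), ":a"), paste0(colnames(rs$d), ":d"))
    list(X = X, C = cbind(rs$c, rs$c_dom), locus = rep(seq_len(k), 2),
         type = rep(c("add", "dom"), each = k))
  }
}

#' Iteratively reweighted LASSO for multiple-QTL mapping
#'
#' Fits the over-saturated GLM with one genetic effect per putative locus by
#' L1-penalized coordinate descent inside IRLS, alternating with updates of
#' the per-individual over-dispersion caused by Haley-Knott genotype
#' imputation:
#' \enumerate{
#'   \item initialize all effects at zero and `psi = 1`;
#'   \item fit the unweighted penalized GLM (lambda chosen by
#'     cross-validation, a BIC path rule, or fixed);
#'   \item update `psi_i = 1 + sum_j b_j^2 c_ij` from the nonzero effects;
#'   \item refit the penalized GLM on the psi-standardized design;
#'   \item alternate 3-4 until the maximum coefficient change falls below
#'     `outer_tol` (or `outer_maxit` is reached).
#' }
#' `mode = "unweighted"` stops after step 2 (the fast variant that ignores
#' over-dispersion heterogeneity).
#'
#' @param y Phenotype vector (binary/count; binomial successes with
#'   `trials > 1`; numeric for gaussian).
#' @param regressors A `"regressor_set"` from [build_regressors()].
#' @param family,link Trait family and link (see [qtl_family()]).
#' @param trials Binomial denominator (scalar or per-individual).
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @param lambda_rule `"cv"` (default), `"bic"` or `"aic"` (fast
#'   information-criterion path rules, no cross-validation),
#'   `"ratio"` (fast, no selection: lambda is the `lambda_ratio` fraction of
#'   the data's lambda_max, the liberal path-end convention whose redundant
#'   loci are removed by pruning and the refit t-tests), or `"fixed"`
#'   (supply `lambda`).
#' @param lambda Penalty when `lambda_rule = "fixed"`.
#' @param lambda_ratio Fraction of lambda_max used by `"ratio"`.
#' @param n_lambda,lambda_min_ratio Path controls.
#' @param cv_folds Folds for `"cv"`.
#' @param cv_each_iteration Re-select lambda at every outer iteration
#'   (default `FALSE`: lambda is chosen once at step 2 and reused).
#' @param standardize Penalize on the unit-variance column scale (default
#'   `TRUE`, the usual LASSO convention): between-marker regressors are
#'   variance-attenuated by genotype uncertainty, and standardization keeps
#'   the selection from snapping to the flanking markers.  Effects are
#'   always reported on the genotype-coding scale.
#' @param outer_tol,outer_maxit Outer-loop convergence controls.
#' @param seed Seed for the cross-validation fold split.
#' @return An object of class `"irlasso"`; see Details for components.
#' @details The returned object contains `coefficients` (intercept followed
#'   by the sparse genome-wide effect vector), `psi`, `lambda`,
#'   `outer_iterations`, `converged`, `mode`, the family, and the regressor
#'   set (for methods).  Use [summary.irlasso()] for post-selection refit,
#'   t statistics and QTL calls.
#' @examples
#' spec <- backcross_10qtl_spec("binary", 150)
#' sc <- simulate_cross(spec, seed = 7)
#' rs <- build_regressors(sc$marker_geno, locus_grid(spec$map, 2), "backcross")
#' fit <- irlasso(sc$pheno, rs, "binomial", lambda_rule = "bic")
#' fit
#' @export
irlasso <- function(y, regressors, family = c("binomial", "poisson", "gaussian"),
                    link = NULL, trials = 1,
                    mode = c("weighted", "unweighted"),
                    lambda_rule = c("cv", "bic", "aic", "ratio", "fixed"),
                    lambda = NULL, lambda_ratio = 0.1,
                    n_lambda = 30, lambda_min_ratio = NULL, cv_folds = 5,
                    cv_each_iteration = FALSE, standardize = TRUE,
                    outer_tol = 1e-4, outer_maxit = 25, seed = 1) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  lambda_rule <- match.arg(lambda_rule)
  fam <- qtl_family(family, link)
  des <- regressor_design(regressors)
  n <- length(y)
  stopifnot(nrow(des$X) == n)
  trials <- rep(trials, length.out = n)
  yy <- if (family == "binomial") {
    if (any(y < 0 | y > trials | y != round(y)))
      stop("binomial phenotypes must be integer counts in [0, trials]")
    y / trials
  } else y
  if (family == "poisson" && any(y < 0 | y != round(y)))
    stop("Poisson phenotypes must be non-negative integers")
  if (lambda_rule == "fixed" && is.null(lambda))
    stop("lambda_rule = \"fixed\" requires lambda")

  p <- ncol(des$X)
  Xs1 <- cbind(`(Intercept)` = 1, des$X)
  pf <- if (standardize) column_sd_pf(des$X) else rep(1, p)

  select_lambda <- function(Xs) {
    switch(lambda_rule,
      cv = {
        cv <- cv_lambda(Xs, yy, fam, trials, folds = cv_folds, seed = seed,
                        n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                        pf = pf)
        list(lambda = cv$lambda_min, cv = cv, path = cv$full_path)
      },
      bic = ,
      aic = {
        k <- if (lambda_rule == "aic") 2 else log(n)
        path <- pen_glm_path(Xs, yy, fam, trials, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio, pf = pf,
                             bic_stop = TRUE, ic_k = k)
        sel <- bic_lambda(path, Xs, yy, fam, trials, k = k)
        list(lambda = sel$lambda, cv = NULL, path = path)
      },
      ratio = {
        lmax <- lambda_max_value(Xs, yy, fam, trials, pf)
        target <- lmax * lambda_ratio
        path <- pen_glm_path(Xs, yy, fam, trials,
                             lambda = lambda_path(lmax, 8, lambda_ratio),
                             pf = pf)
        list(lambda = target, cv = NULL, path = path)
      },
      fixed = list(lambda = lambda, cv = NULL, path = NULL))
  }

  # Step 2: unweighted penalized fit
  sel <- select_lambda(Xs1)
  lam <- sel$lambda
  beta <- if (!is.null(sel$path)) {
    i <- which.min(abs(sel$path$lambda - lam))
    sel$path$beta[, i]
  } else rep(0, p + 1)
  fit2 <- pirls_one(Xs1, yy, fam, trials, lam, beta, pf)
  beta <- fit2$beta

  psi <- rep(1, n)
  outer_iterations <- 1L
  converged <- TRUE
  if (mode == "weighted") {
    converged <- FALSE
    best <- list(beta = beta, obj = Inf, psi = psi)
    obj_prev <- Inf
    best_delta <- Inf
    stalled <- 0
    for (it in seq_len(outer_maxit)) {
      # Step 3: over-dispersion from current nonzero effects
      psi <- overdispersion(beta[-1], des$C)
      Xs <- standardized_design(Xs1, psi)
      # Step 4: penalized fit on the standardized design
      if (cv_each_iteration && lambda_rule != "fixed") {
        sel_it <- select_lambda(Xs)
        lam <- sel_it$lambda
        if (!is.null(sel_it$cv)) sel$cv <- sel_it$cv
      }
      fit4 <- pirls_one(Xs, yy, fam, trials, lam, beta, pf,
                        irls_maxit = 10)
      delta <- max(abs(fit4$beta - beta))
      beta <- fit4$beta
      obj <- penalized_deviance(Xs, yy, fam, trials, beta, lam)
      if (obj < best$obj) best <- list(beta = beta, obj = obj, psi = psi)
      outer_iterations <- it + 1L
      # coefficient convergence, or objective stall (collinear loci let the
      # coefficients drift along a flat objective indefinitely while the
      # deviance improves only in the sixth decimal)
      if (delta < outer_tol ||
          abs(obj - obj_prev) < 2e-6 * (abs(obj_prev) + 0.1)) {
        converged <- TRUE
        break
      }
      # progress stall: the alternation is wandering between near-collinear
      # loci without shrinking its steps; stop and keep the best iterate
      if (delta < 0.95 * best_delta) {
        best_delta <- delta
        stalled <- 0
      } else {
        stalled <- stalled + 1
        if (stalled >= 3) break
      }
      obj_prev <- obj
    }
    if (!converged) {  # oscillation / slow convergence: best iterate wins
      beta <- best$beta
    }
    # report psi at the final coefficients so fitted()/predict() agree
    psi <- overdispersion(beta[-1], des$C)
  }

  coefs <- stats::setNames(beta, c("(Intercept)", colnames(des$X)))
  out <- list(coefficients = coefs, psi = psi, lambda = lam,
              lambda_rule = lambda_rule, cv = sel$cv, mode = mode,
              outer_iterations = outer_iterations, converged = converged,
              family = fam, y = y, trials = trials, regressors = regressors,
              design = des, call = match.call())
  class(out) <- "irlasso"
  out
}

# penalized deviance objective used to pick the best iterate under oscillation
penalized_deviance <- function(Xs, yy, fam, trials, beta, lam) {
  mu <- fam$linkinv(as.vector(Xs %*% beta))
  fam$deviance(yy, mu, trials) / (2 * length(yy)) + lam * sum(abs(beta[-1]))
}

#' @export
print.irlasso <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat("Iteratively reweighted LASSO QTL fit (", x$mode, " mode, ",
      x$family$family, "/", x$family$link, ")\n", sep = "")
  cat("  loci scanned: ", length(x$coefficients) - 1L,
      ", nonzero effects: ", nz, "\n", sep = "")
  cat("  lambda = ", signif(x$lambda, 4), " (", x$lambda_rule, "), ",
      "outer iterations: ", x$outer_iterations,
      if (!x$converged) " (not converged)", "\n", sep = "")
  cat("  over-dispersion psi: [", signif(min(x$psi), 4), ", ",
      signif(max(x$psi), 4), "]\n", sep = "")
  invisible(x)
}

#' Coefficients of an `irlasso` fit
#' @param object An `"irlasso"` object.
#' @param nonzero Return only the intercept and nonzero effects?
#' @param ... Unused.
#' @export
coef.irlasso <- function(object, nonzero = FALSE, ...) {
  cf <- object$coefficients
  if (nonzero) cf[c(TRUE, cf[-1] != 0)] else cf
}

# standardized linear predictor at the training data
irlasso_eta <- function(object) {
  Xs1 <- cbind(1, object$design$X)
  as.vector(standardized_design(Xs1, object$psi) %*% object$coefficients)
}

#' Fitted means of an `irlasso` fit
#' @param object An `"irlasso"` object.
#' @param ... Unused.
#' @export
fitted.irlasso <- function(object, ...) {
  object$family$linkinv(irlasso_eta(object))
}

#' Predict from an `irlasso` fit
#'
#' @param object An `"irlasso"` object.
#' @param newdata A `"regressor_set"` (over-dispersion standardization is
#'   applied with the fitted effects), a plain indicator matrix conformable
#'   with the design columns (taken as exact genotypes, `psi = 1`), or
#'   `NULL` for the training data.
#' @param type `"link"` (standardized linear predictor) or `"response"`.
#' @param ... Unused.
#' @export
predict.irlasso <- function(object, newdata = NULL,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- irlasso_eta(object)
  } else {
    b <- object$coefficients[-1]
    if (inherits(newdata, "regressor_set")) {
      des <- regressor_design(newdata)
      psi <- overdispersion(b, des$C)
      eta <- (object$coefficients[1] + as.vector(des$X %*% b)) / sqrt(psi)
    } else {
      X <- as.matrix(newdata)
      stopifnot(ncol(X) == length(b))
      eta <- object$coefficients[1] + as.vector(X %*% b)
    }
  }
  if (type == "link") eta else object$family$linkinv(eta)
}

#' Residuals of an `irlasso` fit
#' @param object An `"irlasso"` object.
#' @param type `"response"`, `"pearson"` or `"working"`.
#' @param ... Unused.
#' @export
residuals.irlasso <- function(object,
                              type = c("response", "pearson", "working"), ...) {
  type <- match.arg(type)
  fam <- object$family
  eta <- irlasso_eta(object)
  mu <- fam$linkinv(eta)
  yy <- if (fam$family == "binomial") object$y / object$trials else object$y
  switch(type,
         response = yy - mu,
         pearson = (yy - mu) / sqrt(fam$variance(mu) * object$psi / object$trials),
         working = (yy - mu) * fam$gprime(mu))
}

#' Simulate phenotypes from a fitted model
#'
#' Draws new phenotype vectors from the trait family at the fitted means.
#'
#' @param object An `"irlasso"` object.
#' @param nsim Number of replicate vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.irlasso <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- length(mu)
  draws <- replicate(nsim, switch(object$family$family,
    gaussian = stats::rnorm(n, mu, 1),
    poisson = stats::rpois(n, mu),
    binomial = stats::rbinom(n, object$trials, mu)))
  as.data.frame(draws)
}

#' Profile plot of an `irlasso` fit
#'
#' Plots the penalized genetic-effect profile along the genome (or the
#' -log10 p profile of a [summary.irlasso()]); chromosome boundaries are
#' dashed, marker positions ticked.
#'
#' @param x An `"irlasso"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.irlasso <- function(x, ...) {
  grid <- x$regressors$grid
  map <- attr(grid, "map")
  b <- x$coefficients[-1]
  add <- x$design$type == "add"
  pos <- grid$genome_cM[x$design$locus[add]]
  graphics::plot(pos, b[add], type = "h", xlab = "genome position (cM)",
                 ylab = "penalized genetic effect", ...)
  genome_rules(map)
  invisible(x)
}

# chromosome separators + marker ticks for genome-wide profile plots
genome_rules <- function(map) {
  len <- chrom_lengths(map)
  graphics::abline(v = cumsum(unname(len))[-length(len)], lty = 3, col = "grey")
  mk <- cumulative_position(map, map$chrom, map$pos_cM)
  graphics::axis(1, at = mk, labels = FALSE, tcl = -0.2)
}
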