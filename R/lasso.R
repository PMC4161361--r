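#' Soft-threshold operator
#'
#' The scalar solution of the one-dimensional LASSO problem:
#' `sign(rho) * max(|rho| - lambda, 0)`.
#'
#' @param rho Numeric vector.
#' @param lambda Non-negative threshold.
#' @return Thresholded values.
#' @export
soft_threshold <- function(rho, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  sign(rho) * pmax(abs(rho) - lambda, 0)
}

#' Weighted LASSO by coordinate descent
#'
#' Minimizes `(1/(2n)) sum_i w_i (z_i - sum_j X_ij beta_j)^2 +
#' lambda * sum_j pf_j |beta_j|` by cyclic coordinate descent with
#' soft-thresholding and active-set iteration.  Weights are normalized to
#' mean 1 internally so `lambda` is comparable across sample sizes.
#'
#' @param X Design matrix (include an intercept column yourself and give it
#'   penalty factor 0 if an unpenalized intercept is wanted).
#' @param z Response vector.
#' @param w Positive observation weights (default 1).
#' @param lambda Penalty.
#' @param penalty_factor Per-column multiplier on `lambda` (default 1;
#'   0 leaves a column unpenalized).
#' @param beta_init Warm-start coefficients (default 0).
#' @param tol Convergence tolerance on the curvature-weighted squared
#'   coefficient change `max_j q_j (delta beta_j)^2` per sweep (the default
#'   `1e-14` corresponds to coefficient changes of about `1e-7` on
#'   unit-variance columns).
#' @param max_sweeps Sweep cap; exceeding it yields a warning, not an error.
#' @return List with `beta`, `sweeps`, `converged`, `objective`.
#' @examples
#' X <- cbind(1, matrix(rnorm(40), 20))
#' fit <- weighted_lasso(X, rnorm(20), lambda = 0.1, penalty_factor = c(0, 1, 1))
#' @export
weighted_lasso <- function(X, z, w = rep(1, length(z)), lambda,
                           penalty_factor = rep(1, ncol(X)),
                           beta_init = rep(0, ncol(X)),
                           tol = 1e-14, max_sweeps = 1e5) {
  stopifnot(nrow(X) == length(z), length(w) == length(z),
            length(penalty_factor) == ncol(X), lambda >= 0,
            all(is.finite(z)), all(is.finite(w)), all(w > 0))
  wn <- w / mean(w)
  res <- .cd_solve(X, z, wn, lambda, penalty_factor, beta_init, tol,
                   as.integer(max_sweeps))
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_sweeps, " sweeps")
  res$objective <- .cd_objective(X, z, wn, lambda, penalty_factor, res$beta)
  res
}

#' Geometric lambda path
#'
#' @param lambda_max Largest penalty (typically the smallest value that
#'   zeroes every penalized coefficient).
#' @param n_lambda Path length.
#' @param lambda_min_ratio Ratio of smallest to largest lambda.
#' @return Strictly decreasing lambda grid.
#' @export
lambda_path <- function(lambda_max, n_lambda = 30, lambda_min_ratio = 0.05) {
  stopifnot(n_lambda >= 1, lambda_min_ratio > 0, lambda_min_ratio <= 1)
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    warning("degenerate data: lambda_max is not positive; using lambda = 0")
    return(0)
  }
  if (n_lambda == 1) return(lambda_max)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

# --- penalized GLM via IRLS + coordinate descent ---------------------------

# IRLS working response and weights at linear predictor eta.
# y is the observed proportion for binomial (trials = denominator).
working_quantities <- function(y, eta, fam, trials = 1) {
  mu <- fam$linkinv(eta)
  gp <- fam$gprime(mu)
  z <- eta + (y - mu) * gp
  w <- trials / (fam$variance(mu) * gp^2)
  list(z = z, w = w, mu = mu)
}

# Fit the weighted-LASSO GLM at a single lambda by penalized IRLS.
# Xs: design INCLUDING the (possibly non-constant) intercept column first.
# pf: penalty factors for the penalized columns; setting pf_j to the SD of
# column j is equivalent to standardizing columns to unit variance before
# penalization (coefficients stay on the original genotype-coding scale).
pirls_one <- function(Xs, y, fam, trials, lambda, beta_init,
                      pf = rep(1, ncol(Xs) - 1L),
                      irls_tol = 1e-6, irls_maxit = 20, cd_tol = 1e-7) {
  pf <- c(0, pf)
  beta <- beta_init
  converged <- FALSE
  obj_old <- Inf
  for (it in seq_len(irls_maxit)) {
    eta <- as.vector(Xs %*% beta)
    wq <- working_quantities(y, eta, fam, trials)
    sol <- .cd_solve(Xs, wq$z, wq$w / mean(wq$w), lambda, pf, beta, cd_tol,
                     100000L)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    # near-collinear grid columns let coefficients wander along a flat
    # objective; a stalled penalized objective also counts as converged
    obj <- penalized_deviance(Xs, y, fam, trials, beta, lambda)
    if (delta < irls_tol ||
        abs(obj - obj_old) < 1e-6 * (abs(obj_old) + 0.1)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  list(beta = beta, iterations = it, converged = converged)
}

# Intercept-only GLM fit (unpenalized) on intercept column x0.
intercept_fit <- function(x0, y, fam, trials) {
  b0 <- fam$linkfun(mean(fam$initialize_mu(y, trials)))
  for (it in 1:50) {
    eta <- x0 * b0
    wq <- working_quantities(y, eta, fam, trials)
    b0_new <- sum(wq$w * x0 * wq$z) / sum(wq$w * x0^2)
    if (!is.finite(b0_new)) break
    if (abs(b0_new - b0) < 1e-8) { b0 <- b0_new; break }
    b0 <- b0_new
  }
  b0
}

# lambda_max: smallest lambda with all penalized coefficients zero, computed
# from the working quantities of the intercept-only fit (glmnet convention).
lambda_max_value <- function(Xs, y, fam, trials, pf = rep(1, ncol(Xs) - 1L)) {
  x0 <- Xs[, 1]
  b0 <- intercept_fit(x0, y, fam, trials)
  wq <- working_quantities(y, x0 * b0, fam, trials)
  wn <- wq$w / mean(wq$w)
  r <- wq$z - x0 * b0
  g <- abs(crossprod(Xs[, -1, drop = FALSE], wn * r)) / length(y)
  max(g / pmax(pf, 1e-8))
}

# Penalized GLM solutions along a lambda path (warm-started, descending).
# Returns list(lambda, beta (p x nlambda)).
pen_glm_path <- function(Xs, y, fam, trials, lambda = NULL, n_lambda = 30,
                         lambda_min_ratio = NULL,
                         pf = rep(1, ncol(Xs) - 1L), dfmax = NULL,
                         bic_stop = FALSE, ic_k = NULL) {
  n <- length(y)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (n < ncol(Xs)) 0.05 else 0.01
  if (is.null(lambda)) {
    lmax <- lambda_max_value(Xs, y, fam, trials, pf)
    lambda <- lambda_path(lmax, n_lambda, lambda_min_ratio)
  }
  if (is.null(dfmax)) dfmax <- max(20L, floor(n / 4))
  p <- ncol(Xs)
  B <- matrix(0, p, length(lambda))
  beta <- rep(0, p)
  beta[1] <- intercept_fit(Xs[, 1], y, fam, trials)
  used <- length(lambda)
  bic <- rep(NA_real_, length(lambda))
  rises <- 0
  for (l in seq_along(lambda)) {
    fitl <- pirls_one(Xs, y, fam, trials, lambda[l], beta, pf)
    beta <- fitl$beta
    B[, l] <- beta
    if (sum(beta[-1] != 0) > dfmax) { used <- l; break }
    if (bic_stop) {
      if (is.null(ic_k)) ic_k <- log(n)
      mu <- fam$linkinv(as.vector(Xs %*% beta))
      bic[l] <- fam$deviance(y, mu, trials) + ic_k * sum(beta[-1] != 0)
      # once the information criterion has risen well past its minimum,
      # smaller penalties only add noise loci: stop the descent
      if (l >= 4 && bic[l] > min(bic, na.rm = TRUE) + 1e-8) {
        rises <- rises + 1
        if (rises >= 3) { used <- l; break }
      } else rises <- 0
    }
  }
  list(lambda = lambda[seq_len(used)], beta = B[, seq_len(used), drop = FALSE])
}

# population SD of penalized design columns: used as penalty factors so the
# LASSO acts on unit-variance columns (glmnet's standardize = TRUE)
column_sd_pf <- function(X) {
  n <- nrow(X)
  s <- sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 0))
  pmax(s, 1e-3)
}

# deviance of observations under mean mu
held_out_deviance <- function(fam, y, mu, trials) fam$deviance(y, mu, trials)

#' K-fold cross-validation for the penalized GLM
#'
#' Splits individuals into random folds (seeded), fits the penalized GLM
#' along a shared lambda path on each training set, and scores held-out
#' deviance; the chosen lambda minimizes the mean deviance.
#'
#' @param Xs Design matrix including the intercept column first.
#' @param y Response (proportions for binomial).
#' @param fam A `"qtl_family"`.
#' @param trials Binomial denominator (scalar or vector).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold split.
#' @param n_lambda,lambda_min_ratio Path controls.
#' @param pf Penalty factor per penalized column (column SDs give the
#'   standardized-LASSO convention).
#' @return List of class `"cv_lambda"`: `lambda` (grid), `mean_deviance`,
#'   `sd_deviance`, `lambda_min` (chosen), `folds`, `seed`.
#' @export
cv_lambda <- function(Xs, y, fam, trials = 1, folds = 5, seed = 1,
                      n_lambda = 30, lambda_min_ratio = NULL,
                      pf = rep(1, ncol(Xs) - 1L)) {
  n <- length(y)
  stopifnot(folds >= 2, n >= folds)
  full <- pen_glm_path(Xs, y, fam, trials, n_lambda = n_lambda,
                       lambda_min_ratio = lambda_min_ratio, pf = pf)
  lambda <- full$lambda
  trials <- rep(trials, length.out = n)
  assign_folds <- function(s) {
    set.seed(s)
    sample(rep(seq_len(folds), length.out = n))
  }
  fold_id <- assign_folds(seed)
  if (fam$family == "binomial") {
    # a fold whose training response is constant cannot be fit: redraw once
    const_tr <- function(fid) any(vapply(seq_len(folds), function(f)
      length(unique(y[fid != f])) < 2, logical(1)))
    if (const_tr(fold_id)) {
      fold_id <- assign_folds(seed + 1L)
      if (const_tr(fold_id))
        warning("constant response in a training fold after one redraw")
    }
  }
  dev <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    path_f <- pen_glm_path(Xs[tr, , drop = FALSE], y[tr], fam, trials[tr],
                           lambda = lambda, pf = pf, dfmax = Inf)
    eta_te <- Xs[!tr, , drop = FALSE] %*% path_f$beta
    for (l in seq_along(lambda))
      dev[f, l] <- held_out_deviance(fam, y[!tr], fam$linkinv(eta_te[, l]),
                                     trials[!tr])
  }
  mean_dev <- colMeans(dev)
  out <- list(lambda = lambda, mean_deviance = mean_dev,
              sd_deviance = apply(dev, 2, stats::sd),
              lambda_min = lambda[which.min(mean_dev)],
              folds = folds, seed = seed, fold_id = fold_id,
              full_path = full)
  class(out) <- "cv_lambda"
  out
}

#' @export
print.cv_lambda <- function(x, ...) {
  cat("Cross-validated lambda path (", length(x$lambda), " values, ",
      x$folds, " folds): lambda_min = ", signif(x$lambda_min, 4), "\n", sep = "")
  invisible(x)
}

# Information-criterion selection along the path: deviance + k * df, where
# df is the number of nonzero penalized coefficients and k the per-parameter
# penalty (log(n) for BIC, 2 for AIC).  Used by the fast
# (cross-validation-free) modes.
bic_lambda <- function(path, Xs, y, fam, trials, k = log(length(y))) {
  dev <- df <- numeric(length(path$lambda))
  for (l in seq_along(path$lambda)) {
    mu <- fam$linkinv(as.vector(Xs %*% path$beta[, l]))
    dev[l] <- fam$deviance(y, mu, trials)
    df[l] <- sum(path$beta[-1, l] != 0)
  }
  ic <- dev + k * df
  list(lambda = path$lambda[which.min(ic)], bic = ic, deviance = dev, df = df)
}
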