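#' GLM family for discrete-trait QTL mapping
#'
#' Thin wrapper around [stats::family] objects exposing the pieces the
#' iteratively reweighted LASSO needs: link g, inverse link, link derivative
#' g'(mu) = d eta / d mu, variance function V(mu), and the log-likelihood used
#' for cross-validation deviance.  Supported pairs: gaussian/identity;
#' poisson with log, identity or sqrt links; binomial with logit, probit,
#' cloglog or log links.
#'
#' The inverse link clips binomial means to \[1e-10, 1 - 1e-10\] and Poisson
#' means to >= 1e-10 so that IRLS weights stay finite for extreme linear
#' predictors.
#'
#' @param family_name `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param link_name Link name; `NULL` selects the canonical link
#'   (identity, logit, log).
#' @return An object of class `"qtl_family"`: a list with elements
#'   `family`, `link`, `linkfun(mu)`, `linkinv(eta)` (clipped),
#'   `linkinv_raw(eta)` (unclipped), `mu_eta(eta)`, `gprime(mu)`,
#'   `variance(mu)`, `loglik(y, mu, trials)`, `deviance(y, mu, trials)`,
#'   and `initialize_mu(y, trials)`.
#' @examples
#' fam <- qtl_family("binomial", "logit")
#' fam$linkinv(0)       # 0.5
#' fam$variance(0.5)    # 0.25
#' @export
qtl_family <- function(family_name = c("gaussian", "binomial", "poisson"),
                       link_name = NULL) {
  family_name <- match.arg(family_name)
  supported <- list(gaussian = "identity",
                    poisson = c("log", "identity", "sqrt"),
                    binomial = c("logit", "cloglog", "probit", "log"))
  if (is.null(link_name)) link_name <- supported[[family_name]][1]
  if (!link_name %in% supported[[family_name]])
    stop("unsupported family/link pair: ", family_name, "/", link_name,
         "; supported links for ", family_name, ": ",
         paste(supported[[family_name]], collapse = ", "))
  base <- switch(family_name,
                 gaussian = stats::gaussian(link = link_name),
                 poisson = stats::poisson(link = link_name),
                 binomial = stats::binomial(link = link_name))
  eps <- 1e-10
  clip <- switch(family_name,
                 gaussian = function(mu) mu,
                 poisson = function(mu) pmax(mu, eps),
                 binomial = function(mu) pmin(pmax(mu, eps), 1 - eps))
  linkinv <- function(eta) clip(base$linkinv(eta))
  loglik <- switch(family_name,
    gaussian = function(y, mu, trials = 1) {
      # up to the -n/2 log(2 pi sigma^2) constant, with unit dispersion
      -0.5 * sum((y - mu)^2)
    },
    poisson = function(y, mu, trials = 1) sum(y * log(mu) - mu),
    binomial = function(y, mu, trials = 1) {
      # y is the observed proportion; trials the binomial denominator
      sum(trials * (y * log(mu) + (1 - y) * log(1 - mu)))
    })
  fam <- list(
    family = family_name,
    link = link_name,
    linkfun = function(mu) base$linkfun(clip(mu)),
    linkinv = linkinv,
    linkinv_raw = base$linkinv,
    mu_eta = base$mu.eta,
    gprime = function(mu) 1 / base$mu.eta(base$linkfun(clip(mu))),
    variance = function(mu) pmax(base$variance(clip(mu)),
                                 if (family_name == "gaussian") 1 else eps),
    loglik = loglik,
    deviance = function(y, mu, trials = 1)
      -2 * (loglik(y, clip(mu), trials) - loglik(y, sat_mu(family_name, y), trials)),
    initialize_mu = function(y, trials = 1) switch(family_name,
      gaussian = rep(mean(y), length(y)),
      poisson = rep(max(mean(y), 0.1), length(y)),
      binomial = rep(min(max(mean(y), 0.05), 0.95), length(y)))
  )
  class(fam) <- "qtl_family"
  fam
}

# saturated-model means for deviance (clipped for binomial/poisson zeros)
sat_mu <- function(family_name, y) {
  switch(family_name,
         gaussian = y,
         poisson = pmax(y, 1e-10),
         binomial = pmin(pmax(y, 1e-10), 1 - 1e-10))
}

#' @export
print.qtl_family <- function(x, ...) {
  cat("QTL mapping GLM family:", x$family, "with", x$link, "link\n")
  invisible(x)
}
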