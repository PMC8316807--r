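## Bayesian Gaussian mixed model with nested random intercepts
## (group within species), fitted by conjugate Gibbs sampling.  The model is
##   y_i = x_i' beta + u_species[s(i)] + u_group[g(i)] + e_i,
## beta ~ N(0, 1e10 I) (diffuse), each variance component with a univariate
## inverse-Wishart prior, V = 1 and nu = 0.002, i.e. IG(nu/2, nu V/2).
## Groups are indexed within species, so identical group labels in two
## species never pool.

#' Prior configuration for [fit_lmm()]
#'
#' @param V,nu scale and degrees of freedom of the univariate
#'   inverse-Wishart prior on each variance component (equivalently an
#'   inverse-gamma with shape `nu/2` and scale `nu*V/2`); defaults `V = 1`,
#'   `nu = 0.002` are weakly informative.
#' @param beta_mean,beta_var mean and variance of the independent normal
#'   priors on the fixed effects (default diffuse, variance `1e10`).
#' @return a list of class `prior_config`.
#' @export
prior_config <- function(V = 1, nu = 0.002, beta_mean = 0, beta_var = 1e10) {
  stopifnot(V > 0, nu > 0, beta_var > 0)
  if (beta_mean != 0) stop("only beta_mean = 0 is supported", call. = FALSE)
  structure(list(V = V, nu = nu, beta_mean = beta_mean, beta_var = beta_var),
            class = "prior_config")
}

#' Chain configuration for [fit_lmm()]
#'
#' @param n_iter total Gibbs iterations (default 13000).
#' @param burn_in discarded initial iterations (default 3000).
#' @param thin thinning interval (default 10).
#' @param seed optional integer seed; when given, `set.seed(seed)` is
#'   called before sampling so the fit is fully reproducible.
#' @return a list of class `chain_config`; at least 100 retained samples
#'   are required.
#' @export
chain_config <- function(n_iter = 13000, burn_in = 3000, thin = 10, seed = NULL) {
  stopifnot(n_iter > burn_in, thin >= 1)
  if ((n_iter - burn_in) / thin < 100) {
    stop("chain must retain at least 100 samples", call. = FALSE)
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "chain_config")
}

#' Log10-transform vocal rates for the Gaussian model
#'
#' @param rates numeric vocal rates (bouts/hour) or a data frame with a
#'   `rate` column, e.g. from [vocal_rate()].
#' @param offset added uniformly before the log10 so individuals with zero
#'   observed bouts are retained (default 0.01 bouts/h).
#' @return the transformed response `log10(rate + offset)`.
#' @export
prepare_response <- function(rates, offset = 0.01) {
  if (is.data.frame(rates)) rates <- rates$rate
  if (any(rates < 0)) stop("negative vocal rates", call. = FALSE)
  if (any(rates + offset <= 0)) {
    stop("zero rate with zero offset: log10 undefined; use a positive offset",
         call. = FALSE)
  }
  log10(rates + offset)
}

#' Fit the Gaussian mixed model by Gibbs sampling
#'
#' Fits `formula` (response already on the modelling scale, e.g. from
#' [prepare_response()]) with fixed effects as given and random intercepts
#' for species and for group nested within species, using standard
#' conjugate updates: the fixed-effect block from its multivariate-normal
#' full conditional, each random intercept from its normal full
#' conditional, and each variance from its inverse-gamma full conditional.
#' Predictors enter untransformed, so coefficients are per unit of the raw
#' measure.
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame with the model variables plus the species and
#'   group identifier columns.
#' @param species,group names of the identifier columns (defaults
#'   `"species_id"`, `"group_id"`).
#' @param priors a [prior_config()].
#' @param chain a [chain_config()].
#' @param fixed_variances optional named list fixing any of `species`,
#'   `group`, `resid` to a known value instead of sampling it (used for
#'   calibration checks against generalized least squares).
#' @return an object of class `vocal_lmm` with a coefficient table
#'   (posterior mean, 95% credible interval, pMCMC), retained draws for
#'   fixed effects and variance components, and a variance partition.
#' @seealso [pmcmc()], [variance_partition()]
#' @examples
#' d <- data.frame(y = rnorm(60), x = rnorm(60),
#'                 species_id = rep(c("a", "b", "c"), each = 20),
#'                 group_id = rep(1:6, each = 10))
#' fit <- fit_lmm(y ~ x, d, chain = chain_config(2000, 1000, 10, seed = 1))
#' coef(fit)
#' @export
fit_lmm <- function(formula, data, species = "species_id", group = "group_id",
                    priors = prior_config(), chain = chain_config(),
                    fixed_variances = NULL) {
  stopifnot(inherits(priors, "prior_config"), inherits(chain, "chain_config"))
  for (col in c(species, group)) {
    if (is.null(data[[col]])) stop("column not found in data: ", col, call. = FALSE)
  }
  mf <- model.frame(formula, data, na.action = NULL)
  if (anyNA(mf)) stop("fit_lmm: missing values in model variables", call. = FALSE)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix", call. = FALSE)
  sp_f <- factor(data[[species]])
  gr_f <- factor(paste(data[[species]], data[[group]], sep = "\r"))
  fix <- function(name) {
    v <- fixed_variances[[name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  if (!is.null(chain$seed)) set.seed(chain$seed)
  draws <- .gibbs_lmm_cpp(as.numeric(y), X,
                          as.integer(sp_f) - 1L, as.integer(gr_f) - 1L,
                          priors$V, priors$nu, priors$beta_var,
                          chain$n_iter, chain$burn_in, chain$thin,
                          fix("species"), fix("group"), fix("resid"))
  beta <- draws$beta
  colnames(beta) <- colnames(X)
  sigma2 <- draws$sigma2
  colnames(sigma2) <- c("species", "group", "resid")
  coefs <- data.frame(
    term = colnames(X),
    post_mean = colMeans(beta),
    ci_lower = apply(beta, 2, quantile, 0.025),
    ci_upper = apply(beta, 2, quantile, 0.975),
    pMCMC = apply(beta, 2, pmcmc),
    row.names = NULL, stringsAsFactors = FALSE
  )
  fit <- structure(list(
    call = match.call(), formula = formula, coefficients = coefs,
    beta_draws = beta, sigma2_draws = sigma2,
    u_species = setNames(draws$u_species, levels(sp_f)),
    u_group = setNames(draws$u_group, levels(gr_f)),
    y = as.numeric(y), X = X,
    species = as.character(sp_f), group = as.character(gr_f),
    n = length(y), n_species = nlevels(sp_f), n_groups = nlevels(gr_f),
    priors = priors, chain = chain
  ), class = "vocal_lmm")
  fit$variance_partition <- variance_partition(fit)
  fit
}

#' MCMC sign probability of a posterior sample
#'
#' `pMCMC = 2 * max(1, min(n_pos, n_neg)) / n`, capped at 1: twice the
#' smaller tail proportion of the draws relative to zero, floored at one
#' minority draw so a one-sided sample reports `2/n` rather than 0.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @return a probability in `(0, 1]`.
#' @export
pmcmc <- function(samples) {
  n <- length(samples)
  if (n < 100) stop("pmcmc requires at least 100 draws", call. = FALSE)
  m <- min(sum(samples > 0), sum(samples < 0))
  min(1, 2 * max(1, m) / n)
}

#' Variance partition of a fitted mixed model
#'
#' The fixed-effect share is the variance of the fitted linear predictor
#' `X %*% beta_hat` across individuals (beta at its posterior mean); the
#' random and residual shares are the posterior means of the corresponding
#' variance components.  Shares are normalized to sum to one.
#'
#' @param fit a `vocal_lmm` object.
#' @return named numeric vector of proportions `fixed`, `species`, `group`,
#'   `resid`.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "vocal_lmm"))
  vf <- var(as.vector(fit$X %*% colMeans(fit$beta_draws)))
  vc <- colMeans(fit$sigma2_draws)
  comp <- c(fixed = vf, species = vc[["species"]], group = vc[["group"]],
            resid = vc[["resid"]])
  comp / sum(comp)
}

#' @export
coef.vocal_lmm <- function(object, ...) {
  setNames(object$coefficients$post_mean, object$coefficients$term)
}

#' @export
fitted.vocal_lmm <- function(object, ...) {
  as.vector(object$X %*% colMeans(object$beta_draws)) +
    object$u_species[object$species] + object$u_group[object$group]
}

#' @export
residuals.vocal_lmm <- function(object, ...) object$y - fitted(object)

#' @export
predict.vocal_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.vector(object$X %*% colMeans(object$beta_draws)))
  X <- model.matrix(delete.response.formula(object$formula), newdata)
  as.vector(X %*% colMeans(object$beta_draws))
}

delete.response.formula <- function(f) {
  f[[2]] <- NULL
  f
}

#' @export
print.vocal_lmm <- function(x, digits = 3, ...) {
  cat("Bayesian Gaussian mixed model (Gibbs sampler)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d individuals, %d groups, %d species; %d retained draws\n",
              x$n, x$n_groups, x$n_species, nrow(x$beta_draws)))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.vocal_lmm <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  vc <- colMeans(object$sigma2_draws)
  cat("\nPosterior mean variance components:\n")
  print(round(vc, digits + 1))
  cat("\nVariance partition (proportions):\n")
  print(round(object$variance_partition, digits))
  invisible(object)
}

#' @export
plot.vocal_lmm <- function(x, ...) {
  terms <- colnames(x$beta_draws)
  old <- par(mfrow = c(ceiling(length(terms) / 2), min(2, length(terms))))
  on.exit(par(old))
  for (tm in terms) {
    hist(x$beta_draws[, tm], breaks = 30, main = tm, xlab = "posterior draw")
    abline(v = 0, lty = 2)
  }
  invisible(x)
}
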