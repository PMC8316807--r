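#' Phylogenetic generalized least squares with fixed Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C)` with `C` the phylogenetic
#' covariance scaled by a fixed Pagel's lambda, by generalized least
#' squares: `beta = (X' C^-1 X)^-1 X' C^-1 y`, residual variance
#' `sigma2 = e' C^-1 e / (n - p)`, standard errors from
#' `sigma2 (X' C^-1 X)^-1`, and two-sided p-values from the t distribution
#' with `n - p` degrees of freedom.  Lambda is fixed, not estimated:
#' `lambda = 1` (the default) assumes full Brownian phylogenetic signal,
#' deliberately conservative for small species samples where the signal
#' cannot be estimated reliably.
#'
#' @param formula model formula over columns of `data`.
#' @param data species-level data frame; species identifiers are taken
#'   from the `species` column (default `species_id`) or, failing that,
#'   the row names.
#' @param tree an `ape::phylo` time-calibrated tree containing all species
#'   in `data`.
#' @param lambda fixed Pagel's lambda in `[0, 1]` (default 1).
#' @param species name of the species identifier column.
#' @return an object of class `pgls` with a coefficient table (`beta`,
#'   `se`, `t`, `p`), `sigma2`, `n` and the residual degrees of freedom.
#' @seealso [pgls_fit()] for the matrix-level interface,
#'   [phylo_covariance()].
#' @export
pgls <- function(formula, data, tree, lambda = 1, species = "species_id") {
  ids <- if (!is.null(data[[species]])) as.character(data[[species]]) else rownames(data)
  C <- phylo_covariance(tree, species = ids, lambda = lambda)
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  fit <- pgls_fit(y, X, C)
  fit$call <- match.call()
  fit$formula <- formula
  fit$lambda <- lambda
  fit$species <- ids
  fit
}

#' @rdname pgls
#' @param y numeric species trait vector.
#' @param X predictor matrix including the intercept column.
#' @param C phylogenetic covariance matrix aligned with `y`.
#' @export
pgls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))[seq_len(p)]
  }
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (n - p < 1L) stop("pgls_fit: residual degrees of freedom < 1", call. = FALSE)
  Ci <- tryCatch(solve(C), error = function(e) {
    stop("pgls_fit: singular covariance matrix", call. = FALSE)
  })
  XtCiX <- t(X) %*% Ci %*% X
  XtCiX_inv <- tryCatch(solve(XtCiX), error = function(e) {
    stop("pgls_fit: singular design", call. = FALSE)
  })
  beta <- as.vector(XtCiX_inv %*% t(X) %*% Ci %*% y)
  e <- y - as.vector(X %*% beta)
  sigma2 <- as.numeric(t(e) %*% Ci %*% e) / (n - p)
  se <- sqrt(diag(XtCiX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  structure(list(
    coefficients = data.frame(term = colnames(X), beta = beta, se = se,
                              t = tval, p = pval, row.names = NULL,
                              stringsAsFactors = FALSE),
    sigma2 = sigma2, n = n, df_residual = n - p,
    fitted = as.vector(X %*% beta), residuals = e, y = y, X = X
  ), class = "pgls")
}

#' @export
coef.pgls <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata) || is.null(object$formula)) return(object$fitted)
  X <- model.matrix(delete.response.formula(object$formula), newdata)
  as.vector(X %*% coef(object))
}

#' @export
print.pgls <- function(x, digits = 3, ...) {
  cat("Phylogenetic GLS")
  if (!is.null(x$lambda)) cat(" (Pagel's lambda fixed at ", x$lambda, ")", sep = "")
  cat("\n")
  if (!is.null(x$formula)) cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d species, residual df = %d, sigma2 = %.4g\n",
              x$n, x$df_residual, x$sigma2))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) print(object, ...)

#' Join species-level traits for the repertoire models
#'
#' Builds the species table consumed by the PGLS models: the composite
#' dominance-style index, the species mean group size (mean over the
#' species' groups), and log10-transformed repertoire counts,
#' `log10(count + log_offset)` (hierarchy-related call counts may be 0, so
#' a positive offset is needed).  Species missing from any source are
#' dropped with a message.
#'
#' @param indices output of [composite_index()].
#' @param repertoires validated repertoire table.
#' @param group_meta validated group metadata.
#' @param log_offset offset inside the log10 transform (default 1).
#' @return data frame with one row per species: `species_id`, `composite`,
#'   `group_size`, `total_calls`, `hierarchy_calls`, `log_total`,
#'   `log_hierarchy`, plus the raw species-mean style measures.
#' @export
species_table <- function(indices, repertoires, group_meta, log_offset = 1) {
  gs <- aggregate(group_meta["group_size"], by = group_meta["species_id"], FUN = mean)
  out <- merge(indices, gs, by = "species_id")
  out <- merge(out, repertoires, by = "species_id")
  dropped <- setdiff(indices$species_id, out$species_id)
  if (length(dropped) > 0L) {
    message("species_table: dropping species missing repertoire or groups: ",
            paste(dropped, collapse = ", "))
  }
  if (nrow(out) == 0L) stop("species_table: empty join", call. = FALSE)
  out$log_total <- log10(out$total_calls + log_offset)
  out$log_hierarchy <- log10(out$hierarchy_calls + log_offset)
  out
}
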