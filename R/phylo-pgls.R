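# Brownian-motion phylogenetic generalized least squares and its ordinary
# least squares counterpart.
#
# The residual covariance is fixed proportional to shared branch length
# (no Pagel's lambda estimation). The variance scale is profiled by maximum
# likelihood for logLik/AIC; standard errors and t-tests use the unbiased
# (n - p) estimate, the convention of the standard GLS tools.

.gls_fit <- function(y, X, C, method_label) {
  n <- length(y)
  p <- ncol(X)
  L <- chol(C)
  ty <- backsolve(L, y, transpose = TRUE)
  tX <- backsolve(L, X, transpose = TRUE)
  f <- stats::lm.fit(tX, ty)
  if (f$rank < p) stop("singular design matrix", call. = FALSE)
  beta <- f$coefficients
  rss <- sum(f$residuals^2)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(L)))
  perfect <- rss < 1e-12 * max(1, sum(ty^2))
  ll <- if (perfect) Inf else
    -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  k <- p + 1  # coefficients + variance
  aic <- 2 * k - 2 * ll
  s2 <- rss / (n - p)
  XtX_inv <- solve(crossprod(tX))
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  if (perfect) {
    se[] <- 0
    tval[] <- NA_real_
    pval[] <- NA_real_
    warning("residual variance is (numerically) zero; ",
            "standard errors and P-values are undefined", call. = FALSE)
  }
  structure(list(
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p_value = unname(pval)),
    sigma2_ml = sigma2_ml, logLik = ll, AIC = aic, df_residual = n - p,
    n = n, method = method_label, perfect_fit = perfect
  ), class = "pgls_fit")
}

#' Brownian-motion PGLS of one trait on one predictor
#'
#' @param tree a `phylo` object covering the species.
#' @param response,predictor numeric vectors named by species (tip labels).
#' @return object of class `"pgls_fit"` with a coefficient table
#'   (estimate, SE, t, P), `sigma2_ml`, `logLik`, `AIC` (with `k` counted
#'   as coefficients + 1 for the variance) and `df_residual`. On a star
#'   phylogeny the estimates equal the OLS fit exactly.
#' @seealso [ols_fit()], [pgls_select()]
#' @export
pgls_brownian <- function(tree, response, predictor) {
  y <- .match_tip_values(tree, response)
  x <- .match_tip_values(tree, predictor)
  C <- ape::vcv(tree)
  X <- cbind("(Intercept)" = 1, predictor = unname(x))
  fit <- .gls_fit(unname(y), X, C, "PGLS (Brownian)")
  fit$predictor <- if (!is.null(attr(predictor, "label")))
    attr(predictor, "label") else "predictor"
  fit
}

#' Ordinary least squares counterpart
#'
#' The same fit with an identity residual covariance (phylogeny ignored),
#' reported in the same structure so PGLS and OLS results can be shown side
#' by side.
#'
#' @param response,predictor numeric vectors (matched by names when both
#'   are named).
#' @return object of class `"pgls_fit"`.
#' @export
ols_fit <- function(response, predictor) {
  if (!is.null(names(response)) && !is.null(names(predictor)))
    predictor <- predictor[names(response)]
  stopifnot(length(response) == length(predictor), !anyNA(response),
            !anyNA(predictor))
  X <- cbind("(Intercept)" = 1, predictor = unname(predictor))
  .gls_fit(unname(response), X, diag(length(response)), "OLS")
}

#' Single-predictor PGLS model selection by AIC
#'
#' Fits one Brownian PGLS per candidate environmental variable and returns
#' the fit with the lowest AIC together with the full AIC table (ties go to
#' the first candidate in column order).
#'
#' @param tree a `phylo` object.
#' @param response numeric vector named by species.
#' @param predictors data.frame of candidate predictors, rows named by
#'   species.
#' @return list with `best` (a `"pgls_fit"`), `best_predictor` and
#'   `aic_table` (data.frame of predictor, AIC, logLik, slope, slope P).
#' @export
pgls_select <- function(tree, response, predictors) {
  predictors <- as.data.frame(predictors)
  if (is.null(rownames(predictors)))
    stop("'predictors' must have species row names", call. = FALSE)
  fits <- lapply(names(predictors), function(v) {
    x <- stats::setNames(predictors[[v]], rownames(predictors))
    pgls_brownian(tree, response, x)
  })
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  tab <- data.frame(
    predictor = names(predictors), AIC = aic,
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    slope = vapply(fits, function(f) f$coefficients$estimate[2], numeric(1)),
    p_slope = vapply(fits, function(f) f$coefficients$p_value[2], numeric(1))
  )
  best_i <- which.min(aic)
  best <- fits[[best_i]]
  best$predictor <- names(predictors)[best_i]
  list(best = best, best_predictor = names(predictors)[best_i],
       aic_table = tab[order(tab$AIC), ])
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(x$method, "fit\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("logLik: %.4f  AIC: %.4f  (n = %d)\n", x$logLik, x$AIC, x$n))
  invisible(x)
}
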