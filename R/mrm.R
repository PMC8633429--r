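# Multiple regression on distance matrices (MRM).
#
# Ordinary least squares on the unfolded strict lower triangles of the
# matrices; inference by permuting rows and columns of the response matrix
# jointly (predictors fixed), refitting, and comparing |coefficient| and
# R^2 against their permutation distributions.

#' Multiple regression on distance matrices
#'
#' @param response square distance matrix (labels as dimnames). May contain
#'   `NA` entries, which are removed pairwise together with any triangle
#'   element missing in a predictor; the usable pair count is reported.
#' @param predictors a single matrix or a (optionally named) list of
#'   matrices with the same labels as `response`.
#' @param n_permutations number of random row/column permutations of the
#'   response (default 5000).
#' @param seed integer seed for the permutation stream; required so that
#'   permutation P-values are reproducible.
#' @return object of class `"mrm_fit"`: `coefficients` (data.frame with
#'   `estimate` and permutation `p_value` per term), `r_squared`,
#'   `p_r_squared`, `n_pairs` (triangle elements used), `n_permutations`
#'   and `seed`. P-values use the +1 correction
#'   \eqn{(c + 1)/(n_{perm} + 1)}, so they are never zero.
#' @examples
#' g <- as.matrix(dist(cbind(1:6, (1:6)^2)))
#' dimnames(g) <- list(letters[1:6], letters[1:6])
#' mrm(2 * g, g, n_permutations = 99, seed = 1)
#' @export
mrm <- function(response, predictors, n_permutations = 5000, seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for the permutation test", call. = FALSE)
  response <- .as_square_labelled(response, "'response'")
  if (!is.list(predictors)) predictors <- list(predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("X", seq_along(predictors))
  predictors <- lapply(predictors, .as_square_labelled,
                       what = "each predictor")
  labs <- rownames(response)
  n <- length(labs)
  if (n < 4L) stop("need at least four plots", call. = FALSE)
  for (p in predictors)
    if (!identical(rownames(p), labs))
      stop("mismatched labels between response and predictors", call. = FALSE)

  lt <- lower.tri(response)
  y <- response[lt]
  Xp <- vapply(predictors, function(m) m[lt], numeric(sum(lt)))
  Xp <- matrix(Xp, ncol = length(predictors),
               dimnames = list(NULL, names(predictors)))
  X <- cbind("(Intercept)" = 1, Xp)
  pred_ok <- rowSums(is.na(Xp)) == 0

  fit_one <- function(yv) {
    ok <- pred_ok & !is.na(yv)
    if (sum(ok) < ncol(X) + 1L) return(NULL)  # p + 2 with p predictors
    f <- stats::lm.fit(X[ok, , drop = FALSE], yv[ok])
    b <- f$coefficients
    ss_tot <- sum((yv[ok] - mean(yv[ok]))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(f$residuals^2) / ss_tot
    list(b = b, r2 = r2, n = sum(ok))
  }

  obs <- fit_one(y)
  if (is.null(obs))
    stop("fewer usable plot pairs than coefficients + 2", call. = FALSE)

  set.seed(seed)
  count_b <- numeric(length(obs$b))
  count_r2 <- 0
  for (i in seq_len(n_permutations)) {
    pm <- sample.int(n)
    yp <- response[pm, pm][lt]
    pf <- fit_one(yp)
    if (is.null(pf)) next
    ge <- abs(pf$b) >= abs(obs$b)
    ge[is.na(ge)] <- FALSE
    count_b <- count_b + ge
    if (!is.na(pf$r2) && pf$r2 >= obs$r2) count_r2 <- count_r2 + 1
  }
  p_b <- (count_b + 1) / (n_permutations + 1)
  p_r2 <- (count_r2 + 1) / (n_permutations + 1)

  structure(list(
    coefficients = data.frame(term = names(obs$b), estimate = unname(obs$b),
                              p_value = unname(p_b)),
    r_squared = obs$r2, p_r_squared = p_r2, n_pairs = obs$n,
    n_permutations = n_permutations, seed = seed
  ), class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat("Multiple regression on distance matrices\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("R-squared: %.4f (permutation P = %.4g, %d permutations, %d pairs)\n",
              x$r_squared, x$p_r_squared, x$n_permutations, x$n_pairs))
  invisible(x)
}
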