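# Brownian-motion trait simulation and Blomberg's K.

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Tip values accumulate independent Gaussian increments along branches with
#' variance `rate * branch length`, so two tips covary by `rate *` (shared
#' branch length). Implemented through the Cholesky factor of the Brownian
#' covariance matrix; reproducible under `seed`.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param rate Brownian rate (variance per unit branch length); must be
#'   positive.
#' @param n number of independent replicate traits.
#' @param root root state added to every tip (default 0).
#' @param seed optional integer seed.
#' @return matrix of tip values, `n_tips` rows (named by tip label) by `n`
#'   columns.
#' @export
simulate_bm <- function(tree, rate = 1, n = 1, root = 0, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a positive number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  L <- chol(C)  # upper triangular, C = t(L) %*% L
  z <- matrix(stats::rnorm(nrow(C) * n), nrow(C), n)
  x <- root + sqrt(rate) * crossprod(L, z)
  rownames(x) <- rownames(C)
  x
}

# K statistic from the dense Brownian covariance (Blomberg et al. form):
# observed MSE0/MSE over its analytical Brownian expectation.
.k_statistic <- function(x, C, invC) {
  n <- length(x)
  one <- rep(1, n)
  sum_invC <- sum(invC)
  a <- as.numeric(one %*% invC %*% x) / sum_invC
  d <- x - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(d %*% invC %*% d) / (n - 1)
  if (mse == 0) stop("constant trait: K undefined", call. = FALSE)
  expected <- (sum(diag(C)) - n / sum_invC) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K with a randomization test
#'
#' K compares the observed ratio of the tip variance around the
#' phylogenetic mean (MSE0) to the generalized-least-squares mean squared
#' error under the Brownian covariance (MSE), against the analytical
#' expectation of that ratio on the same tree. `K = 1` is the Brownian
#' expectation, `K -> 0` indicates no phylogenetic signal, `K > 1` stronger
#' resemblance among relatives than Brownian motion predicts.
#'
#' Significance: tip values are shuffled across tips; the one-sided P-value
#' is the proportion of shuffles (with +1 correction) whose variance of
#' independent contrasts is less than or equal to the observed one (signal
#' = lower contrast variance than random arrangements). A two-sided version
#' is reported alongside.
#'
#' @param tree a `phylo` object with positive branch lengths (polytomies
#'   are resolved to zero-length binary branches for the contrasts).
#' @param x tip values named by tip label.
#' @param n_randomizations tip shuffles for the P-value (default 999; 0
#'   skips the test and returns `NA` P-values).
#' @param seed optional integer seed for the shuffles.
#' @return list with `K`, `p_value` (one-sided), `p_two_sided`,
#'   `n_randomizations` and `seed`.
#' @export
blomberg_k <- function(tree, x, n_randomizations = 999, seed = NULL) {
  x <- .match_tip_values(tree, x)
  n <- length(x)
  if (n < 4L) stop("need at least four tips", call. = FALSE)
  C <- ape::vcv(tree)
  invC <- solve(C)
  K <- .k_statistic(unname(x), C, invC)
  p_one <- p_two <- NA_real_
  if (n_randomizations > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs_var <- stats::var(pic_contrasts(tree, x))
    sim_var <- vapply(seq_len(n_randomizations), function(i) {
      xs <- stats::setNames(sample(unname(x)), names(x))
      stats::var(pic_contrasts(tree, xs))
    }, numeric(1))
    lo <- sum(sim_var <= obs_var)
    hi <- sum(sim_var >= obs_var)
    p_one <- (lo + 1) / (n_randomizations + 1)
    p_two <- min(1, 2 * min((lo + 1), (hi + 1)) / (n_randomizations + 1))
  }
  list(K = K, p_value = p_one, p_two_sided = p_two,
       n_randomizations = n_randomizations, seed = seed)
}
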