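# Simulation-based phylogenetic ANOVA with Holm-adjusted post hoc tests.
#
# The observed F is the ordinary one-way ANOVA statistic; its null
# distribution is generated by simulating Brownian traits on the tree (rate
# estimated from the data by GLS) and recomputing F, which accounts for the
# phylogenetic non-independence of species within groups.

# one-way ANOVA statistics for a matrix of traits (columns = replicates)
.anova_F_matrix <- function(X, g) {
  ng <- tabulate(g)
  k <- nlevels(g)
  n <- nrow(X)
  gm <- rowsum(X, g) / ng
  grand <- colMeans(X)
  ssb <- colSums(ng * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- sst - ssb
  msw <- ssw / (n - k)
  list(F = (ssb / (k - 1)) / msw, group_means = gm, msw = msw)
}

.pairwise_t_matrix <- function(gm, msw, ng, pair_idx) {
  # t statistics per group pair (rows) and replicate (columns)
  out <- matrix(NA_real_, ncol(pair_idx), length(msw))
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]
    j <- pair_idx[2, k]
    out[k, ] <- (gm[i, ] - gm[j, ]) / sqrt(msw * (1 / ng[i] + 1 / ng[j]))
  }
  out
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' Tests trait differences among groups of species (e.g. phylogenetic
#' sections or leaf-habit classes) while accounting for the phylogeny: the
#' observed one-way ANOVA F is compared with F values recomputed on traits
#' simulated under Brownian motion on the tree, with the Brownian rate
#' estimated from the data by GLS. Post hoc pairwise t statistics get
#' simulation-based P-values, Holm-adjusted across pairs.
#'
#' @param tree a `phylo` object.
#' @param x tip values named by tip label.
#' @param groups group membership, named by tip label (factor or
#'   character); every group needs at least two tips.
#' @param n_simulations Brownian null simulations (default 1000).
#' @param seed optional integer seed.
#' @return list with `F`, `p_value` (simulation-based, +1 corrected),
#'   `posthoc` (data.frame of pairwise `t`, raw and Holm-adjusted
#'   simulation P-values), `sigma2` (estimated rate), `n_simulations`,
#'   `seed`.
#' @export
phyl_anova <- function(tree, x, groups, n_simulations = 1000, seed = NULL) {
  x <- .match_tip_values(tree, x)
  if (is.null(names(groups)))
    stop("'groups' must be named by tip label", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(groups))
  if (length(miss))
    stop("missing group for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  g <- factor(as.character(groups[tree$tip.label]))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least two tips", call. = FALSE)

  n <- length(x)
  obs <- .anova_F_matrix(matrix(unname(x), ncol = 1), g)
  ng <- tabulate(g)
  pair_idx <- utils::combn(nlevels(g), 2)
  t_obs <- .pairwise_t_matrix(obs$group_means, obs$msw, ng, pair_idx)[, 1]

  # Brownian rate from the data (GLS around the phylogenetic mean); F is
  # scale-invariant so this only sets the scale of the simulated traits
  C <- ape::vcv(tree)
  invC <- solve(C)
  a <- as.numeric(rep(1, n) %*% invC %*% unname(x)) / sum(invC)
  d <- unname(x) - a
  sigma2 <- as.numeric(d %*% invC %*% d) / (n - 1)

  if (!is.null(seed)) set.seed(seed)
  L <- chol(C)
  z <- matrix(stats::rnorm(n * n_simulations), n, n_simulations)
  Xsim <- sqrt(max(sigma2, .Machine$double.eps)) * crossprod(L, z)
  sim <- .anova_F_matrix(Xsim, g)
  p_F <- (sum(sim$F >= obs$F[1]) + 1) / (n_simulations + 1)

  t_sim <- .pairwise_t_matrix(sim$group_means, sim$msw, ng, pair_idx)
  p_pair <- vapply(seq_along(t_obs), function(i)
    (sum(abs(t_sim[i, ]) >= abs(t_obs[i])) + 1) / (n_simulations + 1),
    numeric(1))
  posthoc <- data.frame(
    group_1 = levels(g)[pair_idx[1, ]], group_2 = levels(g)[pair_idx[2, ]],
    t = t_obs, p_value = p_pair,
    p_holm = stats::p.adjust(p_pair, method = "holm")
  )
  list(F = obs$F[1], p_value = p_F, posthoc = posthoc, sigma2 = sigma2,
       n_simulations = n_simulations, seed = seed)
}
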