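# Shared fixtures, built in code.

# small labelled symmetric distance matrix from planar points
dist_from_points <- function(pts, labels = letters[seq_len(nrow(pts))]) {
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

# random rooted binary tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# dense Brownian covariance GLS estimate of slope/intercept (oracle path)
gls_oracle <- function(tree, y, x) {
  C <- ape::vcv(tree)
  y <- y[rownames(C)]
  x <- x[rownames(C)]
  X <- cbind(1, x)
  iC <- solve(C)
  beta <- solve(t(X) %*% iC %*% X, t(X) %*% iC %*% y)
  drop(beta)
}

# 99% two-sided binomial bounds on a rejection count
binom_bounds99 <- function(n, p = 0.05) {
  mu <- n * p
  s <- sqrt(n * p * (1 - p))
  c(lower = mu - 2.5758 * s, upper = mu + 2.5758 * s)
}

# individual-level records for two species over plots
toy_records <- function() {
  data.frame(
    species = rep(c("sp1", "sp2"), each = 4),
    plot = c("A", "A", "B", "B", "A", "A", "B", "B"),
    VD = c(1, 2, 2, 4, 10, 10, 10, 10),
    VF = c(5, 5, 4, 4, 2, 2, 3, 3)
  )
}
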