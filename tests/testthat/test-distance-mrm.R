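test_that("geographic and environmental distances match a pairwise-loop oracle", {
  set.seed(8)
  plots <- data.frame(plot = paste0("p", 1:6),
                      x = runif(6, 0, 100), y = runif(6, 0, 100),
                      e1 = rnorm(6), e2 = rnorm(6, 10, 4))
  g <- geographic_distance(plots)
  for (i in 1:6) for (j in 1:6)
    expect_equal(g[i, j], sqrt((plots$x[i] - plots$x[j])^2 +
                               (plots$y[i] - plots$y[j])^2))
  ev <- environmental_distance(plots, c("e1", "e2"))
  z1 <- (plots$e1 - mean(plots$e1)) / sd(plots$e1)
  z2 <- (plots$e2 - mean(plots$e2)) / sd(plots$e2)
  for (i in 1:6) for (j in 1:6)
    expect_equal(ev[i, j], sqrt((z1[i] - z1[j])^2 + (z2[i] - z2[j])^2))

  # identical plots are at distance zero
  same <- data.frame(plot = c("a", "b"), x = c(1, 1), y = c(2, 2))
  expect_equal(geographic_distance(same)["a", "b"], 0)
})

test_that("a one-standard-deviation step in one variable gives distance one", {
  plots <- data.frame(plot = paste0("p", 1:4),
                      v1 = c(0, 1, 1.618034, -0.618034),  # sd exactly 1
                      v2 = c(3, 3, 4, 5))
  expect_equal(sd(plots$v1), 1, tolerance = 1e-6)
  ev <- environmental_distance(plots, c("v1", "v2"))
  expect_equal(ev["p1", "p2"], 1, tolerance = 1e-6)
  # constant variable cannot be scaled
  plots$v3 <- 7
  expect_error(environmental_distance(plots, c("v1", "v3")), "constant")
})

test_that("mrm recovers an exact linear relation and matches plain OLS", {
  set.seed(30)
  pts <- cbind(runif(8), runif(8))
  g <- dist_from_points(pts, paste0("p", 1:8))
  fit <- mrm(2 * g, list(geo = g), n_permutations = 99, seed = 4)
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # single predictor: coefficients equal lm() on the unfolded triangles
  resp <- dist_from_points(cbind(runif(8), runif(8)), paste0("p", 1:8))
  fit2 <- mrm(resp, list(geo = g), n_permutations = 99, seed = 4)
  lt <- lower.tri(resp)
  oracle <- coef(lm(resp[lt] ~ g[lt]))
  expect_equal(fit2$coefficients$estimate, unname(oracle), tolerance = 1e-10)
})

test_that("mrm permutation p-values are reproducible and labels are checked", {
  set.seed(31)
  g <- dist_from_points(cbind(runif(7), runif(7)), paste0("p", 1:7))
  r <- dist_from_points(cbind(runif(7), runif(7)), paste0("p", 1:7))
  f1 <- mrm(r, g, n_permutations = 199, seed = 11)
  f2 <- mrm(r, g, n_permutations = 199, seed = 11)
  expect_identical(f1$coefficients$p_value, f2$coefficients$p_value)
  expect_identical(f1$p_r_squared, f2$p_r_squared)
  expect_true(all(f1$coefficients$p_value > 0 & f1$coefficients$p_value <= 1))

  bad <- r
  dimnames(bad) <- list(paste0("q", 1:7), paste0("q", 1:7))
  expect_error(mrm(bad, g, n_permutations = 9, seed = 1), "labels")
})

test_that("mrm deletes missing response entries pairwise", {
  set.seed(32)
  g <- dist_from_points(cbind(runif(9), runif(9)), paste0("p", 1:9))
  r <- 1.5 * g
  r[1, 2] <- r[2, 1] <- NA
  r[4, 7] <- r[7, 4] <- NA
  fit <- mrm(r, g, n_permutations = 49, seed = 2)
  expect_equal(fit$n_pairs, choose(9, 2) - 2)
  expect_equal(fit$coefficients$estimate[2], 1.5, tolerance = 1e-10)
})
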