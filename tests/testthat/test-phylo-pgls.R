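test_that("PGLS on a star phylogeny equals OLS exactly", {
  star <- ape::stree(6, type = "star")
  star$tip.label <- LETTERS[1:6]
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(120)
  x <- setNames(rnorm(6), star$tip.label)
  y <- setNames(1 + 0.5 * x + rnorm(6, 0, 0.2), star$tip.label)
  pg <- pgls_brownian(star, y, x)
  ol <- ols_fit(y, x)
  expect_equal(pg$coefficients$estimate, ol$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(pg$coefficients$se, ol$coefficients$se, tolerance = 1e-12)
})

test_that("PGLS equals the dense-matrix GLS oracle and nlme::gls", {
  tr <- random_tree(8, seed = 121)
  set.seed(122)
  x <- setNames(rnorm(8), tr$tip.label)
  y <- setNames(2 + x + simulate_bm(tr, 0.5)[, 1], tr$tip.label)
  fit <- pgls_brownian(tr, y, x)
  expect_equal(fit$coefficients$estimate, unname(gls_oracle(tr, y, x)),
               tolerance = 1e-10)

  skip_if_not_installed("nlme")
  # nlme's Brownian structure is a correlation matrix, so the comparison
  # needs an ultrametric tree (equal root-to-tip variances)
  set.seed(129)
  trc <- ape::rcoal(8)
  trc$tip.label <- paste0("t", 1:8)
  xc <- setNames(rnorm(8), trc$tip.label)
  yc <- setNames(1 + 2 * xc + simulate_bm(trc, 0.5)[, 1], trc$tip.label)
  fitc <- pgls_brownian(trc, yc, xc)
  dat <- data.frame(y = yc[trc$tip.label], x = xc[trc$tip.label],
                    sp = trc$tip.label)
  gfit <- nlme::gls(y ~ x, data = dat,
                    correlation = ape::corBrownian(phy = trc, form = ~sp),
                    method = "ML")
  expect_equal(fitc$coefficients$estimate, unname(coef(gfit)),
               tolerance = 1e-6)
  expect_equal(fitc$logLik, as.numeric(stats::logLik(gfit)),
               tolerance = 1e-6)
})

test_that("a perfect fit is flagged instead of reporting spurious inference", {
  tr <- random_tree(6, seed = 123)
  x <- setNames(rnorm(6), tr$tip.label)
  expect_warning(fit <- pgls_brownian(tr, x, x), "zero")
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-10)
  expect_true(fit$perfect_fit)
  expect_true(all(is.na(fit$coefficients$p_value)))
})

test_that("AIC model selection picks the generating predictor", {
  tr <- random_tree(30, seed = 124)
  set.seed(125)
  good <- setNames(rnorm(30), tr$tip.label)
  noise1 <- setNames(rnorm(30), tr$tip.label)
  noise2 <- setNames(rnorm(30), tr$tip.label)
  y <- setNames(3 * good + simulate_bm(tr, 0.2)[, 1], tr$tip.label)
  preds <- data.frame(n1 = noise1[tr$tip.label], good = good[tr$tip.label],
                      n2 = noise2[tr$tip.label],
                      row.names = tr$tip.label)
  sel <- pgls_select(tr, y, preds)
  expect_equal(sel$best_predictor, "good")
  expect_equal(nrow(sel$aic_table), 3)
  expect_equal(sel$aic_table$AIC[1], min(sel$aic_table$AIC))
  # AIC follows the stated convention: 2k - 2 logLik with k = coefs + 1
  expect_equal(sel$best$AIC, 2 * 3 - 2 * sel$best$logLik)
})

test_that("PGLS slope recovery is unbiased under the Brownian model", {
  tr <- random_tree(50, seed = 126)
  set.seed(127)
  slopes <- replicate(50, {
    x <- setNames(rnorm(50), tr$tip.label)
    y <- 2 * x + simulate_bm(tr, 1)[, 1]
    pgls_brownian(tr, setNames(y, tr$tip.label), x)$coefficients$estimate[2]
  })
  expect_equal(mean(slopes), 2, tolerance = 0.1)
})
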