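test_that("tree reading, pruning and unifurcation collapse behave", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  pruned <- prune_tree(tr, c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  # the suppressed node's branches sum: A now sits on a length-2 branch
  lens <- setNames(pruned$edge.length, pruned$tip.label[pruned$edge[, 2]])
  expect_equal(unname(lens[c("A", "C")]), c(2, 2))

  expect_identical(prune_tree(tr, tr$tip.label)$tip.label, tr$tip.label)
  expect_error(prune_tree(tr, c("A", "Z")), "Z")
  expect_error(read_tree("((A:1,B:1):1,C:2"), "malformed|parenthes")
  expect_error(read_tree("((A,B),C);"), "branch lengths")

  rt <- random_tree(20, seed = 51)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(rt, tmp)
  back <- read_tree(tmp)
  expect_equal(back$tip.label, rt$tip.label)
  expect_equal(back$edge.length, rt$edge.length, tolerance = 1e-8)
})

test_that("name reconciliation unifies case and separators", {
  tr <- read_tree("((Quercus_laeta:1,Quercus_resinosa:1):1,Quercus_gilva:2);")
  got <- reconcile_names(tr, c("quercus laeta", "QUERCUS_RESINOSA",
                               "Quercus gilva"))
  expect_equal(got, c("Quercus_laeta", "Quercus_resinosa", "Quercus_gilva"))
  expect_error(reconcile_names(tr, c("Quercus laeta", "Quercus nobody")),
               "nobody")
})

test_that("contrasts on a cherry and on constant data follow the formula", {
  tr <- read_tree("(A:1,B:1);")
  expect_equal(unname(pic_contrasts(tr, c(A = 3, B = 1))), 2 / sqrt(2),
               ignore_attr = TRUE)
  tr3 <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(unname(pic_contrasts(tr3, c(A = 5, B = 5, C = 5))), c(0, 0),
               ignore_attr = TRUE)
  expect_error(pic_contrasts(tr3, c(A = 1, B = 2)), "missing")
})

test_that("contrasts agree with ape::pic across random trees", {
  for (s in 1:5) {
    tr <- random_tree(12, seed = 60 + s)
    x <- setNames(rnorm(12), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    theirs <- ape::pic(x, tr)
    expect_equal(mine[names(theirs)], theirs, tolerance = 1e-12)
  }
})

test_that("contrast regression equals dense-matrix GLS on small trees", {
  for (s in 1:5) {
    n <- 6
    tr <- random_tree(n, seed = 70 + s)
    set.seed(700 + s)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(2 * x + rnorm(n, 0, 0.5), tr$tip.label)
    cx <- pic_contrasts(tr, x)
    cy <- pic_contrasts(tr, y)
    slope_pic <- sum(cx * cy) / sum(cx^2)  # through-origin
    slope_gls <- gls_oracle(tr, y, x)[2]
    expect_equal(slope_pic, unname(slope_gls), tolerance = 1e-10)
    # GLS sum of squares around the phylogenetic mean = sum of squared PICs
    C <- ape::vcv(tr)
    iC <- solve(C)
    a <- sum(iC %*% y[rownames(C)]) / sum(iC)
    d <- y[rownames(C)] - a
    expect_equal(sum(cy^2), drop(d %*% iC %*% d), tolerance = 1e-10)
  }
})

test_that("contrast variance calibrates to the Brownian rate", {
  tr <- random_tree(40, seed = 80)
  set.seed(81)
  x <- simulate_bm(tr, rate = 3, n = 200)
  v <- apply(x, 2, function(col)
    mean(pic_contrasts(tr, setNames(col, rownames(x)))^2))
  expect_equal(mean(v), 3, tolerance = 0.15)
})
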