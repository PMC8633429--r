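test_that("rdpi reproduces hand-enumerated cross-plot pair means", {
  one <- rdpi(list(A = 1, B = 3))
  expect_equal(one$rdpi, 0.5)
  expect_equal(one$n_pairs, 1L)

  # four cross-plot pairs enumerated by hand:
  # (1,2)->1/3, (1,4)->3/5, (2,2)->0, (2,4)->1/3
  four <- rdpi(list(A = c(1, 2), B = c(2, 4)))
  expect_equal(four$rdpi, (1 / 3 + 3 / 5 + 0 + 1 / 3) / 4)
  expect_equal(four$n_pairs, 4L)

  expect_equal(rdpi(list(A = c(2, 2), B = 2, C = c(2, 2)))$rdpi, 0)
  expect_error(rdpi(list(A = c(1, 2))), "cross-environment")
  expect_error(rdpi(list(A = -1, B = 2)), "nonnegative")
})

test_that("rdpi is scale-invariant and bounded in [0, 1]", {
  set.seed(5)
  for (i in 1:20) {
    vals <- list(A = runif(3, 0, 10), B = runif(4, 0, 10), C = runif(2, 0, 10))
    r <- rdpi(vals)$rdpi
    expect_gte(r, 0)
    expect_lte(r, 1)
    scaled <- lapply(vals, function(v) v * 37.5)
    expect_equal(rdpi(scaled)$rdpi, r, tolerance = 1e-12)
  }
  # one side all zero, other positive: every pair has exactly one zero -> 1
  expect_equal(rdpi(list(A = c(0, 0), B = c(5, 5)))$rdpi, 1)
  # both-zero pairs contribute 0, not NaN
  expect_equal(rdpi(list(A = 0, B = 0))$rdpi, 0)
})

test_that("rdpi_table composes per-species rdpi and excludes single-plot species", {
  rec <- toy_records()
  rec1 <- rbind(rec, data.frame(species = "sp3", plot = "A",
                                VD = c(3, 4), VF = c(1, 2)))
  expect_message(tab <- rdpi_table(rec1, traits = c("VD", "VF")), "sp3")
  expect_equal(attr(tab, "excluded"), "sp3")
  expect_false("sp3" %in% tab$species)
  direct <- rdpi(split(rec$VD[rec$species == "sp1"],
                       rec$plot[rec$species == "sp1"]))
  expect_equal(tab$rdpi[tab$species == "sp1" & tab$trait == "VD"],
               direct$rdpi)
  expect_true(all(tab$rdpi >= 0 & tab$rdpi <= 1))
})

test_that("scalar rdpi equals the pair-count-weighted mean of the plot-pair matrix", {
  set.seed(9)
  rec <- data.frame(
    species = "sp",
    plot = rep(c("A", "B", "C"), times = c(3, 2, 4)),
    VD = runif(9, 1, 10)
  )
  m <- rdpi_plot_pair_matrix(rec, "sp", "VD")
  np <- attr(m, "n_pairs")
  lt <- lower.tri(m)
  weighted <- sum(m[lt] * np[lt]) / sum(np[lt])
  expect_equal(weighted, rdpi(split(rec$VD, rec$plot))$rdpi)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(0, 3))
})

test_that("plot-pair matrices leave absent plots missing and section_mean averages entrywise", {
  rec <- toy_records()
  plots <- c("A", "B", "Z")  # Z never sampled
  m1 <- rdpi_plot_pair_matrix(rec, "sp1", "VD", plots = plots)
  expect_true(all(is.na(m1["Z", ])))
  m2 <- rdpi_plot_pair_matrix(rec, "sp2", "VD", plots = plots)
  avg <- section_mean(list(m1, m2))
  expect_equal(avg["A", "B"], mean(c(m1["A", "B"], m2["A", "B"])))
  expect_true(is.na(avg["A", "Z"]))  # missing everywhere stays missing
  # three-matrix entrywise mean against a hand average
  m3 <- m1
  m3["A", "B"] <- m3["B", "A"] <- 0.9
  avg3 <- section_mean(list(m1, m2, m3))
  expect_equal(avg3["A", "B"], mean(c(m1["A", "B"], m2["A", "B"], 0.9)))
})

test_that("arcsine-square-root transform matches its closed form", {
  expect_equal(rdpi_transform(0), 0)
  expect_equal(rdpi_transform(1), pi / 2)
  expect_equal(rdpi_transform(0.25), pi / 6)
  expect_error(rdpi_transform(1.2), "\\[0, 1\\]")
})

test_that("welch_ttest matches the textbook formula and handles degenerate input", {
  set.seed(14)
  a <- rnorm(8, 1, 2)
  b <- rnorm(12, 0.5, 1)
  got <- welch_ttest(a, b)
  se2 <- var(a) / 8 + var(b) / 12
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 8)^2 / 7 + (var(b) / 12)^2 / 11)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  same <- welch_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  sep <- welch_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_gt(abs(sep$t), 100)
  expect_lt(sep$p_value, 0.01)
})
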