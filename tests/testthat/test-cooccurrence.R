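test_that("pair pmf matches enumeration on tiny cases and normalizes", {
  p2 <- pair_pmf(N = 2, n1 = 1, n2 = 1)
  expect_equal(p2$j, 0:1)
  expect_equal(p2$p, c(0.5, 0.5))

  ubiq <- pair_pmf(N = 6, n1 = 6, n2 = 4)
  expect_equal(ubiq$j, 4)
  expect_equal(ubiq$p, 1)

  set.seed(41)
  for (i in 1:25) {
    N <- sample(3:40, 1)
    n1 <- sample(0:N, 1)
    n2 <- sample(0:N, 1)
    pmf <- pair_pmf(N, n1, n2)
    expect_equal(sum(pmf$p), 1, tolerance = 1e-12)
    swap <- pair_pmf(N, n2, n1)
    expect_equal(pmf$p, swap$p)
    expect_equal(sum(pmf$j * pmf$p), n1 * n2 / N, tolerance = 1e-10)
  }
  expect_error(pair_pmf(5, 6, 2), "exceed")
})

test_that("pmf at N = 10 equals exhaustive enumeration over all placements", {
  N <- 10; n1 <- 5; n2 <- 4
  A <- combn(N, n1)  # all sites for species 1
  B <- combn(N, n2)
  Am <- t(apply(A, 2, function(s) as.integer(seq_len(N) %in% s)))
  Bm <- t(apply(B, 2, function(s) as.integer(seq_len(N) %in% s)))
  overlap <- Am %*% t(Bm)
  counts <- table(factor(overlap, levels = 0:min(n1, n2)))
  oracle <- as.numeric(counts) / length(overlap)
  pmf <- pair_pmf(N, n1, n2)
  expect_equal(pmf$p, oracle[pmf$j + 1], tolerance = 1e-12)
})

test_that("pair classification applies inclusive tails and the alpha rule", {
  pos <- classify_pair(10, 5, 4, 4)
  expect_equal(pos$p_gt, 5 / choose(10, 4))
  expect_equal(pos$label, "positive")
  expect_equal(pos$expected, 2)

  ubiq <- classify_pair(8, 8, 3, 3)
  expect_equal(ubiq$p_lt, 1)
  expect_equal(ubiq$p_gt, 1)
  expect_equal(ubiq$label, "random")

  two <- classify_pair(2, 1, 1, 1)  # mass 0.5 at the observed maximum
  expect_equal(two$p_gt, 0.5)
  expect_equal(two$label, "random")

  sym <- classify_pair(10, 4, 5, 4)  # species order within a pair
  expect_equal(sym$p_gt, pos$p_gt)
  expect_equal(sym$label, pos$label)

  expect_error(classify_pair(10, 5, 4, 5), "support")
  # p_lt + p_gt >= 1 (shared mass at the observed value)
  set.seed(42)
  for (i in 1:20) {
    N <- sample(4:30, 1); n1 <- sample(1:N, 1); n2 <- sample(1:N, 1)
    pmf <- pair_pmf(N, n1, n2)
    obs <- sample(pmf$j, 1)
    cp <- classify_pair(N, n1, n2, obs)
    expect_gte(cp$p_lt + cp$p_gt, 1)
  }
})

test_that("labels are monotone in the observed co-occurrence", {
  N <- 20; n1 <- 9; n2 <- 7
  labs <- vapply(pair_pmf(N, n1, n2)$j, function(j)
    classify_pair(N, n1, n2, j)$label, character(1))
  code <- c(negative = -1, random = 0, positive = 1)[labs]
  expect_true(all(diff(code) >= 0))
})

test_that("cooccurrence_table evaluates all unordered pairs", {
  set.seed(43)
  m21 <- matrix(rbinom(21 * 33, 1, 0.3), 21, 33,
                dimnames = list(paste0("sp", 1:21), paste0("pl", 1:33)))
  m21[rowSums(m21) == 0, 1] <- 1
  res <- cooccurrence_table(m21)
  expect_equal(res$summary$total_pairs, choose(21, 2))
  expect_equal(res$summary$positive + res$summary$negative +
                 res$summary$random, res$summary$total_pairs)
  expect_equal(sum(res$summary$percent), 100)
  # an assemblage of 22 taxa gives the familiar 231-pair analysis
  m22 <- rbind(m21, sp22 = rbinom(33, 1, 0.4))
  m22["sp22", 1] <- 1
  expect_equal(cooccurrence_table(m22)$summary$total_pairs, 231)

  m2 <- matrix(c(1, 0, 1, 1), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(cooccurrence_table(m2)$summary$total_pairs, 1)

  m0 <- rbind(m2, c(0, 0))
  rownames(m0)[3] <- "ghost"
  expect_warning(res0 <- cooccurrence_table(m0), "ghost")
  expect_equal(res0$summary$total_pairs, 1)
})
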