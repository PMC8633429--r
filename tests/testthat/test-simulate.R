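test_that("the default configuration reproduces the study dimensions", {
  sim <- simulate_study(simulation_config(seed = 42))
  expect_equal(nrow(sim$species), 21)
  expect_equal(nrow(sim$plots), 33)
  expect_equal(dim(sim$presence), c(21, 33))
  expect_true(all(rowSums(sim$presence) >= 1))
  expect_equal(sort(unique(sim$species$section)), c("Lobatae", "Quercus"))
  expect_true(all(table(sim$species$habit) >= 2))
  expect_true(all(sim$plots$AI >= 0.78 & sim$plots$AI <= 1.78))
  # individuals only appear in plots marked present
  combos <- unique(sim$individuals[c("species", "plot")])
  expect_true(all(mapply(function(s, p) sim$presence[s, p] == 1,
                         combos$species, combos$plot)))
  expect_equal(sim$individuals$FD,
               sim$individuals$FL + 2 * sim$individuals$FW)
})

test_that("the same seed regenerates a byte-identical bundle", {
  a <- simulate_study(simulation_config(seed = 7))
  b <- simulate_study(simulation_config(seed = 7))
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$presence, b$presence)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  d <- simulate_study(simulation_config(seed = 8))
  expect_false(identical(a$individuals$VD, d$individuals$VD))
})

test_that("a zero-effect world is perfectly flat and has zero RDPI", {
  cfg <- simulation_config(
    seed = 5, n_species = 6, n_plots = 8,
    bm_rate = c(VD = 0, VF = 0, FL = 0, FW = 0, WD = 0, H = 0),
    env_slope = c(VD = 0, VF = 0, FL = 0, FW = 0, WD = 0, H = 0),
    habit_effect = list(deciduous = c(), brevideciduous = c(),
                        evergreen = c()),
    cv_within = 0, n_vessels = 0, niche_breadth = 0.5,
    occupancy_amplitude = 1)
  sim <- simulate_study(cfg)
  expect_equal(length(unique(sim$individuals$VF)), 1)
  tab <- rdpi_table(sim$individuals, traits = c("VD", "VF", "WD"))
  expect_equal(unique(tab$rdpi), 0)
})

test_that("stronger within-species noise raises measured RDPI", {
  mean_rdpi <- function(cv, seed) {
    cfg <- simulation_config(seed = seed, n_species = 8, n_plots = 10,
                             cv_within = cv, n_vessels = 0,
                             niche_breadth = 0.4, occupancy_amplitude = 0.9)
    sim <- simulate_study(cfg)
    suppressMessages(mean(rdpi_table(sim$individuals, traits = "VD")$rdpi))
  }
  lo <- mean(vapply(1:5, function(s) mean_rdpi(0.05, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mean_rdpi(0.30, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(), "mandatory")
  expect_error(simulation_config(seed = 1, n_species = 2,
                                 habit_effect = list(a = c(), b = c(),
                                                     c = c())),
               "habit classes")
  expect_error(simulation_config(seed = 1, aridity_range = c(2, 1)))
})

test_that("the vessel-level generator couples diameter and area tightly", {
  vess <- simulate_vessels(n_species = 10, seed = 3)
  expect_equal(nrow(vess), 50)
  # per-individual area exceeds the circle area of the mean diameter
  # (Jensen: averaging areas vs averaging diameters)
  expect_true(all(vess$VA >= pi * (vess$VD / 2)^2))
})

test_that("the recovery report tracks generating slopes and signal", {
  cfg <- simulation_config(seed = 11, n_species = 12, n_plots = 16,
                           niche_breadth = 0.35, occupancy_amplitude = 0.9)
  sim <- simulate_study(cfg)
  rec <- recovery_suite(sim)
  expect_equal(nrow(rec), 6)
  expect_true(all(is.finite(rec$slope_pgls)))
  expect_true(all(rec$K > 0))
  # slope signs recovered for the strongest responses (H: +0.35, VF: -0.25)
  expect_gt(rec$slope_pgls[rec$trait == "H"], 0)
  expect_lt(rec$slope_pgls[rec$trait == "VF"], 0)
})
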