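# Synthetic gradient-study generator.
#
# Emulates the sampling structure of a wood-anatomy gradient study: species
# on a pure-birth phylogeny split into two sections with three leaf-habit
# classes, plots on a linear elevation/aridity gradient with correlated
# climate variables, Gaussian-niche occupancy on the aridity axis,
# species-plot trait means built from Brownian evolution + habit shifts +
# environmental slopes, and lognormal individual-level measurement noise
# with optional per-vessel sub-measurements.

#' Configuration for a synthetic gradient study
#'
#' Defaults reproduce the sampling structure of the emulated study design:
#' 21 species in 2 sections and 3 leaf-habit classes, 33 plots spanning
#' aridity index 0.78-1.78 (elevation 650-2738 m), 5 individuals per
#' species per plot, 50 vessel diameters per individual (CV 30%). Trait
#' effects operate on the natural-log scale: Brownian rates are log-scale
#' variances over a unit-height tree, `env_slope` is the log-scale change
#' per unit aridity index, and `habit_effect` lists log shifts per class.
#' The occupancy niche (`niche_breadth` 0.06 AI units, amplitude 0.55)
#' yields roughly 2-3 occupied plots per species, matching a sample of
#' ~275 individuals; occasional single-plot species are intentional (they
#' exercise the plasticity-exclusion rule).
#'
#' @param seed integer seed (mandatory; the whole bundle is reproducible
#'   from it).
#' @param n_species,n_plots,individuals_per_plot study dimensions.
#' @param aridity_range increasing length-2 vector of AI limits.
#' @param elevation_range elevation limits, m.
#' @param trait_baseline named vector of trait scale anchors (VD um, VF per
#'   mm^2, FL/FW um, WD g cm^-3, H m).
#' @param bm_rate named vector of Brownian rates (log-scale variance per
#'   unit tree height); 0 switches phylogenetic deviation off for a trait.
#' @param env_slope named vector of log-scale responses to AI.
#' @param habit_effect named list of per-class named log shifts.
#' @param cv_within within-species (between-individual) coefficient of
#'   variation of the lognormal measurement noise.
#' @param niche_breadth Gaussian niche SD on the AI axis.
#' @param occupancy_amplitude occupancy probability at the niche optimum.
#' @param n_vessels vessel diameters measured per individual (0 disables
#'   vessel-level measurement; VA is then the equivalent-circle area of the
#'   individual mean diameter).
#' @param vessel_cv coefficient of variation of per-vessel diameters.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed,
                              n_species = 21,
                              n_plots = 33,
                              individuals_per_plot = 5,
                              aridity_range = c(0.78, 1.78),
                              elevation_range = c(650, 2738),
                              trait_baseline = c(VD = 180, VF = 10, FL = 15,
                                                 FW = 3.5, WD = 0.65, H = 15),
                              bm_rate = c(VD = 0.03, VF = 0.03, FL = 0.02,
                                          FW = 0.02, WD = 0.01, H = 0.04),
                              env_slope = c(VD = 0.15, VF = -0.25, FL = 0.10,
                                            FW = -0.05, WD = -0.15, H = 0.35),
                              habit_effect = list(
                                deciduous = c(VD = -0.10, H = -0.15),
                                brevideciduous = c(),
                                evergreen = c(VD = 0.15, FL = 0.08, H = 0.25)),
                              cv_within = 0.15,
                              niche_breadth = 0.06,
                              occupancy_amplitude = 0.55,
                              n_vessels = 50,
                              vessel_cv = 0.30) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory", call. = FALSE)
  stopifnot(n_species >= 2, n_plots >= 2, individuals_per_plot >= 1,
            length(aridity_range) == 2, diff(aridity_range) > 0,
            min(aridity_range) > 0, cv_within >= 0, niche_breadth > 0,
            occupancy_amplitude > 0, occupancy_amplitude <= 1,
            n_vessels >= 0, vessel_cv >= 0, all(bm_rate >= 0))
  if (length(habit_effect) > n_species)
    stop("more habit classes than species", call. = FALSE)
  structure(list(seed = as.integer(seed), n_species = n_species,
                 n_plots = n_plots,
                 individuals_per_plot = individuals_per_plot,
                 aridity_range = aridity_range,
                 elevation_range = elevation_range,
                 trait_baseline = trait_baseline, bm_rate = bm_rate,
                 env_slope = env_slope, habit_effect = habit_effect,
                 cv_within = cv_within, niche_breadth = niche_breadth,
                 occupancy_amplitude = occupancy_amplitude,
                 n_vessels = n_vessels, vessel_cv = vessel_cv),
            class = "simulation_config")
}

# lognormal draw preserving the arithmetic mean at the given CV
.rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a full synthetic gradient study
#'
#' @param config a [simulation_config()].
#' @return list with `tree` (`phylo`, tips `species_01`...), `species`
#'   (data.frame: species, section, habit, AI niche optimum), `plots`
#'   (data.frame: plot, x, y, elevation, AI, MAP, PET, mtdq, pwaq, pwq,
#'   ps), `presence` (species x plots 0/1 matrix), `individuals`
#'   (data.frame of measured trees: species, plot, VD, VF, VA, FL, FW, FD,
#'   WD, H, DBH) and `truth` (generating tree, per-species log-scale
#'   latent trait values, environmental slopes, habit effects, occupancy
#'   probabilities and the seed) sufficient to recompute every table.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must come from simulation_config()", call. = FALSE)
  set.seed(config$seed)
  ns <- config$n_species
  np <- config$n_plots
  traits <- names(config$trait_baseline)

  # phylogeny: pure-birth, rescaled to unit height
  tree <- ape::rphylo(ns, birth = 1, death = 0)
  tree$tip.label <- sprintf("species_%02d", seq_len(ns))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))

  # sections = the two clades descending from the root
  root <- ns + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade1 <- if (kids[1] <= ns) tree$tip.label[kids[1]] else
    ape::extract.clade(tree, kids[1])$tip.label
  section <- ifelse(tree$tip.label %in% clade1, "Quercus", "Lobatae")

  # leaf habits: section-biased draws, every class kept at >= 1 species
  # (>= 2 when the species pool allows it, so group tests stay defined)
  habit_levels <- names(config$habit_effect)
  probs <- list(Quercus = c(0.45, 0.35, 0.20), Lobatae = c(0.25, 0.55, 0.20))
  habit <- vapply(section, function(s)
    sample(habit_levels, 1, prob = probs[[s]][seq_along(habit_levels)]),
    character(1))
  min_per_class <- if (ns >= 2 * length(habit_levels)) 2L else 1L
  repeat {
    cnt <- table(factor(habit, levels = habit_levels))
    short <- names(cnt)[cnt < min_per_class]
    if (!length(short)) break
    donor <- names(cnt)[which.max(cnt)]
    habit[which(habit == donor)[1]] <- short[1]
  }

  # plots on the gradient
  elev <- seq(config$elevation_range[1], config$elevation_range[2],
              length.out = np)
  ai_lo <- config$aridity_range[1]
  ai_hi <- config$aridity_range[2]
  ai <- ai_lo + (ai_hi - ai_lo) * (elev - min(elev)) / diff(range(elev))
  ai <- pmin(ai_hi, pmax(ai_lo, ai + stats::rnorm(np, 0, 0.015)))
  sai <- (ai - ai_lo) / (ai_hi - ai_lo)
  pet <- 1400 - 350 * sai + stats::rnorm(np, 0, 25)
  plots <- data.frame(
    plot = sprintf("plot_%02d", seq_len(np)),
    x = (elev - min(elev)) / 50 + stats::rnorm(np, 0, 2),
    y = stats::runif(np, 0, 40),
    elevation = elev,
    AI = ai, PET = pet, MAP = ai * pet,
    mtdq = 36 - 15 * sai + stats::rnorm(np, 0, 0.6),
    pwaq = 60 + 180 * sai + stats::rnorm(np, 0, 12),
    pwq = 500 + 450 * sai + stats::rnorm(np, 0, 30),
    ps = 115 - 30 * sai + stats::rnorm(np, 0, 3)
  )

  # Gaussian niche occupancy on the AI axis
  optimum <- sample(seq(ai_lo, ai_hi, length.out = ns)) +
    stats::rnorm(ns, 0, 0.02)
  p_occ <- config$occupancy_amplitude *
    exp(-0.5 * (outer(optimum, ai, "-") / config$niche_breadth)^2)
  presence <- matrix(stats::rbinom(ns * np, 1, p_occ), ns, np,
                     dimnames = list(tree$tip.label, plots$plot))
  for (i in seq_len(ns))                      # every species occurs somewhere
    presence[i, which.min(abs(ai - optimum[i]))] <- 1L

  # species-level latent log values: baseline + Brownian deviation + habit
  base_log <- matrix(rep(log(config$trait_baseline), each = ns), ns,
                     length(traits), dimnames = list(tree$tip.label, traits))
  for (tr in traits) {
    rate <- config$bm_rate[[tr]]
    if (rate > 0)
      base_log[, tr] <- base_log[, tr] + simulate_bm(tree, rate = rate)[, 1]
    eff <- vapply(habit, function(h) {
      e <- config$habit_effect[[h]]
      if (!is.null(e) && tr %in% names(e)) e[[tr]] else 0
    }, numeric(1))
    base_log[, tr] <- base_log[, tr] + eff
  }

  # individuals
  ai_mid <- mean(config$aridity_range)
  rows <- list()
  for (i in seq_len(ns)) {
    for (j in which(presence[i, ] == 1L)) {
      mu_log <- base_log[i, ] + config$env_slope[traits] * (ai[j] - ai_mid)
      nind <- config$individuals_per_plot
      ind <- vapply(traits, function(tr)
        .rlnorm_cv(nind, exp(mu_log[[tr]]), config$cv_within),
        numeric(nind))
      ind <- matrix(ind, nrow = nind, dimnames = list(NULL, traits))
      if (config$n_vessels > 0) {
        VD <- numeric(nind)
        VA <- numeric(nind)
        for (m in seq_len(nind)) {
          dvess <- .rlnorm_cv(config$n_vessels, ind[m, "VD"],
                              config$vessel_cv)
          VD[m] <- mean(dvess)
          VA[m] <- mean(pi * (dvess / 2)^2)
        }
      } else {
        VD <- ind[, "VD"]
        VA <- pi * (VD / 2)^2
      }
      H <- ind[, "H"]
      rows[[length(rows) + 1L]] <- data.frame(
        species = tree$tip.label[i], plot = plots$plot[j],
        VD = VD, VF = ind[, "VF"], VA = VA,
        FL = ind[, "FL"], FW = ind[, "FW"],
        FD = ind[, "FL"] + 2 * ind[, "FW"],
        WD = ind[, "WD"], H = H,
        DBH = (15 + 1.2 * H) * .rlnorm_cv(nind, 1, 0.10)
      )
    }
  }
  individuals <- do.call(rbind, rows)
  rownames(individuals) <- NULL

  species <- data.frame(species = tree$tip.label, section = section,
                        habit = habit, ai_optimum = optimum)
  truth <- list(tree = tree, base_log = base_log,
                env_slope = config$env_slope,
                habit_effect = config$habit_effect,
                occupancy_probability = p_occ, optimum = optimum,
                config = config, seed = config$seed)
  list(tree = tree, species = species, plots = plots, presence = presence,
       individuals = individuals, truth = truth)
}

#' Simulate per-vessel diameter measurements
#'
#' The vessel-level measurement model on its own: species mean diameters
#' drawn uniformly, individuals lognormal around the species mean, and a
#' fixed number of lognormal per-vessel diameters per individual; each
#' individual's vessel diameter is the mean measured diameter and its
#' vessel area the mean equivalent-circle area of the same vessels.
#'
#' @param n_species number of species.
#' @param n_individuals individuals per species.
#' @param n_vessels vessel diameters per individual.
#' @param diameter_range uniform range of species mean diameters, um.
#' @param cv lognormal coefficient of variation of per-vessel diameters
#'   (also used between individuals, halved).
#' @param seed optional integer seed.
#' @return data.frame with one row per individual: `species`, `VD`, `VA`.
#' @export
simulate_vessels <- function(n_species = 21, n_individuals = 5,
                             n_vessels = 50, diameter_range = c(120, 260),
                             cv = 0.30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp_mean <- stats::runif(n_species, diameter_range[1], diameter_range[2])
  rows <- lapply(seq_len(n_species), function(i) {
    ind_mean <- .rlnorm_cv(n_individuals, sp_mean[i], cv / 2)
    vd <- numeric(n_individuals)
    va <- numeric(n_individuals)
    for (m in seq_len(n_individuals)) {
      d <- .rlnorm_cv(n_vessels, ind_mean[m], cv)
      vd[m] <- mean(d)
      va[m] <- mean(pi * (d / 2)^2)
    }
    data.frame(species = sprintf("species_%02d", i), VD = vd, VA = va)
  })
  do.call(rbind, rows)
}

#' Ground-truth recovery report for a simulated study
#'
#' Convenience summary of how well the pipeline recovers the generating
#' parameters of one simulated bundle: per-trait PGLS slope of the log10
#' species mean against the species' mean occupied aridity versus the
#' generating slope (rescaled to log10), and Blomberg's K of the log10
#' species means.
#'
#' @param sim output of [simulate_study()].
#' @return data.frame with one row per trait: generating slope (log10
#'   scale), estimated PGLS slope, Blomberg's K.
#' @export
recovery_suite <- function(sim) {
  traits <- names(sim$truth$config$trait_baseline)
  sm <- species_means(sim$individuals, traits = traits, log10 = TRUE)
  occ_ai <- vapply(sm$species, function(s) {
    pl <- sim$individuals$plot[sim$individuals$species == s]
    mean(sim$plots$AI[match(unique(pl), sim$plots$plot)])
  }, numeric(1))
  names(occ_ai) <- sm$species
  out <- data.frame(trait = traits,
                    slope_true_log10 = sim$truth$env_slope[traits] / log(10),
                    slope_pgls = NA_real_, K = NA_real_)
  for (i in seq_along(traits)) {
    y <- stats::setNames(sm[[traits[i]]], sm$species)
    fit <- pgls_brownian(sim$tree, y, occ_ai)
    out$slope_pgls[i] <- fit$coefficients$estimate[2]
    out$K[i] <- blomberg_k(sim$tree, y, n_randomizations = 0)$K
  }
  rownames(out) <- NULL
  out
}
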