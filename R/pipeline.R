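# End-to-end pipeline: input validation, stage orchestration, CSV output
# with a run manifest. CSV is the single tabular interchange format; trees
# travel as Newick.

#' Pipeline configuration
#'
#' @param seed integer seed governing every stochastic stage (mandatory:
#'   seeds are never defaulted silently).
#' @param traits trait columns analysed at the individual level.
#' @param log10 log10-transform individual values before species means.
#' @param vif_threshold threshold for the environmental variable screen.
#' @param env_variables candidate environmental columns of the plot table.
#' @param mrm_traits traits whose section-level RDPI matrices enter MRM.
#' @param n_permutations MRM permutations.
#' @param n_randomizations Blomberg's K randomizations.
#' @param n_simulations phylogenetic-ANOVA simulations.
#' @param alpha significance threshold for co-occurrence classification.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed,
                            traits = c("VD", "VF", "FL", "FW", "FD", "WD", "H"),
                            log10 = TRUE,
                            vif_threshold = 10,
                            env_variables = c("AI", "mtdq", "pwaq", "pwq", "ps"),
                            mrm_traits = c("VD", "VF"),
                            n_permutations = 5000,
                            n_randomizations = 999,
                            n_simulations = 1000,
                            alpha = 0.05) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory for the pipeline", call. = FALSE)
  structure(list(seed = as.integer(seed), traits = traits, log10 = log10,
                 vif_threshold = vif_threshold, env_variables = env_variables,
                 mrm_traits = mrm_traits, n_permutations = n_permutations,
                 n_randomizations = n_randomizations,
                 n_simulations = n_simulations, alpha = alpha),
            class = "pipeline_config")
}

#' Validate a study bundle
#'
#' Schema and plausibility checks: required columns, name reconciliation
#' across tables, tree and presence matrix, plausible measurement ranges
#' (vessel diameters are expected in um, 10-500), duplicated individuals.
#' Nothing is modified; fatal issues are marked in the report.
#'
#' @param bundle list with `individuals`, `plots`, `species`, `presence`
#'   and optionally `tree` (as produced by [simulate_study()] or
#'   [read_study_bundle()]).
#' @return data.frame report (`check`, `severity`, `message`) with
#'   attribute `"ok"` (no fatal issue).
#' @export
validate_inputs <- function(bundle) {
  rep_rows <- list()
  note <- function(check, severity, message)
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      check = check, severity = severity, message = message)

  ind <- bundle$individuals
  need <- c("species", "plot", "VD", "VF", "FL", "FW", "WD", "H")
  miss <- setdiff(need, names(ind))
  if (length(miss))
    note("individuals.columns", "fatal",
         paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (any(!is.na(ind$VD) & (ind$VD < 10 | ind$VD > 500)))
      note("individuals.VD_range", "warning",
           "vessel diameters outside 10-500 um; check units (mm vs um?)")
    if (any(!is.na(ind$WD) & (ind$WD <= 0 | ind$WD > 1.5)))
      note("individuals.WD_range", "warning",
           "wood densities outside (0, 1.5] g cm^-3")
    if (anyDuplicated(ind))
      note("individuals.duplicates", "warning", "duplicated individual rows")
  }
  if (!all(c("plot", "x", "y") %in% names(bundle$plots)))
    note("plots.columns", "fatal", "plot table needs plot, x, y columns")
  else if (!all(unique(ind$plot) %in% bundle$plots$plot))
    note("plots.reconcile", "fatal",
         paste("plots missing from plot table:",
               paste(setdiff(unique(ind$plot), bundle$plots$plot),
                     collapse = ", ")))
  if (!is.null(bundle$species) &&
      !all(unique(ind$species) %in% bundle$species$species))
    note("species.reconcile", "fatal",
         paste("species missing from species table:",
               paste(setdiff(unique(ind$species), bundle$species$species),
                     collapse = ", ")))
  if (!is.null(bundle$tree)) {
    absent <- unique(ind$species)[
      is.na(match(.canonical_name(unique(ind$species)),
                  .canonical_name(bundle$tree$tip.label)))]
    if (length(absent))
      note("tree.reconcile", "fatal",
           paste("species not in tree:", paste(absent, collapse = ", ")))
  }
  if (!is.null(bundle$presence)) {
    combos <- unique(ind[c("species", "plot")])
    bad <- vapply(seq_len(nrow(combos)), function(r) {
      s <- combos$species[r]; p <- combos$plot[r]
      !(s %in% rownames(bundle$presence)) ||
        !(p %in% colnames(bundle$presence)) ||
        bundle$presence[s, p] == 0
    }, logical(1))
    if (any(bad))
      note("presence.consistency", "warning",
           "individuals recorded in plots marked absent in the presence matrix")
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(check = character(0), severity = character(0),
               message = character(0))
  attr(report, "ok") <- !any(report$severity == "fatal")
  report
}

#' Run the full analysis pipeline
#'
#' Orders the stages: derived variables -> species means -> correlations and
#' PCA -> RDPI -> distance matrices -> MRM -> co-occurrence -> phylogenetic
#' signal, PGLS model selection and phylogenetic ANOVA. Stages that need a
#' phylogeny are skipped with a message when the bundle has no tree. When
#' `out_dir` is given, every result is written as CSV with a metadata
#' header plus a JSON run manifest (package version, seeds, parameters,
#' input checksums where inputs came from files).
#'
#' @param bundle study bundle (see [validate_inputs()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return named list of stage results (invisibly writes files when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(bundle, config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()", call. = FALSE)
  report <- validate_inputs(bundle)
  if (!attr(report, "ok"))
    stop("input validation failed:\n",
         paste(report$message[report$severity == "fatal"], collapse = "\n"),
         call. = FALSE)
  res <- list(validation = report)
  ind <- bundle$individuals

  # stage: derived variables -------------------------------------------
  dv <- derive_vessel_variables(ind$VD, ind$VF,
                                VA = if ("VA" %in% names(ind)) ind$VA else NULL)
  ind <- cbind(ind[setdiff(names(ind), c("VA", "S", "F", "VI", "RC"))], dv)
  res$individuals_derived <- ind
  derived <- c("S", "F", "VI", "RC")
  all_traits <- union(config$traits, derived)

  # stage: species means ------------------------------------------------
  sm <- species_means(ind, traits = all_traits, log10 = config$log10)
  res$species_means <- sm

  # stage: environmental screen -----------------------------------------
  env_cols <- intersect(config$env_variables, names(bundle$plots))
  if (length(env_cols) >= 2) {
    res$vif <- select_variables_vif(bundle$plots[env_cols],
                                    threshold = config$vif_threshold)
    env_cols <- res$vif$retained
  }

  # stage: correlations + PCA -------------------------------------------
  tr_tab <- sm[setdiff(names(sm), "species")]
  rownames(tr_tab) <- sm$species
  res$correlations_raw <- correlation_matrix(tr_tab, "raw")
  res$pca_traits <- trait_pca(tr_tab, exclude = c("VA", "S"))

  # stage: RDPI -> distances -> MRM --------------------------------------
  res$rdpi <- rdpi_table(ind, traits = config$traits)
  multi_plot <- setdiff(sort(unique(ind$species)), attr(res$rdpi, "excluded"))
  all_plots <- sort(unique(as.character(ind$plot)))
  geo <- geographic_distance(bundle$plots)[all_plots, all_plots]
  env <- environmental_distance(bundle$plots, env_cols)[all_plots, all_plots]
  res$mrm <- list()
  if (!is.null(bundle$species) && "section" %in% names(bundle$species)) {
    secs <- split(bundle$species$species, bundle$species$section)
    for (sec in names(secs)) {
      for (tr in config$mrm_traits) {
        sp_ok <- intersect(secs[[sec]], multi_plot)
        if (length(sp_ok) < 1) next
        mats <- lapply(sp_ok, function(s)
          rdpi_plot_pair_matrix(ind, s, tr, plots = all_plots))
        resp <- section_mean(mats)
        resp[!is.na(resp)] <- rdpi_transform(resp[!is.na(resp)])
        fit <- tryCatch(
          mrm(resp, list(environment = env, geography = geo),
              n_permutations = config$n_permutations, seed = config$seed),
          error = function(e) e$message)
        res$mrm[[paste(sec, tr, sep = ".")]] <- fit
      }
    }
  }

  # stage: co-occurrence --------------------------------------------------
  if (!is.null(bundle$presence))
    res$cooccurrence <- cooccurrence_table(bundle$presence,
                                           alpha = config$alpha)

  # stage: phylogenetic comparative ---------------------------------------
  if (is.null(bundle$tree)) {
    message("no tree in bundle: skipping contrasts, K, PGLS and ",
            "phylogenetic ANOVA")
  } else {
    tree <- prune_tree(bundle$tree,
                       reconcile_names(bundle$tree, sm$species,
                                       partial = TRUE))
    res$tree_used <- tree
    tr_phy <- tr_tab[tree$tip.label, , drop = FALSE]
    res$correlations_pic <- correlation_matrix(tr_phy, "pic", tree = tree)
    pic_mat <- as.data.frame(lapply(tr_phy, function(v)
      pic_contrasts(tree, stats::setNames(v, rownames(tr_phy)))))
    res$pca_pic <- trait_pca(pic_mat, exclude = c("VA", "S"))
    res$blomberg_k <- lapply(stats::setNames(nm = config$traits), function(tr)
      blomberg_k(tree, stats::setNames(tr_phy[[tr]], rownames(tr_phy)),
                 n_randomizations = config$n_randomizations,
                 seed = config$seed))
    # species-level environment: mean over occupied plots
    env_sp <- do.call(rbind, lapply(rownames(tr_phy), function(s) {
      pl <- unique(ind$plot[ind$species == s])
      colMeans(bundle$plots[match(pl, bundle$plots$plot), env_cols,
                            drop = FALSE])
    }))
    rownames(env_sp) <- rownames(tr_phy)
    res$pgls <- lapply(stats::setNames(nm = config$traits), function(tr)
      pgls_select(tree, stats::setNames(tr_phy[[tr]], rownames(tr_phy)),
                  as.data.frame(env_sp)))
    if (!is.null(bundle$species) && "habit" %in% names(bundle$species)) {
      grp <- stats::setNames(bundle$species$habit, bundle$species$species)
      grp <- grp[tree$tip.label]
      if (all(table(grp) >= 2) && length(unique(grp)) >= 2) {
        res$phyl_anova <- lapply(stats::setNames(nm = config$traits),
          function(tr) phyl_anova(tree,
            stats::setNames(tr_phy[[tr]], rownames(tr_phy)), grp,
            n_simulations = config$n_simulations, seed = config$seed))
      } else {
        message("habit groups too small for phylogenetic ANOVA; skipped")
      }
    }
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, bundle, config, out_dir)
  res
}

# ---------------------------------------------------------------------------
# CSV / Newick IO

#' Write a result table as CSV with a metadata header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded in the `#` header comment line.
#' @export
write_result_csv <- function(df, path, params = list()) {
  meta <- sprintf("# oaktraits %s | %s",
                  as.character(utils::packageVersion("oaktraits")),
                  paste(names(params), unlist(params), sep = "=",
                        collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_result_csv()] (or any plain CSV)
#' @param path input path.
#' @return data.frame (metadata comment lines are skipped).
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a simulated study bundle to a directory
#'
#' One CSV per table (`individuals.csv`, `plots.csv`, `species.csv`,
#' `presence.csv`) plus `tree.nwk`; consumable by [read_study_bundle()].
#'
#' @param sim output of [simulate_study()] (or any bundle-shaped list).
#' @param dir output directory (created if needed).
#' @export
write_study_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = if (!is.null(sim$truth)) sim$truth$seed else NA)
  write_result_csv(sim$individuals, file.path(dir, "individuals.csv"), params)
  write_result_csv(sim$plots, file.path(dir, "plots.csv"), params)
  write_result_csv(sim$species, file.path(dir, "species.csv"), params)
  pres <- data.frame(species = rownames(sim$presence), sim$presence,
                     check.names = FALSE)
  write_result_csv(pres, file.path(dir, "presence.csv"), params)
  if (!is.null(sim$tree))
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Read a study bundle from a directory
#' @param dir directory written by [write_study_bundle()].
#' @return bundle list (`individuals`, `plots`, `species`, `presence`,
#'   `tree` when present) with the source paths in attribute `"paths"`.
#' @export
read_study_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  bundle <- list(
    individuals = read_result_csv(path("individuals.csv")),
    plots = read_result_csv(path("plots.csv")),
    species = read_result_csv(path("species.csv"))
  )
  pres <- read_result_csv(path("presence.csv"))
  m <- as.matrix(pres[-1])
  rownames(m) <- pres$species
  bundle$presence <- m
  if (file.exists(path("tree.nwk"))) bundle$tree <- read_tree(path("tree.nwk"))
  files <- list.files(dir, full.names = TRUE)
  attr(bundle, "paths") <- files
  bundle
}

# write every pipeline result + manifest
write_pipeline_outputs <- function(res, bundle, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = config$seed)
  write_result_csv(res$species_means, file.path(out_dir, "species_means.csv"),
                   params)
  write_result_csv(res$rdpi, file.path(out_dir, "rdpi.csv"), params)
  write_result_csv(as.data.frame(res$correlations_raw$r),
                   file.path(out_dir, "correlations_raw.csv"), params)
  if (!is.null(res$cooccurrence))
    write_result_csv(res$cooccurrence$pairs,
                     file.path(out_dir, "cooccurrence_pairs.csv"), params)
  if (length(res$mrm)) {
    mrm_tab <- do.call(rbind, lapply(names(res$mrm), function(nm) {
      f <- res$mrm[[nm]]
      if (!inherits(f, "mrm_fit"))
        return(data.frame(model = nm, term = NA, estimate = NA, p_value = NA,
                          r_squared = NA, p_r_squared = NA))
      cbind(model = nm, f$coefficients, r_squared = f$r_squared,
            p_r_squared = f$p_r_squared)
    }))
    write_result_csv(mrm_tab, file.path(out_dir, "mrm.csv"), params)
  }
  if (!is.null(res$blomberg_k)) {
    ktab <- data.frame(trait = names(res$blomberg_k),
                       K = vapply(res$blomberg_k, `[[`, numeric(1), "K"),
                       p_value = vapply(res$blomberg_k, `[[`, numeric(1),
                                        "p_value"))
    write_result_csv(ktab, file.path(out_dir, "blomberg_k.csv"), params)
  }
  if (!is.null(res$pgls)) {
    ptab <- do.call(rbind, lapply(names(res$pgls), function(tr)
      cbind(trait = tr, res$pgls[[tr]]$aic_table)))
    write_result_csv(ptab, file.path(out_dir, "pgls_aic.csv"), params)
  }
  if (!is.null(res$phyl_anova)) {
    atab <- data.frame(trait = names(res$phyl_anova),
                       F = vapply(res$phyl_anova, `[[`, numeric(1), "F"),
                       p_value = vapply(res$phyl_anova, `[[`, numeric(1),
                                        "p_value"))
    write_result_csv(atab, file.path(out_dir, "phyl_anova.csv"), params)
  }
  checksums <- NULL
  paths <- attr(bundle, "paths")
  if (!is.null(paths)) checksums <- as.list(tools::md5sum(paths))
  manifest <- list(
    package = "oaktraits",
    version = as.character(utils::packageVersion("oaktraits")),
    seed = config$seed,
    parameters = unclass(config),
    input_checksums = checksums,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
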