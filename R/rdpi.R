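# Relative distance plasticity index (RDPI) and the associated tests.
#
# RDPI for one species and one trait is the mean, over all pairs of
# individuals growing under different conditions (here: plots), of the
# relative pairwise distance |x' - x| / (x' + x). It ranges from 0 (no
# plasticity) to 1 (maximal plasticity) for nonnegative traits.

.rdpi_pairs <- function(a, b) {
  # all cross pairs between two value vectors; 0/0 pairs contribute 0
  d <- abs(outer(b, a, "-"))
  s <- outer(b, a, "+")
  ratio <- ifelse(s == 0, 0, d / s)
  list(sum = sum(ratio), n = length(ratio))
}

#' Relative distance plasticity index
#'
#' @param values_by_plot named list mapping plot identifiers to vectors of
#'   nonnegative trait values for the individuals of one species in that
#'   plot.
#' @return list with `rdpi` (in `[0, 1]`) and `n_pairs`, the number of
#'   cross-plot individual pairs averaged. Pairs within a plot are excluded
#'   (the index compares individuals under *different* conditions); pairs
#'   with both values zero contribute 0.
#' @examples
#' rdpi(list(A = c(1, 2), B = c(2, 4)))
#' @export
rdpi <- function(values_by_plot) {
  if (!is.list(values_by_plot) || length(values_by_plot) < 2L)
    stop("no cross-environment pairs: need individuals from at least two plots",
         call. = FALSE)
  vals <- lapply(values_by_plot, as.numeric)
  if (any(vapply(vals, length, integer(1)) < 1L))
    stop("every plot must contribute at least one individual", call. = FALSE)
  if (any(unlist(vals) < 0, na.rm = TRUE))
    stop("trait values must be nonnegative", call. = FALSE)
  if (anyNA(unlist(vals)))
    stop("missing trait values", call. = FALSE)
  total <- 0
  n <- 0L
  k <- length(vals)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      pp <- .rdpi_pairs(vals[[i]], vals[[j]])
      total <- total + pp$sum
      n <- n + pp$n
    }
  }
  list(rdpi = total / n, n_pairs = n)
}

#' RDPI for every species and trait in an individual-level table
#'
#' Species recorded in a single plot carry no cross-environment information
#' and are excluded with a message (the standard exclusion rule for
#' single-plot species).
#'
#' @param records data.frame with `species`, `plot` and trait columns.
#' @param traits character vector of trait column names.
#' @param species optional subset of species to evaluate.
#' @return data.frame with columns `species`, `trait`, `rdpi`, `n_pairs`,
#'   plus an attribute `"excluded"` listing single-plot species.
#' @export
rdpi_table <- function(records, traits, species = NULL) {
  stopifnot(all(c("species", "plot") %in% names(records)))
  missing_cols <- setdiff(traits, names(records))
  if (length(missing_cols))
    stop("trait column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(species)) {
    records <- records[records$species %in% species, , drop = FALSE]
    if (!nrow(records))
      stop("no records left for the requested species", call. = FALSE)
  }
  sp <- sort(unique(records$species))
  n_plots <- vapply(sp, function(s)
    length(unique(records$plot[records$species == s])), integer(1))
  excluded <- sp[n_plots < 2L]
  if (length(excluded))
    message("excluding single-plot species: ", paste(excluded, collapse = ", "))
  sp <- sp[n_plots >= 2L]
  out <- expand.grid(species = sp, trait = traits, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$rdpi <- NA_real_
  out$n_pairs <- NA_integer_
  for (r in seq_len(nrow(out))) {
    sub <- records[records$species == out$species[r], , drop = FALSE]
    res <- rdpi(split(sub[[out$trait[r]]], sub$plot))
    out$rdpi[r] <- res$rdpi
    out$n_pairs[r] <- res$n_pairs
  }
  attr(out, "excluded") <- excluded
  out
}

#' Arcsine-square-root transform for RDPI values
#'
#' The standard variance-stabilizing transform for proportions,
#' \eqn{\arcsin\sqrt{x}}, applied before distance-matrix regression.
#'
#' @param values numeric values in `[0, 1]`.
#' @return transformed values in `[0, pi/2]`.
#' @export
rdpi_transform <- function(values) {
  if (any(!is.na(values) & (values < 0 | values > 1)))
    stop("values must lie in [0, 1]", call. = FALSE)
  asin(sqrt(values))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom (the
#' fractional-df form), used to compare RDPI values between phylogenetic
#' sections. Wraps [stats::t.test()]; when both groups are constant the
#' statistic is defined by convention (equal means: t = 0, P = 1; unequal
#' means: infinite t, P = 0).
#'
#' @param group_a,group_b numeric vectors, at least two values each.
#' @return list with `t`, `df` and two-sided `p_value`.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least two values per group", call. = FALSE)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
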