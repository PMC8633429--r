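# Plot-pair distance matrices: RDPI, geographic and environmental.
#
# All distance matrices are plain symmetric numeric matrices with plot
# identifiers as dimnames and a zero diagonal; RDPI matrices may contain NA
# where a species is absent from one of the two plots.

.as_square_labelled <- function(m, what) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop(what, " must be a square matrix with matching row/column labels",
         call. = FALSE)
  m
}

#' Geographic distance matrix between plots
#'
#' Euclidean distance on planar coordinates.
#'
#' @param plots data.frame with `plot`, `x` and `y` columns (same length
#'   unit for `x` and `y`).
#' @return symmetric matrix of distances, plots as dimnames.
#' @export
geographic_distance <- function(plots) {
  stopifnot(all(c("plot", "x", "y") %in% names(plots)))
  if (anyNA(plots[c("x", "y")]))
    stop("missing coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(plots[c("x", "y")]))
  dimnames(d) <- list(plots$plot, plots$plot)
  d
}

#' Environmental distance matrix between plots
#'
#' Each variable is centred and scaled to unit standard deviation (to
#' remove the different measurement units), then plots are compared by
#' Euclidean distance in the standardized space.
#'
#' @param plots data.frame with a `plot` column and the variables.
#' @param variables character vector of variable columns to use.
#' @return symmetric matrix of distances, plots as dimnames.
#' @export
environmental_distance <- function(plots, variables) {
  stopifnot("plot" %in% names(plots))
  missing_cols <- setdiff(variables, names(plots))
  if (length(missing_cols))
    stop("variable(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  z <- plots[variables]
  if (anyNA(z)) stop("missing environmental values", call. = FALSE)
  sds <- vapply(z, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant variable(s) cannot be scaled: ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  d <- as.matrix(stats::dist(scale(z)))
  dimnames(d) <- list(plots$plot, plots$plot)
  d
}

#' Plot-pair RDPI matrix for one species and trait
#'
#' Entry (p, q) is the RDPI restricted to individual pairs drawn one from
#' plot p and one from plot q; entries are `NA` when the species is absent
#' from either plot. The pair-count-weighted mean of the off-diagonal
#' entries equals the scalar [rdpi()] of the species.
#'
#' @param records individual-level data.frame (`species`, `plot`, traits).
#' @param species species identifier to restrict to.
#' @param trait trait column name.
#' @param plots optional character vector fixing the matrix labels (useful
#'   to align matrices across species); defaults to the plots where the
#'   species occurs.
#' @return symmetric matrix with attribute `"n_pairs"` (pair counts).
#' @export
rdpi_plot_pair_matrix <- function(records, species, trait, plots = NULL) {
  stopifnot(all(c("species", "plot", trait) %in% names(records)))
  sub <- records[records$species == species, , drop = FALSE]
  if (!nrow(sub)) stop("species not present in records", call. = FALSE)
  occupied <- sort(unique(as.character(sub$plot)))
  if (length(occupied) < 2L)
    stop("species occurs in fewer than two plots", call. = FALSE)
  if (is.null(plots)) plots <- occupied
  plots <- as.character(plots)
  k <- length(plots)
  m <- matrix(NA_real_, k, k, dimnames = list(plots, plots))
  np <- matrix(0L, k, k, dimnames = list(plots, plots))
  vals <- split(sub[[trait]], as.character(sub$plot))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      a <- vals[[plots[i]]]
      b <- vals[[plots[j]]]
      if (is.null(a) || is.null(b)) next
      pp <- .rdpi_pairs(a, b)
      m[i, j] <- m[j, i] <- pp$sum / pp$n
      np[i, j] <- np[j, i] <- pp$n
    }
  }
  diag(m) <- ifelse(plots %in% occupied, 0, NA_real_)
  attr(m, "n_pairs") <- np
  m
}

#' Entrywise mean of distance matrices over a set of species
#'
#' Averages per-species RDPI plot-pair matrices into one matrix (typically
#' per phylogenetic section), ignoring missing entries; an entry missing in
#' every matrix stays missing.
#'
#' @param matrices list of square matrices with identical labels.
#' @return symmetric matrix of entrywise means.
#' @export
section_mean <- function(matrices) {
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  matrices <- lapply(matrices, .as_square_labelled, what = "each matrix")
  labs <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), labs))
      stop("matrices must share identical labels", call. = FALSE)
  arr <- array(unlist(matrices), dim = c(length(labs), length(labs),
                                         length(matrices)))
  out <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  dimnames(out) <- list(labs, labs)
  out
}
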