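# Trait correlations (raw and on independent contrasts) and PCA.

#' Pairwise trait correlations, raw or on independent contrasts
#'
#' Raw mode: ordinary Pearson correlations among species means with
#' [stats::cor.test()] P-values. PIC mode: the correlation of the two
#' contrast sets through the origin, \eqn{r = \sum xy / \sqrt{\sum x^2 \sum
#' y^2}} (contrasts have no defined mean, so the regression is forced
#' through zero; the formula is invariant to paired sign flips of the
#' contrasts), with significance from the through-origin regression t on
#' `n_tips - 2` degrees of freedom.
#'
#' @param traits data.frame of species-level trait values, rows named by
#'   species (or with a `species` column).
#' @param mode `"raw"` or `"pic"`.
#' @param tree required for `mode = "pic"`.
#' @return list with matrices `r`, `p_value` and `n` (pairs used).
#'   Zero-variance traits give `NA` entries with a warning.
#' @export
correlation_matrix <- function(traits, mode = c("raw", "pic"), tree = NULL) {
  mode <- match.arg(mode)
  traits <- .species_rownames(traits)
  if (nrow(traits) < 3L) stop("need at least three species", call. = FALSE)
  vars <- names(traits)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  constant <- vapply(traits, function(v) stats::var(v) == 0, logical(1))
  if (any(constant))
    warning("zero-variance trait(s): ", paste(vars[constant], collapse = ", "),
            call. = FALSE)

  if (mode == "pic") {
    if (is.null(tree)) stop("mode = \"pic\" requires a tree", call. = FALSE)
    contrasts <- lapply(traits, function(v)
      pic_contrasts(tree, stats::setNames(v, rownames(traits))))
    df <- length(tree$tip.label) - 2
  }

  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (constant[i] || constant[j]) next
      if (mode == "raw") {
        ct <- stats::cor.test(traits[[i]], traits[[j]])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      } else {
        cx <- contrasts[[i]]
        cy <- contrasts[[j]]
        rij <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
        tval <- rij * sqrt(df / (1 - rij^2))
        r[i, j] <- r[j, i] <- rij
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tval), df)
      }
    }
  }
  n <- matrix(nrow(traits), k, k, dimnames = list(vars, vars))
  if (mode == "pic") n[] <- nrow(traits) - 1
  list(r = r, p_value = p, n = n, mode = mode)
}

#' Combined raw / contrast correlation table
#'
#' One square matrix with the raw Pearson correlations below the diagonal
#' and the independent-contrast correlations above it — the conventional
#' layout for reporting both side by side.
#'
#' @inheritParams correlation_matrix
#' @return square matrix (diagonal `NA`).
#' @export
combined_correlation_table <- function(traits, tree) {
  raw <- correlation_matrix(traits, "raw")
  pic <- correlation_matrix(traits, "pic", tree = tree)
  out <- raw$r
  out[upper.tri(out)] <- pic$r[upper.tri(pic$r)]
  diag(out) <- NA_real_
  out
}

#' Principal component analysis of a trait table
#'
#' Eigendecomposition of the correlation (`standardize = TRUE`) or
#' covariance matrix via [stats::prcomp()]. Percent variances always sum
#' to 100. Works equally on species means and on independent contrasts.
#'
#' @param data numeric data.frame or matrix (rows = species or contrasts).
#' @param standardize scale each variable to unit variance (correlation
#'   PCA, the default).
#' @param exclude optional variable names to drop first (e.g. redundant
#'   derived variables).
#' @return list with `loadings`, `scores`, `sdev` and `percent_variance`.
#' @export
trait_pca <- function(data, standardize = TRUE, exclude = NULL) {
  data <- as.data.frame(data)
  if (!is.null(exclude)) data <- data[setdiff(names(data), exclude)]
  if (ncol(data) < 2L) stop("need at least two variables", call. = FALSE)
  if (nrow(data) <= ncol(data))
    message("fewer rows than variables + 1; trailing components are degenerate")
  if (standardize) {
    sds <- vapply(data, stats::sd, numeric(1))
    if (any(sds == 0))
      stop("constant column(s) under standardization: ",
           paste(names(data)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(data, center = TRUE, scale. = standardize)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, scores = pc$x, sdev = pc$sdev,
       percent_variance = pv)
}

# accept either species row names or a species column
.species_rownames <- function(traits) {
  traits <- as.data.frame(traits)
  if ("species" %in% names(traits)) {
    rownames(traits) <- traits$species
    traits$species <- NULL
  }
  num <- vapply(traits, is.numeric, logical(1))
  traits[num]
}
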