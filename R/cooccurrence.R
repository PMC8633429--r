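# Probabilistic pairwise species co-occurrence.
#
# Under the null that two species occupy sites independently, the number of
# jointly occupied sites follows the exact hypergeometric distribution; each
# pair is classified as a positive, negative or random association from the
# exact tail probabilities.

#' Exact co-occurrence probability mass function
#'
#' For species occupying `n1` and `n2` of `N` sites independently, the
#' probability of observing exactly `j` shared sites is
#' \eqn{P(j) = C(n_1, j) C(N - n_1, n_2 - j) / C(N, n_2)} on the support
#' \eqn{\max(0, n_1 + n_2 - N) \le j \le \min(n_1, n_2)}.
#'
#' @param N total number of sites.
#' @param n1,n2 number of sites occupied by each species (each `<= N`).
#' @return data.frame with columns `j` and `p` over the support.
#' @examples
#' pair_pmf(N = 2, n1 = 1, n2 = 1)
#' @export
pair_pmf <- function(N, n1, n2) {
  stopifnot(length(N) == 1, length(n1) == 1, length(n2) == 1)
  if (N < 1 || n1 < 0 || n2 < 0) stop("counts must be nonnegative", call. = FALSE)
  if (n1 > N || n2 > N)
    stop("occupied-site counts cannot exceed the number of sites", call. = FALSE)
  j <- seq(max(0, n1 + n2 - N), min(n1, n2))
  data.frame(j = j, p = stats::dhyper(j, n1, N - n1, n2))
}

#' Classify one species pair
#'
#' Tail probabilities include the observed value in both tails (the
#' standard convention for this exact model, and the source of its
#' conservativeness): `p_lt` is the probability of `j <=` observed, `p_gt`
#' of `j >=` observed. The pair is labelled `"positive"` when `p_gt <
#' alpha`, `"negative"` when `p_lt < alpha`, otherwise `"random"`.
#'
#' @param N,n1,n2 as in [pair_pmf()].
#' @param observed observed number of jointly occupied sites; must lie in
#'   the support of the pmf.
#' @param alpha significance threshold (default 0.05).
#' @return one-row data.frame: `n1`, `n2`, `observed`, `expected`
#'   (`n1 * n2 / N`), `p_lt`, `p_gt`, `label`.
#' @export
classify_pair <- function(N, n1, n2, observed, alpha = 0.05) {
  pmf <- pair_pmf(N, n1, n2)
  if (!observed %in% pmf$j)
    stop("'observed' lies outside the support of the co-occurrence pmf",
         call. = FALSE)
  p_lt <- sum(pmf$p[pmf$j <= observed])
  p_gt <- sum(pmf$p[pmf$j >= observed])
  label <- if (p_gt < alpha) "positive" else if (p_lt < alpha) "negative" else "random"
  data.frame(n1 = n1, n2 = n2, observed = observed, expected = n1 * n2 / N,
             p_lt = p_lt, p_gt = p_gt, label = label)
}

#' Pairwise co-occurrence analysis of a presence-absence matrix
#'
#' Evaluates every unordered species pair (`S(S-1)/2` pairs for `S`
#' species). By default no pair is filtered by expected co-occurrence; set
#' `filter_expected = TRUE` to drop pairs with expectation below
#' `min_expected` (a compatibility option with common implementations).
#'
#' @param presence species-by-plots matrix (0/1 or logical), species as row
#'   names.
#' @param alpha significance threshold (default 0.05).
#' @param filter_expected drop pairs with expected co-occurrence below
#'   `min_expected`?
#' @param min_expected expectation threshold used when filtering.
#' @return list with `pairs` (one row per evaluated pair: `species_1`,
#'   `species_2`, counts, tail probabilities, `label`) and `summary`
#'   (counts and full-precision percentages of each label, total pairs,
#'   `N` plots).
#' @export
cooccurrence_table <- function(presence, alpha = 0.05,
                               filter_expected = FALSE, min_expected = 1) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("sp", seq_len(nrow(presence)))
  occ <- presence > 0
  counts <- rowSums(occ)
  if (any(counts == 0)) {
    warning("excluding species with zero occurrences: ",
            paste(rownames(occ)[counts == 0], collapse = ", "), call. = FALSE)
    occ <- occ[counts > 0, , drop = FALSE]
    counts <- counts[counts > 0]
  }
  S <- nrow(occ)
  if (S < 2L) stop("need at least two species with occurrences", call. = FALSE)
  N <- ncol(occ)
  idx <- utils::combn(S, 2)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    obs <- sum(occ[i, ] & occ[j, ])
    res <- classify_pair(N, counts[[i]], counts[[j]], obs, alpha = alpha)
    rows[[k]] <- cbind(data.frame(species_1 = rownames(occ)[i],
                                  species_2 = rownames(occ)[j]), res)
  }
  pairs <- do.call(rbind, rows)
  if (filter_expected)
    pairs <- pairs[pairs$expected >= min_expected, , drop = FALSE]
  lab <- factor(pairs$label, levels = c("positive", "negative", "random"))
  cnt <- table(lab)
  summary <- list(
    n_species = S, n_plots = N, total_pairs = nrow(pairs),
    positive = unname(cnt["positive"]), negative = unname(cnt["negative"]),
    random = unname(cnt["random"]),
    percent = stats::setNames(100 * as.numeric(cnt) / nrow(pairs), names(cnt))
  )
  list(pairs = pairs, summary = summary)
}
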