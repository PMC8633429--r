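# Phylogenetically independent contrasts (Felsenstein's algorithm).
#
# One post-order pass: at each internal node the standardized contrast is
# (x_L - x_R) / sqrt(v_L + v_R), the nodal value is the variance-weighted
# mean of the daughters, and the branch below the node is lengthened by
# v_L v_R / (v_L + v_R).

#' Phylogenetically independent contrasts
#'
#' @param tree a binary `phylo` object with branch lengths. Polytomies are
#'   resolved to zero-length binary branches when `resolve_polytomies =
#'   TRUE` (the default); otherwise they raise an error.
#' @param x tip values, named by tip label (or unnamed in tip order).
#' @param scaled divide each contrast by the square root of its expected
#'   variance (default TRUE).
#' @return numeric vector of `n_tips - 1` contrasts, named by internal node
#'   number, with attribute `"variance"` holding the expected variance
#'   (`v_L + v_R`) of each contrast.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 3, B = 1, C = 2))
#' @export
pic_contrasts <- function(tree, x, scaled = TRUE, resolve_polytomies = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (!ape::is.binary(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; resolve them or set resolve_polytomies = TRUE",
           call. = FALSE)
    tree <- ape::multi2di(tree)
  }
  x <- .match_tip_values(tree, x)
  n <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  e1 <- tr$edge[, 1]
  e2 <- tr$edge[, 2]
  el <- tr$edge.length
  nn <- n + tr$Nnode
  val <- numeric(nn)
  val[seq_len(n)] <- x
  extra <- numeric(nn)
  contrast <- numeric(tr$Nnode)
  cvar <- numeric(tr$Nnode)
  for (node in unique(e1)) {
    idx <- which(e1 == node)
    if (length(idx) != 2L)
      stop("internal node with ", length(idx), " daughters after resolution",
           call. = FALSE)
    c1 <- e2[idx[1]]
    c2 <- e2[idx[2]]
    v1 <- el[idx[1]] + extra[c1]
    v2 <- el[idx[2]] + extra[c2]
    if (v1 + v2 <= 0)
      stop("zero-length daughter pair at node ", node,
           ": contrasts undefined", call. = FALSE)
    k <- node - n
    d <- val[c1] - val[c2]
    contrast[k] <- if (scaled) d / sqrt(v1 + v2) else d
    cvar[k] <- v1 + v2
    val[node] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
    extra[node] <- v1 * v2 / (v1 + v2)
  }
  names(contrast) <- as.character(seq(n + 1L, nn))
  attr(contrast, "variance") <- cvar
  contrast
}
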