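# Tree handling: reading, pruning, and reconciling tip labels with trait
# tables. Trees are ape "phylo" objects throughout.

#' Read a rooted, branch-lengthed Newick tree
#'
#' @param source a Newick string or the path of a Newick file.
#' @return a `phylo` object; errors if the tree is unrooted, lacks branch
#'   lengths, or has negative branch lengths.
#' @export
read_tree <- function(source) {
  tree <- suppressWarnings(
    if (length(source) == 1L && file.exists(source)) ape::read.tree(source)
    else ape::read.tree(text = source))
  if (is.null(tree)) stop("malformed Newick input", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree
}

#' Prune a tree to a set of tips
#'
#' Removes all tips not in `keep_tips` and collapses the resulting
#' unifurcations, summing branch lengths across suppressed nodes.
#'
#' @param tree a `phylo` object.
#' @param keep_tips tip labels to retain.
#' @return the pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep_tips) {
  unmatched <- setdiff(keep_tips, tree$tip.label)
  if (length(unmatched))
    stop("tip(s) not in tree: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  if (length(keep_tips) < 2L)
    stop("need at least two tips after pruning", call. = FALSE)
  if (setequal(keep_tips, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep_tips)
}

.canonical_name <- function(x) gsub("[ _]+", "_", trimws(tolower(x)))

#' Reconcile species names between a tree and a table
#'
#' Case-insensitive matching with underscores and spaces unified. Returns
#' the table names re-labelled to the tree's tip labels; unmatched names on
#' either side are listed before failing.
#'
#' @param tree a `phylo` object.
#' @param names character vector of species names to reconcile.
#' @param partial allow `names` to cover only a subset of the tips
#'   (default FALSE: every tip must be matched).
#' @return character vector of tree tip labels, parallel to `names`.
#' @export
reconcile_names <- function(tree, names, partial = FALSE) {
  tip_canon <- .canonical_name(tree$tip.label)
  name_canon <- .canonical_name(names)
  hit <- match(name_canon, tip_canon)
  problems <- character(0)
  if (anyNA(hit))
    problems <- c(problems, paste0("not in tree: ",
                                   paste(names[is.na(hit)], collapse = ", ")))
  if (!partial && !all(tip_canon %in% name_canon))
    problems <- c(problems,
                  paste0("tips without data: ",
                         paste(tree$tip.label[!tip_canon %in% name_canon],
                               collapse = ", ")))
  if (length(problems))
    stop("name reconciliation failed; ", paste(problems, collapse = "; "),
         call. = FALSE)
  tree$tip.label[hit]
}

# order a named tip-value vector to tree$tip.label, with validation
.match_tip_values <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop("unnamed trait vector of wrong length", call. = FALSE)
    names(x) <- tree$tip.label
    return(x)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("missing trait value for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("missing trait values", call. = FALSE)
  x
}
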