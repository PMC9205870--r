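#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. Total
#' branch length is conserved. A tree whose branch lengths are all zero has
#' no defined midpoint; it is returned rooted as-is (at its existing basal
#' node).
#'
#' @param tree an \code{ape} \code{phylo} object with branch lengths and
#'   at least two leaves.
#' @return A rooted \code{phylo}.
#' @export
midpointRoot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("midpoint rooting needs >= 2 leaves")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) == 0) return(tree)
  phangorn::midpoint(tree)
}

#' Branch-length attribution between new and known leaves
#'
#' Splits the total branch length of a rooted tree into two categories:
#' (1) branches whose entire descendant leaf set lies in \code{newSet}
#' (clades made exclusively of the new genomes), and (2) everything else.
#' The two sums conserve the total branch length for any \code{newSet}.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param newSet character vector of leaf labels forming the "new" set;
#'   must all be tree leaves.
#' @return Named numeric vector \code{c(new_only = , other = )}.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' pdCategories(tr, c("A", "B"))  # c(new_only = 3, other = 3)
#' @export
pdCategories <- function(tree, newSet) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(newSet, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown leaf label in newSet: ", unknown[1])
  ntip <- length(tree$tip.label)
  isNew <- tree$tip.label %in% newSet
  # post-order accumulation: does every tip below each node lie in newSet?
  allNew <- c(isNew, rep(NA, tree$Nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    if (is.na(allNew[parent])) allNew[parent] <- TRUE
    allNew[parent] <- allNew[parent] && allNew[child]
  }
  newOnly <- sum(tree$edge.length[allNew[tree$edge[, 2]]])
  c(new_only = newOnly, other = sum(tree$edge.length) - newOnly)
}

#' Phylogenetic-diversity expansion percentage
#'
#' The branch length contributed exclusively by the new genomes, as a
#' percentage of all other branch length: 100 x new_only / other.
#'
#' @param newOnly,other category sums from \code{\link{pdCategories}}.
#' @return Percent (NA when \code{other} is 0).
#' @export
pdExpansionPercent <- function(newOnly, other) {
  if (other == 0) return(NA_real_)
  100 * newOnly / other
}

#' One-call PD expansion from a tree and a new-leaf set
#'
#' Midpoint-roots the tree, attributes branch lengths, and returns the
#' expansion percentage with the category sums.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param newSet character vector of "new" leaf labels.
#' @return A one-row data.frame with \code{len_new_only},
#'   \code{len_other}, \code{total} and \code{expansion_pct}.
#' @export
pdExpansion <- function(tree, newSet) {
  rooted <- midpointRoot(tree)
  cats <- pdCategories(rooted, newSet)
  data.frame(len_new_only = cats[["new_only"]],
             len_other = cats[["other"]],
             total = sum(cats),
             expansion_pct = pdExpansionPercent(cats[["new_only"]],
                                                cats[["other"]]))
}
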