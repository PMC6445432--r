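# Rooting and pruning. Both operations treat branch lengths as optional:
# the attachment method itself is purely topological.

#' Root a tree on the branch separating an outgroup
#'
#' The tree is re-rooted on the edge that separates `outgroup` from the
#' remaining taxa; the length of that branch, when present, is divided equally
#' between the two children of the new root. The outgroup must form a split of
#' the unrooted tree.
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup taxon labels; a non-empty
#'   proper subset of the leaf set.
#' @return a rooted `phylo` whose root has exactly two children, one of them
#'   subtending `outgroup`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  outgroup <- normalise_label(outgroup)
  tips <- tree$tip.label
  if (length(outgroup) == 0L) stop("outgroup must be non-empty", call. = FALSE)
  unknown <- setdiff(outgroup, tips)
  if (length(unknown) > 0L) {
    stop(sprintf("outgroup taxa not in tree: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(outgroup) >= length(tips)) {
    stop("outgroup must be a proper subset of the leaf set", call. = FALSE)
  }
  key_og <- clade_key(outgroup)
  key_rest <- clade_key(setdiff(tips, outgroup))
  keys <- vapply(node_tipsets(tree), clade_key, character(1))
  if (!(key_og %in% keys || key_rest %in% keys)) {
    stop(sprintf("outgroup is not monophyletic in the unrooted tree: %s",
                 paste(sort(outgroup), collapse = ", ")), call. = FALSE)
  }
  phy <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
  # drop the placeholder label ape puts on the resolved root
  if (!is.null(phy$node.label)) {
    rl <- root_node(phy) - length(phy$tip.label)
    if (!is.na(phy$node.label[rl]) && phy$node.label[rl] == "Root") phy$node.label[rl] <- ""
  }
  # split the outgroup stem length equally between the two root children
  if (!is.null(phy$edge.length)) {
    r <- root_node(phy)
    rows <- which(phy$edge[, 1L] == r)
    if (length(rows) == 2L && !anyNA(phy$edge.length[rows])) {
      tot <- sum(phy$edge.length[rows])
      phy$edge.length[rows] <- tot / 2
    }
  }
  phy
}

#' Drop taxa from a tree
#'
#' Removes the listed leaves and suppresses the resulting degree-2 internal
#' nodes, summing branch lengths across merged edges. Support labels of
#' suppressed nodes are discarded (the surviving child keeps its own label).
#'
#' @param tree a `phylo` object.
#' @param drop character vector of leaf labels to remove (may be empty).
#' @return the pruned `phylo`; at least two leaves must remain.
#' @export
prune_taxa <- function(tree, drop) {
  drop <- normalise_label(drop)
  if (length(drop) == 0L) return(tree)
  tips <- tree$tip.label
  unknown <- setdiff(drop, tips)
  if (length(unknown) > 0L) {
    stop(sprintf("cannot drop taxa not in tree: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(setdiff(tips, drop)) < 2L) {
    stop("pruning must leave at least two leaves", call. = FALSE)
  }
  for (lab in drop) tree <- drop_one_tip(tree, lab)
  tree
}

# Remove a single tip by edge surgery, suppressing the degree-2 node this
# leaves behind (branch lengths summed, its support label discarded).
drop_one_tip <- function(tree, lab) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  r <- match(lab, tree$tip.label)
  ed <- tree$edge
  lens <- tree$edge.length
  row_r <- which(ed[, 2L] == r)
  p <- ed[row_r, 1L]
  siblings <- sum(ed[, 1L] == p)
  removed_internal <- NA_integer_
  new_root_old_id <- root
  if (siblings > 2L) {
    # polytomy: the parent keeps >= 2 children
    keep <- -row_r
    ed <- ed[keep, , drop = FALSE]
    if (!is.null(lens)) lens <- lens[keep]
  } else if (p == root) {
    # binary root: the sibling subtree becomes the new root
    c_row <- which(ed[, 1L] == p & ed[, 2L] != r)
    c_node <- ed[c_row, 2L]
    keep <- -c(row_r, c_row)
    ed <- ed[keep, , drop = FALSE]
    if (!is.null(lens)) lens <- lens[keep]
    removed_internal <- p
    new_root_old_id <- c_node
  } else {
    # binary internal: merge the two edges around the suppressed parent
    c_row <- which(ed[, 1L] == p & ed[, 2L] != r)
    g_row <- which(ed[, 2L] == p)
    ed[g_row, 2L] <- ed[c_row, 2L]
    if (!is.null(lens)) {
      a <- lens[g_row]
      b <- lens[c_row]
      lens[g_row] <- if (is.na(a)) b else if (is.na(b)) a else a + b
    }
    keep <- -c(row_r, c_row)
    ed <- ed[keep, , drop = FALSE]
    if (!is.null(lens)) lens <- lens[keep]
    removed_internal <- p
  }
  # renumber: tips close the gap left by r; internal ids are compacted with
  # the (possibly new) root first
  old_internal <- setdiff(unique(c(root, nt + seq_len(tree$Nnode))), removed_internal)
  old_internal <- c(new_root_old_id, sort(setdiff(old_internal, new_root_old_id)))
  map <- integer(nt + tree$Nnode)
  tips_kept <- setdiff(seq_len(nt), r)
  map[tips_kept] <- seq_along(tips_kept)
  map[old_internal] <- nt - 1L + seq_along(old_internal)
  tree$edge <- matrix(map[ed], ncol = 2L)
  tree$edge.length <- lens
  tree$tip.label <- tree$tip.label[tips_kept]
  if (!is.null(tree$node.label)) {
    labs <- tree$node.label[old_internal - nt]
    tree$node.label <- if (any(nzchar(labs))) labs else NULL
  }
  tree$Nnode <- length(old_internal)
  attr(tree, "order") <- NULL
  tree
}

#' Clades of a rooted tree
#'
#' Returns one clade per node of the tree (leaf clades included): the set of
#' leaf labels the node subtends. Names of the returned list are canonical
#' clade keys (see [clade_key()]).
#'
#' @param tree a rooted `phylo` object.
#' @return named list of sorted character vectors.
#' @export
clade_set <- function(tree) {
  sets <- lapply(node_tipsets(tree), sort_labels)
  names(sets) <- vapply(sets, clade_key, character(1))
  sets
}
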