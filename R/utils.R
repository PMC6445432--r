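#' @keywords internal
"_PACKAGE"

#' Normalise a taxon label
#'
#' Strips surrounding single quotes (un-escaping doubled quotes), trims
#' whitespace and maps internal spaces to underscores, so that labels from
#' hand-edited Newick, MrBayes TRANSLATE tables and NEXUS matrices compare
#' equal. Comparisons everywhere in the package are exact after this
#' normalisation.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalised labels.
#' @export
#' @examples
#' normalise_label(c("'Xorides sp.'", "Pimpla aquilonia"))
normalise_label <- function(x) {
  x <- trimws(x)
  quoted <- startsWith(x, "'") & endsWith(x, "'") & nchar(x) >= 2L
  x[quoted] <- gsub("''", "'", substr(x[quoted], 2L, nchar(x[quoted]) - 1L), fixed = TRUE)
  gsub("[ \t]+", "_", trimws(x))
}

#' Canonical key for a clade
#'
#' A clade is identified by the sorted, semicolon-joined set of its (already
#' normalised) taxon labels. Keys are used as names of probability buckets and
#' in the exported TSV tables.
#'
#' @param labels character vector of taxon labels.
#' @return a single string.
#' @export
clade_key <- function(labels) {
  paste(sort_labels(unique(labels)), collapse = ";")
}

# byte-wise (C-locale) label sort: fast and locale-independent, so canonical
# keys are reproducible across platforms
sort_labels <- function(x) sort.int(x, method = "radix")

clade_labels_from_key <- function(key) {
  strsplit(key, ";", fixed = TRUE)[[1]]
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero, the convention used for printed percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# children[[node]] = integer vector of child node ids (empty for tips)
tree_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- rep(list(integer(0)), n)
  by_parent <- split(tree$edge[, 2L], tree$edge[, 1L])
  ch[as.integer(names(by_parent))] <- by_parent
  ch
}

# parent[node] = parent id, 0 for root
tree_parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# Edge rows in postorder (children before parents), computed with a plain
# stack so hot loops avoid per-call dispatch overhead. Optionally returns the
# matching edge lengths.
postorder_edges <- function(tree, with_lengths = FALSE) {
  ch <- tree_children(tree)
  nt <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  parents <- integer(n_edge)
  childs <- integer(n_edge)
  k <- 0L
  stack <- root_node(tree)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- ch[[v]]
    for (c0 in kids) {
      k <- k + 1L
      parents[k] <- v
      childs[k] <- c0
      if (c0 > nt) stack <- c(stack, c0)
    }
  }
  ed <- cbind(parents[k:1L], childs[k:1L])
  if (!with_lengths) return(ed)
  lens <- rep(NA_real_, nt + tree$Nnode)
  if (!is.null(tree$edge.length)) lens[tree$edge[, 2L]] <- tree$edge.length
  list(edge = ed, length = lens[ed[, 2L]])
}

# list per node (tips + internals) of the tip labels it subtends
node_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  res <- vector("list", n)
  res[seq_len(nt)] <- as.list(tree$tip.label)
  ed <- postorder_edges(tree)
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]
    res[[p]] <- c(res[[p]], res[[ed[i, 2L]]])
  }
  res
}

# depth of each node counting edges (or summing branch lengths if use_lengths)
node_depths <- function(tree, use_lengths = FALSE) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  depth <- numeric(n)
  po <- postorder_edges(tree, with_lengths = TRUE)
  ed <- po$edge
  lens <- if (use_lengths && !is.null(tree$edge.length)) po$length else rep(1, nrow(ed))
  lens[is.na(lens)] <- 1
  for (i in rev(seq_len(nrow(ed)))) {
    depth[ed[i, 2L]] <- depth[ed[i, 1L]] + lens[i]
  }
  depth
}

root_node <- function(tree) length(tree$tip.label) + 1L

# Tip labels below one node, without materialising every node's tip set.
tips_under <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  ch <- tree_children(tree)
  acc <- character(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= nt) acc <- c(acc, tree$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  acc
}

# Per-node clade keys computed over integer tip ids (much cheaper than
# sorting label vectors); `id_of` maps labels to stable integer ids. With
# `internal_only`, keys are returned just for non-root internal nodes (the
# clades that can vary between trees of a sample).
node_int_keys <- function(tree, id_of, internal_only = FALSE) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  sets <- vector("list", n)
  sets[seq_len(nt)] <- as.list(unname(id_of[tree$tip.label]))
  ed <- postorder_edges(tree)
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]
    sets[[p]] <- c(sets[[p]], sets[[ed[i, 2L]]])
  }
  which_nodes <- if (internal_only) setdiff((nt + 1L):n, nt + 1L) else seq_len(n)
  vapply(sets[which_nodes], function(v) paste(sort.int(v), collapse = ","), character(1))
}
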