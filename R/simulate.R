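# Synthetic fixtures with known ground truth: tree samples in which a rogue
# leaf attaches to edges of a fixed base tree according to a specified
# multinomial (with optional topological jitter elsewhere, so that the
# consensus of the non-rogue taxa contains polytomies), and matrices with
# exact-count fractions of missing/gap/polymorphic/questionable cells.
# Everything is deterministic given the seed.

#' Random rooted binary tree
#'
#' Builds a tree by uniform sequential pair-joining: starting from one node
#' per label, two subtrees are picked uniformly at random and joined, until a
#' single root remains. Deterministic for a given seed; the caller's RNG
#' state is left untouched.
#'
#' @param labels character vector of at least two leaf labels.
#' @param seed integer seed.
#' @return a rooted binary `phylo` without branch lengths.
#' @export
random_tree <- function(labels, seed) {
  labels <- normalise_label(labels)
  stopifnot(length(labels) >= 2L, !anyDuplicated(labels))
  local_seed(seed, {
    nodes <- lapply(labels, nested_leaf)
    while (length(nodes) > 1L) {
      pick <- sample.int(length(nodes), 2L)
      joined <- nested_internal(nodes[pick])
      nodes <- c(nodes[-pick], list(joined))
    }
    build_phylo(nodes[[1L]])
  })
}

# Attach a new leaf by subdividing the stem edge of the node whose clade key
# is `edge_key` (must not be the root clade).
attach_leaf_at <- function(tree, edge_key, label) {
  keys <- vapply(node_tipsets(tree), clade_key, character(1))
  node <- match(edge_key, keys)
  if (is.na(node)) stop(sprintf("no edge with child clade '%s'", edge_key), call. = FALSE)
  if (node == root_node(tree)) stop("cannot attach on the root clade", call. = FALSE)
  attach_leaf_phylo(tree, node, label)
}

# Subdivide the stem edge of `node` (id in `tree`'s numbering) with a new
# internal node carrying the new tip. Topology-only edge surgery; node ids of
# pre-existing internal nodes shift by +1 (tips keep their ids).
attach_leaf_phylo <- function(tree, node, label) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  ed <- tree$edge
  ed[ed > nt] <- ed[ed > nt] + 1L
  b <- if (node > nt) node + 1L else node
  newtip <- nt + 1L
  newint <- nt + 1L + nn + 1L
  row <- which(ed[, 2L] == b)
  ed[row, 2L] <- newint
  tree$edge <- rbind(ed, c(newint, b), c(newint, newtip))
  tree$edge.length <- NULL
  tree$tip.label <- c(tree$tip.label, label)
  if (!is.null(tree$node.label)) tree$node.label <- c(tree$node.label, "")
  tree$Nnode <- nn + 1L
  attr(tree, "order") <- NULL
  tree
}

# One nearest-neighbour-interchange move on edge (u, v) of a phylo: a random
# child of u other than v swaps places with a random child of v.
nni_swap <- function(tree, u, v, x, y) {
  ru <- which(tree$edge[, 1L] == u & tree$edge[, 2L] == x)
  rv <- which(tree$edge[, 1L] == v & tree$edge[, 2L] == y)
  tree$edge[ru, 1L] <- v
  tree$edge[rv, 1L] <- u
  attr(tree, "order") <- NULL
  tree
}

# Candidate NNI edges (u, v): both internal, both inside the jitter clade,
# with u neither the protected node nor one of its ancestors, so the clade
# subtending the protected attachment edge can never change.
nni_candidates <- function(tree, jitter_tips, protected_node) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  parent <- tree_parents(tree)
  anc <- integer(0)
  a <- protected_node
  while (!is.na(a) && a != 0L) {
    anc <- c(anc, a)
    a <- parent[a]
  }
  inside <- logical(n)
  inside[seq_len(nt)] <- tree$tip.label %in% jitter_tips
  inside[(nt + 1L):n] <- TRUE
  ed_po <- postorder_edges(tree)
  for (i in seq_len(nrow(ed_po))) {
    p <- ed_po[i, 1L]
    inside[p] <- inside[p] && inside[ed_po[i, 2L]]
  }
  ed <- tree$edge
  keep <- ed[, 1L] > nt & ed[, 2L] > nt & inside[ed[, 1L]] & inside[ed[, 2L]] &
    !(ed[, 1L] %in% anc) & !(ed[, 2L] %in% anc)
  ed[keep, , drop = FALSE]
}

#' Simulate a tree sample with a known rogue-attachment distribution
#'
#' For each of `n` trees an edge of `base_tree` is drawn from `weights` and
#' the rogue leaf attached there by subdividing it; with probability
#' `jitter_prob` the tree additionally receives `jitter_moves` random
#' nearest-neighbour interchanges restricted to `jitter_clade`, chosen so
#' that they can never disturb the clade subtending the drawn attachment
#' edge. The realised draws are logged, so the generator doubles as an exact
#' oracle: with no jitter, [rogue_distribution()] against the majority-rule
#' consensus of the pruned sample must reproduce the draw frequencies.
#'
#' @param base_tree rooted `phylo` over the non-rogue taxa (topology only;
#'   branch lengths are ignored).
#' @param rogue label of the rogue leaf to insert.
#' @param weights named probability vector; names are clade keys (see
#'   [clade_key()]) identifying edges of `base_tree` by the clade below them.
#'   Must sum to one.
#' @param n number of trees.
#' @param seed integer seed.
#' @param jitter_prob probability that a tree is jittered.
#' @param jitter_clade character vector of labels delimiting the subtree in
#'   which interchange moves are allowed; `NULL` = whole tree.
#' @param jitter_moves number of interchange moves per jittered tree. A
#'   single move leaves every base clade in place in at least half of the
#'   jittered trees, so several moves are needed before clades start
#'   dropping out of a majority-rule consensus.
#' @return a list with elements `sample` (a [tree_sample()] over
#'   `base_tree`'s taxa plus the rogue) and `draws` (character vector of the
#'   drawn edge keys, one per tree).
#' @export
simulate_rogue_sample <- function(base_tree, rogue, weights, n, seed,
                                  jitter_prob = 0, jitter_clade = NULL,
                                  jitter_moves = 1L) {
  rogue <- normalise_label(rogue)
  stopifnot(n >= 1L, jitter_prob >= 0, jitter_prob <= 1, jitter_moves >= 1L)
  if (rogue %in% base_tree$tip.label) {
    stop("the rogue label must not occur in the base tree", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  base <- base_tree
  base$edge.length <- NULL
  keys <- vapply(node_tipsets(base), clade_key, character(1))
  bad <- setdiff(names(weights), keys[-root_node(base)])
  if (length(bad) > 0L) {
    stop(sprintf("weight keys do not identify edges of the base tree: %s",
                 paste(bad, collapse = " | ")), call. = FALSE)
  }
  jitter_tips <- if (is.null(jitter_clade)) base$tip.label else normalise_label(jitter_clade)
  # node id of each weighted edge in the base tree; NNI moves are constrained
  # so these ids and their subtended clades stay valid in jittered trees
  node_of_key <- match(names(weights), keys)
  local_seed(seed, {
    draw_idx <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    draws <- names(weights)[draw_idx]
    jittered <- stats::runif(n) < jitter_prob
    plain <- vector("list", length(weights))  # cache: unjittered attachments
    trees <- vector("list", n)
    for (i in seq_len(n)) {
      k <- draw_idx[i]
      if (!jittered[i]) {
        if (is.null(plain[[k]])) {
          plain[[k]] <- attach_leaf_phylo(base, node_of_key[k], rogue)
        }
        trees[[i]] <- plain[[k]]
        next
      }
      tr <- base
      for (mv in seq_len(jitter_moves)) {
        cand <- nni_candidates(tr, jitter_tips, node_of_key[k])
        if (nrow(cand) == 0L) break
        row <- cand[sample.int(nrow(cand), 1L), ]
        u <- row[1L]
        v <- row[2L]
        ch <- tree_children(tr)
        xs <- setdiff(ch[[u]], v)
        x <- xs[sample.int(length(xs), 1L)]
        ys <- ch[[v]]
        y <- ys[sample.int(length(ys), 1L)]
        tr <- nni_swap(tr, u, v, x, y)
      }
      trees[[i]] <- attach_leaf_phylo(tr, node_of_key[k], rogue)
    }
    prov <- data.frame(file = "simulated", run = 1L, index = seq_len(n),
                       stringsAsFactors = FALSE)
    list(sample = tree_sample(trees, prov), draws = draws)
  })
}

#' Simulate a morphological matrix with exact cell-class fractions
#'
#' Cell classes are assigned by exact count (`floor(fraction * n_cells)` cells
#' per class, remainder single-state), then shuffled into random positions, so
#' that coverage statistics on the result are equality checks rather than
#' stochastic ones. Deterministic for a given seed.
#'
#' @param n_taxa,n_char matrix dimensions.
#' @param fractions named numeric vector with any of `missing`, `gap`,
#'   `polymorphic`, `uncertain`, `questionable`; non-negative, summing to at
#'   most 1.
#' @param n_states number of states for single-state cells (at least 2).
#' @param seed integer seed.
#' @return a `morph_matrix`.
#' @export
simulate_matrix <- function(n_taxa, n_char,
                            fractions = c(missing = 0, gap = 0, polymorphic = 0,
                                          questionable = 0),
                            n_states = 3, seed = 1) {
  stopifnot(n_taxa >= 1L, n_char >= 1L, n_states >= 2L)
  classes <- c("missing", "gap", "polymorphic", "uncertain", "questionable")
  fr <- stats::setNames(rep(0, length(classes)), classes)
  bad <- setdiff(names(fractions), classes)
  if (length(bad) > 0L) stop(sprintf("unknown cell classes: %s", paste(bad, collapse = ", ")),
                             call. = FALSE)
  fr[names(fractions)] <- fractions
  if (any(fr < 0) || sum(fr) > 1) stop("fractions must be >= 0 and sum to <= 1", call. = FALSE)
  n_cells <- n_taxa * n_char
  counts <- floor(fr * n_cells)
  symbols <- as.character(seq_len(n_states) - 1L)
  local_seed(seed, {
    tokens <- character(n_cells)
    pos <- sample.int(n_cells)
    at <- 1L
    take <- function(k) {
      out <- pos[seq.int(at, length.out = k)]
      at <<- at + k
      out
    }
    tokens[take(counts["missing"])] <- "?"
    tokens[take(counts["gap"])] <- "-"
    if (counts["polymorphic"] > 0L) {
      tokens[take(counts["polymorphic"])] <- vapply(seq_len(counts["polymorphic"]), function(i) {
        st <- sort(sample(symbols, 2L))
        paste0("(", paste(st, collapse = ""), ")")
      }, character(1))
    }
    if (counts["uncertain"] > 0L) {
      tokens[take(counts["uncertain"])] <- vapply(seq_len(counts["uncertain"]), function(i) {
        st <- sort(sample(symbols, 2L))
        paste0("{", paste(st, collapse = ""), "}")
      }, character(1))
    }
    if (counts["questionable"] > 0L) {
      tokens[take(counts["questionable"])] <- paste0(
        sample(symbols, counts["questionable"], replace = TRUE), "?")
    }
    rest <- pos[seq.int(at, length.out = n_cells - sum(counts))]
    tokens[rest] <- sample(symbols, length(rest), replace = TRUE)
    cells <- matrix(tokens, nrow = n_taxa, ncol = n_char)
    taxa <- sprintf("t%0*d", nchar(as.character(n_taxa)), seq_len(n_taxa))
    new_morph_matrix(taxa, cells, symbols)
  })
}
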