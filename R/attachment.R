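# Core computation: where does a rogue taxon attach, relative to a consensus
# of the non-rogue taxa? Each sampled tree contributes a count of 1 to exactly
# one bucket: "direct" if the rogue's sister set is a clade of the consensus
# (attachment to that very branch), otherwise "mrca" at the smallest consensus
# clade containing the sister set (attachment to a branch that is absent from
# the consensus). Counts are divided by the number of trees only at the end,
# so probabilities are exact integer multiples of 1/n_trees and always sum to
# one.

# Precomputed lookup structures for one consensus tree.
consensus_index <- function(consensus) {
  tipsets <- node_tipsets(consensus)
  keys <- vapply(tipsets, clade_key, character(1))
  idx <- new.env(parent = emptyenv(), size = length(keys))
  for (i in seq_along(keys)) assign(keys[i], i, envir = idx)
  list(
    tree = consensus,
    tipsets = tipsets,
    keys = keys,
    node_of = idx,
    parent = tree_parents(consensus),
    depth = node_depths(consensus),
    tip_id = stats::setNames(seq_along(consensus$tip.label), consensus$tip.label),
    taxa = sort_labels(consensus$tip.label)
  )
}

index_mrca <- function(idx, tips) {
  ids <- idx$tip_id[tips]
  node <- ids[1L]
  for (b in ids[-1L]) {
    a <- node
    while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
    while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
    while (a != b) {
      a <- idx$parent[a]
      b <- idx$parent[b]
    }
    node <- a
  }
  node
}

#' Sister set of a rogue leaf in one sampled tree
#'
#' Determines the set of non-rogue taxa subtended by the rogue's attachment
#' branch: any other rogue taxa are pruned first, then the sister subtree(s)
#' of the rogue leaf are read off. If the rogue's parent is the root with
#' exactly two children (the rogue is sister to everything else), the full
#' remaining leaf set is returned, representing attachment at the root.
#'
#' @param tree a rooted `phylo` containing `rogue`.
#' @param rogue the rogue leaf label.
#' @param co_rogues labels of the other rogue taxa, pruned before reading the
#'   attachment (may be empty).
#' @return sorted character vector: the clade whose stem branch the rogue
#'   attaches to.
#' @export
attachment_clade <- function(tree, rogue, co_rogues = character(0)) {
  rogue <- normalise_label(rogue)
  co_rogues <- setdiff(normalise_label(co_rogues), rogue)
  if (!(rogue %in% tree$tip.label)) {
    stop(sprintf("rogue '%s' is not a leaf of the tree", rogue), call. = FALSE)
  }
  if (length(tree$tip.label) - length(co_rogues) < 3L) {
    stop("fewer than 2 non-rogue leaves remain", call. = FALSE)
  }
  attachment_sister(tree, rogue, co_rogues)
}

# attachment_clade without re-normalisation/validation, for tight loops
attachment_sister <- function(tree, rogue, co_rogues) {
  for (lab in co_rogues) tree <- drop_one_tip(tree, lab)
  r <- match(rogue, tree$tip.label)
  p <- tree$edge[tree$edge[, 2L] == r, 1L]
  root <- root_node(tree)
  if (p == root && sum(tree$edge[, 1L] == root) == 2L) {
    return(sort_labels(setdiff(tree$tip.label, rogue)))
  }
  sort_labels(setdiff(tips_under(tree, p), rogue))
}

#' Map a sister set onto the consensus
#'
#' If `S` is a clade of the consensus the attachment is `direct` on the branch
#' subtending `S`; otherwise the attachment branch is absent from the
#' consensus and the probability mass belongs to the `mrca` bucket of the
#' smallest consensus clade containing `S`.
#'
#' @param S character vector of taxon labels (a rogue's sister set).
#' @param consensus a rooted `phylo` over the non-rogue taxa.
#' @param .index precomputed consensus lookup structure; used internally for
#'   repeated calls, leave `NULL`.
#' @return a list with elements `kind` (`"direct"` or `"mrca"`), `clade`
#'   (sorted labels of the target consensus clade) and `node` (its node id in
#'   the consensus).
#' @export
map_attachment <- function(S, consensus, .index = NULL) {
  idx <- if (is.null(.index)) consensus_index(consensus) else .index
  S <- sort_labels(normalise_label(S))
  if (length(S) == 0L) stop("empty attachment set", call. = FALSE)
  unknown <- setdiff(S, idx$tree$tip.label)
  if (length(unknown) > 0L) {
    stop(sprintf("attachment set contains unknown taxa: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  map_attachment_impl(S, idx)
}

# map_attachment for pre-normalised, pre-sorted S
map_attachment_impl <- function(S, idx) {
  key <- paste(S, collapse = ";")
  hit <- get0(key, envir = idx$node_of)
  if (!is.null(hit)) {
    return(list(kind = "direct", clade = S, node = hit))
  }
  node <- index_mrca(idx, S)
  list(kind = "mrca", clade = sort_labels(idx$tipsets[[node]]), node = node)
}

#' Attachment distribution of a rogue taxon over a consensus
#'
#' The central operation: for every sampled tree, the rogue's sister set is
#' read ([attachment_clade()]) and mapped onto the consensus
#' ([map_attachment()]); each tree contributes `1/n_trees` to exactly one
#' bucket. Direct buckets live on consensus branches, MRCA buckets on
#' consensus internal nodes; together they always sum to one.
#'
#' @param sample a [tree_sample()] whose trees contain all rogues.
#' @param rogue the rogue leaf label of interest.
#' @param all_rogues labels of all rogue taxa present in the sample
#'   (including `rogue`); the others are pruned tree by tree before the
#'   attachment is read.
#' @param consensus a rooted `phylo` whose leaf set equals the sample's taxa
#'   minus `all_rogues`.
#' @return an object of class `attachment_distribution` with elements `rogue`,
#'   `n_trees`, `direct` and `mrca` (named probability vectors keyed by
#'   canonical clade key), `direct_counts`, `mrca_counts` and `consensus`.
#' @export
rogue_distribution <- function(sample, rogue, all_rogues = rogue, consensus) {
  stopifnot(inherits(sample, "tree_sample"))
  rogue <- normalise_label(rogue)
  all_rogues <- unique(normalise_label(all_rogues))
  if (!(rogue %in% all_rogues)) stop("rogue must be among all_rogues", call. = FALSE)
  if (!all(all_rogues %in% sample$taxa)) {
    stop("all_rogues must be leaves of the sample", call. = FALSE)
  }
  idx <- consensus_index(consensus)
  expected <- sort_labels(setdiff(sample$taxa, all_rogues))
  if (!identical(idx$taxa, expected)) {
    stop("consensus leaf set must equal the sample leaf set minus the rogues", call. = FALSE)
  }
  co <- setdiff(all_rogues, rogue)
  n <- length(sample$trees)
  direct <- new.env(parent = emptyenv())
  mrca <- new.env(parent = emptyenv())
  bump <- function(envir, key) {
    assign(key, (get0(key, envir = envir) %||% 0L) + 1L, envir = envir)
  }
  for (tr in sample$trees) {
    S <- attachment_sister(tr, rogue, co)
    m <- map_attachment_impl(S, idx)
    bump(if (m$kind == "direct") direct else mrca, clade_key(m$clade))
  }
  env_counts <- function(envir) {
    keys <- sort(ls(envir))
    stats::setNames(vapply(keys, get, integer(1), envir = envir), keys)
  }
  dc <- env_counts(direct)
  mc <- env_counts(mrca)
  new_attachment_distribution(rogue, n, dc, mc, consensus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_attachment_distribution <- function(rogue, n, direct_counts, mrca_counts, consensus) {
  structure(list(
    rogue = rogue,
    n_trees = n,
    direct = direct_counts / n,
    mrca = mrca_counts / n,
    direct_counts = direct_counts,
    mrca_counts = mrca_counts,
    consensus = consensus
  ), class = "attachment_distribution")
}

#' @export
print.attachment_distribution <- function(x, max_rows = 10L, ...) {
  cat(sprintf("Attachment distribution for '%s' over %d trees\n", x$rogue, x$n_trees))
  cat(sprintf("  %d direct bucket(s), %d MRCA bucket(s), total probability %.9f\n",
              length(x$direct), length(x$mrca), sum(x$direct) + sum(x$mrca)))
  tab <- attachment_table(x)
  print(utils::head(tab, max_rows), row.names = FALSE)
  if (nrow(tab) > max_rows) cat(sprintf("  ... and %d more rows\n", nrow(tab) - max_rows))
  invisible(x)
}

# data-frame view of a distribution, sorted by descending probability then key
attachment_table <- function(dist) {
  df <- rbind(
    if (length(dist$direct) > 0L) {
      data.frame(rogue = dist$rogue, kind = "direct", clade = names(dist$direct),
                 count = as.integer(dist$direct_counts),
                 probability = as.numeric(dist$direct), stringsAsFactors = FALSE)
    },
    if (length(dist$mrca) > 0L) {
      data.frame(rogue = dist$rogue, kind = "mrca", clade = names(dist$mrca),
                 count = as.integer(dist$mrca_counts),
                 probability = as.numeric(dist$mrca), stringsAsFactors = FALSE)
    }
  )
  df <- df[order(-df$probability, df$clade), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Restrict a distribution to the well-supported part of the consensus
#'
#' Reproduces the "partial plot" view: only consensus branches whose
#' attachment probability exceeds `min_prob` (plus an explicit `keep` set,
#' e.g. the outgroup) are retained. In `"aggregate"` mode the probability of
#' every removed branch or node is re-assigned to the MRCA bucket of the
#' nearest retained ancestor, so the distribution still sums to one; in
#' `"truncate"` mode sub-threshold buckets are simply omitted (matching
#' figures that only display branches above the cutoff, at the price of a
#' total below one). `min_prob = 0` returns the input unchanged.
#'
#' @param dist an `attachment_distribution`.
#' @param consensus the consensus tree `dist` refers to.
#' @param min_prob probability threshold in `[0, 1)`.
#' @param keep labels always retained regardless of probability.
#' @param mode `"aggregate"` (default) or `"truncate"`.
#' @return list with elements `tree` (pruned consensus) and `distribution`.
#' @export
aggregate_partial <- function(dist, consensus, min_prob = 0.01, keep = character(0),
                              mode = c("aggregate", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dist, "attachment_distribution"))
  if (!(min_prob >= 0 && min_prob < 1)) stop("min_prob must be in [0, 1)", call. = FALSE)
  keep <- normalise_label(keep)
  taxa <- sort_labels(consensus$tip.label)
  unknown <- setdiff(keep, taxa)
  if (length(unknown) > 0L) {
    stop(sprintf("keep taxa not in consensus: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (min_prob == 0) {
    return(list(tree = consensus, distribution = dist))
  }
  idx <- consensus_index(consensus)
  buckets <- rbind(
    if (length(dist$direct_counts) > 0L) {
      data.frame(kind = "direct", key = names(dist$direct_counts),
                 count = as.integer(dist$direct_counts), stringsAsFactors = FALSE)
    },
    if (length(dist$mrca_counts) > 0L) {
      data.frame(kind = "mrca", key = names(dist$mrca_counts),
                 count = as.integer(dist$mrca_counts), stringsAsFactors = FALSE)
    }
  )
  buckets$prob <- buckets$count / dist$n_trees
  above <- buckets$prob > min_prob
  retained <- sort_labels(unique(c(keep, unlist(lapply(buckets$key[above], clade_labels_from_key)))))
  if (length(retained) < 2L) {
    stop("fewer than 2 leaves retained; lower min_prob or extend keep", call. = FALSE)
  }
  dropped <- setdiff(taxa, retained)
  pruned <- if (length(dropped) > 0L) prune_taxa(consensus, dropped) else consensus
  pidx <- consensus_index(pruned)
  direct <- new.env(parent = emptyenv())
  mrca <- new.env(parent = emptyenv())
  add <- function(envir, key, count) {
    assign(key, (get0(key, envir = envir) %||% 0L) + count, envir = envir)
  }
  for (i in seq_len(nrow(buckets))) {
    key <- buckets$key[i]
    count <- buckets$count[i]
    if (above[i]) {
      add(if (buckets$kind[i] == "direct") direct else mrca, key, count)
      next
    }
    if (mode == "truncate") next
    # walk up the original consensus until the clade intersects the retained set
    node <- get(key, envir = idx$node_of)
    R <- intersect(idx$tipsets[[node]], retained)
    while (length(R) == 0L) {
      node <- idx$parent[node]
      R <- intersect(idx$tipsets[[node]], retained)
    }
    target <- if (length(R) == 1L) pidx$parent[pidx$tip_id[R]] else index_mrca(pidx, R)
    add(mrca, clade_key(pidx$tipsets[[target]]), count)
  }
  env_counts <- function(envir) {
    keys <- sort(ls(envir))
    stats::setNames(vapply(keys, get, integer(1), envir = envir), keys)
  }
  list(
    tree = pruned,
    distribution = new_attachment_distribution(dist$rogue, dist$n_trees,
                                               env_counts(direct), env_counts(mrca), pruned)
  )
}
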