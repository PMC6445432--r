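# Rooted clade frequencies over a tree sample and the strict-majority-rule
# consensus. Clade semantics are rooted throughout: trees are expected to be
# rooted (e.g. via root_at_outgroup()) before summarisation.

#' Clade frequencies over a tree sample
#'
#' Counts, for every clade occurring in any tree of the sample, the number of
#' trees that contain it. Trivial clades (singletons and the full leaf set)
#' occur in every tree and are flagged as such.
#'
#' @param sample a [tree_sample()].
#' @return an object of class `split_frequencies`: a data frame with columns
#'   `clade` (canonical key), `size`, `count`, `frequency` and `trivial`,
#'   with attribute `n_trees`.
#' @export
split_frequencies <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  n <- length(sample$trees)
  ntaxa <- length(sample$taxa)
  # Count non-trivial clades over integer tip ids (within one tree every node
  # subtends a distinct clade, so no per-tree deduplication is needed); the
  # trivial clades -- singletons and the full leaf set -- occur in every tree
  # and are appended analytically. Keys are translated back to labels once.
  id_of <- stats::setNames(seq_along(sample$taxa), sample$taxa)
  ikeys <- unlist(lapply(sample$trees, function(tr) {
    node_int_keys(tr, id_of, internal_only = TRUE)
  }))
  if (is.null(ikeys)) ikeys <- character(0)
  tab <- table(ikeys)
  sets <- lapply(strsplit(names(tab), ",", fixed = TRUE),
                 function(ix) sample$taxa[as.integer(ix)])
  df <- data.frame(
    clade = c(vapply(sets, clade_key, character(1)), sample$taxa, clade_key(sample$taxa)),
    count = c(as.integer(tab), rep(n, ntaxa + 1L)),
    stringsAsFactors = FALSE
  )
  df$size <- c(lengths(sets), rep(1L, ntaxa), ntaxa)
  df$frequency <- df$count / n
  df$trivial <- df$size == 1L | df$size == ntaxa
  df <- df[order(-df$count, df$clade), c("clade", "size", "count", "frequency", "trivial")]
  rownames(df) <- NULL
  structure(df, n_trees = n, taxa = sample$taxa,
            class = c("split_frequencies", "data.frame"))
}

#' Majority-rule consensus tree
#'
#' Builds the consensus containing exactly the clades whose frequency in the
#' sample strictly exceeds `threshold` (plus the trivial clades). With the
#' default `threshold = 0.5` this is the strict-majority ("halfcompat")
#' consensus: clades at exactly 50% are excluded, which guarantees pairwise
#' compatibility without tie-breaking. Internal nodes carry the clade
#' frequency as `node.label`. With `allcompat = TRUE`, minority clades are
#' added in order of descending frequency when compatible with the tree built
#' so far (ties broken by clade key), yielding a fully resolved tree when
#' possible.
#'
#' @param sample a [tree_sample()].
#' @param threshold clade-frequency threshold in `[0.5, 1)`; clades with
#'   frequency strictly greater are retained.
#' @param allcompat also add compatible minority clades?
#' @return a (possibly multifurcating) `phylo` whose leaf set equals the
#'   sample's taxon set.
#' @export
majority_rule <- function(sample, threshold = 0.5, allcompat = FALSE) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!(threshold >= 0.5 && threshold < 1)) {
    stop("threshold must be in [0.5, 1)", call. = FALSE)
  }
  freqs <- split_frequencies(sample)
  taxa <- attr(freqs, "taxa")
  sel <- freqs[!freqs$trivial & freqs$frequency > threshold, , drop = FALSE]
  sets <- lapply(sel$clade, clade_labels_from_key)
  fr <- sel$frequency
  if (allcompat) {
    rest <- freqs[!freqs$trivial & freqs$frequency <= threshold, , drop = FALSE]
    rest <- rest[order(-rest$frequency, rest$clade), , drop = FALSE]
    compatible <- function(a, b) {
      i <- length(intersect(a, b))
      i == 0L || i == length(a) || i == length(b)
    }
    for (j in seq_len(nrow(rest))) {
      cand <- clade_labels_from_key(rest$clade[j])
      if (all(vapply(sets, compatible, logical(1), b = cand))) {
        sets[[length(sets) + 1L]] <- cand
        fr <- c(fr, rest$frequency[j])
      }
    }
  }
  build_consensus_tree(taxa, sets, fr)
}

# Assemble a rooted (possibly multifurcating) tree from a compatible set of
# non-trivial clades over `taxa`, with `freq` carried onto node labels.
build_consensus_tree <- function(taxa, sets, freq) {
  clades <- c(list(taxa), sets, as.list(taxa))
  labels <- c("1", as.character(freq), rep("", length(taxa)))
  sizes <- lengths(clades)
  ord <- order(-sizes)
  parent <- integer(length(clades))
  for (pos in seq_along(ord)[-1L]) {
    i <- ord[pos]
    best <- NA_integer_
    for (pos2 in seq_len(pos - 1L)) {
      j <- ord[pos2]
      if (sizes[j] > sizes[i] && all(clades[[i]] %in% clades[[j]])) {
        if (is.na(best) || sizes[j] < sizes[best]) best <- j
      }
    }
    parent[i] <- best
  }
  children <- split(seq_along(clades)[-1L], parent[-1L])
  rec <- function(i) {
    if (sizes[i] == 1L) return(nested_leaf(clades[[i]][1L]))
    kids <- children[[as.character(i)]]
    nested_internal(lapply(kids, rec), label = labels[i])
  }
  build_phylo(rec(1L))
}
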