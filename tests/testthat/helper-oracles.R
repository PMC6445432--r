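# Independent oracles built on ape's traversal utilities (prop.part /
# getMRCA / edge-matrix inspection) rather than on the package's own
# clade machinery, plus small fixture builders used across test files.

# All clades of a rooted tree as a list of sorted label vectors, via ape.
oracle_clades <- function(tree) {
  nt <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  internal <- lapply(pp, function(ix) sort(tree$tip.label[ix]))
  c(as.list(sort(tree$tip.label)), internal)
}

oracle_clade_keys <- function(tree) {
  vapply(oracle_clades(tree), paste, character(1), collapse = ";")
}

# Brute-force rogue attachment: read the rogue's sister set straight off the
# edge matrix, then test consensus membership by naive set comparison.
oracle_sister_set <- function(tree, rogue) {
  nt <- length(tree$tip.label)
  r <- match(rogue, tree$tip.label)
  p <- tree$edge[tree$edge[, 2] == r, 1]
  root <- nt + 1L
  if (p == root && sum(tree$edge[, 1] == root) == 2L) {
    return(sort(setdiff(tree$tip.label, rogue)))
  }
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  sort(setdiff(desc(p), rogue))
}

oracle_rogue_distribution <- function(trees, rogue, consensus) {
  ckeys <- oracle_clade_keys(consensus)
  direct <- list()
  mrca <- list()
  for (tr in trees) {
    S <- oracle_sister_set(tr, rogue)
    key <- paste(S, collapse = ";")
    if (key %in% ckeys) {
      direct[[key]] <- (direct[[key]] %||% 0L) + 1L
    } else {
      node <- ape::getMRCA(consensus, S)
      pp <- ape::prop.part(consensus)
      tips <- sort(consensus$tip.label[pp[[node - length(consensus$tip.label)]]])
      mkey <- paste(tips, collapse = ";")
      mrca[[mkey]] <- (mrca[[mkey]] %||% 0L) + 1L
    }
  }
  n <- length(trees)
  list(direct = unlist(direct) / n, mrca = unlist(mrca) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force strict-majority consensus clade set (dictionary counting).
oracle_majority_clades <- function(trees, threshold = 0.5) {
  keys <- unlist(lapply(trees, oracle_clade_keys))
  tab <- table(keys)
  names(tab)[tab / length(trees) > threshold]
}

# A fixed 5-extant-taxon scenario mirroring a three-topology toy in which a
# rogue attaches inside the crown of one genus in two topologies and to a
# conflicting branch in the third.
make_crown_stem_fixture <- function(n = 100, f = c(0.50, 0.43, 0.07)) {
  stopifnot(abs(sum(f) - 1) < 1e-12)
  counts <- diff(c(0, round(cumsum(f) * n)))
  stopifnot(sum(counts) == n)
  topo1 <- parse_newick("(A,(B,((X,C1),(C2,C3))));")  # X on C1's terminal branch
  topo2 <- parse_newick("(A,(B,(C1,(X,(C2,C3)))));")  # X on the (C2,C3) branch
  topo3 <- parse_newick("(A,(B,((X,(C1,C2)),C3)));")  # X on a conflicting branch
  trees <- c(replicate(counts[1], topo1, simplify = FALSE),
             replicate(counts[2], topo2, simplify = FALSE),
             replicate(counts[3], topo3, simplify = FALSE))
  tree_sample(trees)
}
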