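# Reading posterior tree samples (MrBayes ".t" NEXUS dialect or plain Newick),
# burn-in removal and deterministic even subsampling.

#' Construct a tree sample
#'
#' A tree sample is an ordered collection of trees over one identical leaf set
#' with per-tree provenance (source file, run id, tree index within the file).
#'
#' @param trees list of `phylo` objects sharing an identical leaf-label set.
#' @param provenance optional data frame with columns `file`, `run`, `index`
#'   and one row per tree.
#' @return an object of class `tree_sample` with elements `trees`, `taxa`
#'   (sorted leaf labels) and `provenance`.
#' @export
tree_sample <- function(trees, provenance = NULL) {
  if (length(trees) == 0L) stop("a tree sample must contain at least one tree", call. = FALSE)
  taxa <- sort_labels(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- sort_labels(trees[[i]]$tip.label)
    if (!identical(ti, taxa)) {
      stop(sprintf(
        "leaf-set mismatch: tree %d differs from tree 1 (%s)", i,
        paste(union(setdiff(ti, taxa), setdiff(taxa, ti)), collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (is.null(provenance)) {
    provenance <- data.frame(file = NA_character_, run = 1L, index = seq_along(trees),
                             stringsAsFactors = FALSE)
  }
  structure(list(trees = trees, taxa = taxa, provenance = provenance),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d trees over %d taxa (%d source file(s))\n",
              length(x$trees), length(x$taxa),
              length(unique(x$provenance$file))))
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)

# Read all trees from one file; auto-detects NEXUS (TREES block with optional
# TRANSLATE table) versus plain Newick (one statement per ';').
read_trees_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (grepl("^\\s*#nexus", txt, ignore.case = TRUE)) {
    read_nexus_trees_text(txt, path)
  } else {
    stmts <- strsplit(txt, ";", fixed = TRUE)[[1]]
    stmts <- stmts[nzchar(trimws(stmts))]
    lapply(stmts, function(st) {
      tr <- parse_newick(paste0(st, ";"))
      tr$tip.label <- normalise_label(tr$tip.label)
      tr
    })
  }
}

read_nexus_trees_text <- function(txt, path) {
  m <- regmatches(txt, regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", txt, perl = TRUE))
  if (length(m) == 0L) stop(sprintf("no TREES block found in '%s'", path), call. = FALSE)
  block <- sub("(?is)^begin\\s+trees\\s*;", "", m, perl = TRUE)
  block <- sub("(?is)\\bend\\s*;\\s*$", "", block, perl = TRUE)
  stmts <- strsplit(block, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  translate <- NULL
  trees <- list()
  for (st in stmts) {
    if (grepl("^translate\\b", st, ignore.case = TRUE)) {
      translate <- parse_translate(sub("(?i)^translate", "", st, perl = TRUE))
    } else if (grepl("^tree\\b", st, ignore.case = TRUE)) {
      eq <- regexpr("=", st, fixed = TRUE)
      if (eq < 0L) stop(sprintf("malformed tree statement in '%s'", path), call. = FALSE)
      nwk <- substr(st, eq + 1L, nchar(st))
      tr <- parse_newick(paste0(nwk, ";"))
      tr$tip.label <- normalise_label(tr$tip.label)
      if (!is.null(translate)) {
        hit <- match(tr$tip.label, names(translate))
        unresolved <- is.na(hit) & grepl("^[0-9]+$", tr$tip.label)
        if (any(unresolved)) {
          stop(sprintf("TRANSLATE table in '%s' has no entry for: %s", path,
                       paste(tr$tip.label[unresolved], collapse = ", ")), call. = FALSE)
        }
        tr$tip.label[!is.na(hit)] <- translate[hit[!is.na(hit)]]
      }
      trees[[length(trees) + 1L]] <- tr
    }
    # other statements (e.g. "begin taxa" remnants) are ignored
  }
  if (length(trees) == 0L) stop(sprintf("TREES block in '%s' contains no trees", path), call. = FALSE)
  trees
}

parse_translate <- function(body) {
  entries <- strsplit(body, ",", fixed = TRUE)[[1]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  keys <- character(length(entries))
  vals <- character(length(entries))
  for (i in seq_along(entries)) {
    mm <- regmatches(entries[i], regexec("^(\\S+)\\s+(.+)$", entries[i]))[[1]]
    if (length(mm) != 3L) stop(sprintf("malformed TRANSLATE entry: '%s'", entries[i]), call. = FALSE)
    keys[i] <- mm[2]
    vals[i] <- normalise_label(mm[3])
  }
  stats::setNames(vals, keys)
}

# Deterministic even-subsampling indices: k trees out of m with stride
# floor(m / k), starting at the first tree.
stride_indices <- function(m, k) {
  if (k > m) {
    stop(sprintf("requested %d trees per file but only %d available after burn-in", k, m),
         call. = FALSE)
  }
  s <- m %/% k
  1L + (seq_len(k) - 1L) * s
}

#' Read tree samples with burn-in removal and even subsampling
#'
#' Reads one or more tree files (MrBayes-style NEXUS `.t` files with an
#' optional TRANSLATE table, or plain Newick with one tree per statement).
#' Within each file the first `ceiling(burnin_fraction * n)` trees are
#' discarded as burn-in; the remainder is subsampled deterministically: with
#' `m` post-burn-in trees per file and `k = ceiling(n_sample / n_files)`
#' requested per file, the retained 1-based indices are `1, 1 + floor(m/k),
#' 1 + 2*floor(m/k), ...`. Files are concatenated in argument order and the
#' result trimmed to exactly `n_sample` trees by dropping from the last file.
#'
#' @param paths character vector of file paths (one per MCMC run).
#' @param burnin_fraction fraction in `[0, 1)` of each file discarded from the
#'   start.
#' @param n_sample total number of trees to retain across files, or `"all"`.
#' @return a [tree_sample()].
#' @export
parse_nexus_trees <- function(paths, burnin_fraction = 0, n_sample = "all") {
  stopifnot(length(paths) >= 1L)
  if (!(is.numeric(burnin_fraction) && burnin_fraction >= 0 && burnin_fraction < 1)) {
    stop("burnin_fraction must be in [0, 1)", call. = FALSE)
  }
  all_mode <- identical(n_sample, "all")
  if (!all_mode) {
    n_sample <- as.integer(n_sample)
    if (is.na(n_sample) || n_sample < 1L) stop("n_sample must be >= 1 or \"all\"", call. = FALSE)
  }
  nf <- length(paths)
  per_file <- lapply(paths, read_trees_file)
  kept <- list()
  prov <- list()
  for (f in seq_len(nf)) {
    trs <- per_file[[f]]
    nb <- ceiling(burnin_fraction * length(trs))
    post <- seq_along(trs)[seq_along(trs) > nb]
    m <- length(post)
    if (m == 0L) stop(sprintf("no trees left after burn-in in '%s'", paths[f]), call. = FALSE)
    idx <- if (all_mode) seq_len(m) else stride_indices(m, as.integer(ceiling(n_sample / nf)))
    sel <- post[idx]
    kept[[f]] <- trs[sel]
    prov[[f]] <- data.frame(file = paths[f], run = f, index = sel, stringsAsFactors = FALSE)
  }
  trees <- do.call(c, kept)
  provenance <- do.call(rbind, prov)
  if (!all_mode) {
    if (length(trees) < n_sample) {
      stop(sprintf("only %d trees available, %d requested", length(trees), n_sample), call. = FALSE)
    }
    trees <- trees[seq_len(n_sample)]
    provenance <- provenance[seq_len(n_sample), , drop = FALSE]
  }
  tree_sample(trees, provenance)
}
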