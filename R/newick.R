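# Newick I/O.
#
# The parser is a character-level recursive-descent parser so that malformed
# input can be reported with an exact position, and so that quoted labels and
# square-bracket comments (MrBayes "[&U]", figtree annotations) are handled
# the same way on every platform. Trees are returned as ape "phylo" objects.

# ---- nested-node representation used by the parser and the tree editors ----

nested_leaf <- function(label, length = NA_real_) {
  list(label = label, length = length, children = NULL)
}

nested_internal <- function(children, label = "", length = NA_real_) {
  list(label = label, length = length, children = children)
}

# Convert an ape phylo into the nested representation (lengths and internal
# support labels carried along).
to_nested <- function(tree) {
  nt <- length(tree$tip.label)
  ch <- tree_children(tree)
  len_of <- rep(NA_real_, nt + tree$Nnode)
  if (!is.null(tree$edge.length)) len_of[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(id) {
    if (id <= nt) {
      return(nested_leaf(tree$tip.label[id], len_of[id]))
    }
    lab <- if (!is.null(tree$node.label)) tree$node.label[id - nt] else ""
    if (is.na(lab)) lab <- ""
    nested_internal(lapply(ch[[id]], rec), lab, len_of[id])
  }
  rec(root_node(tree))
}

# Build an ape phylo from a nested node. Tips are numbered in traversal
# order, internal nodes in preorder with the root first.
build_phylo <- function(root) {
  count_tips <- function(nd) {
    if (is.null(nd$children)) 1L else sum(vapply(nd$children, count_tips, integer(1)))
  }
  nt <- count_tips(root)
  env <- new.env(parent = emptyenv())
  env$tip_i <- 0L
  env$node_i <- nt
  env$edges <- list()
  env$tips <- character(nt)
  env$node_labs <- character(0)
  env$lens <- list()
  walk <- function(nd) {
    if (is.null(nd$children)) {
      env$tip_i <- env$tip_i + 1L
      id <- env$tip_i
      env$tips[id] <- nd$label
      return(id)
    }
    env$node_i <- env$node_i + 1L
    id <- env$node_i
    env$node_labs[id - nt] <- if (is.null(nd$label)) "" else nd$label
    for (child in nd$children) {
      cid <- walk(child)
      env$edges[[length(env$edges) + 1L]] <- c(id, cid)
      env$lens[[length(env$lens) + 1L]] <- if (is.null(child$length)) NA_real_ else child$length
    }
    id
  }
  walk(root)
  edge <- do.call(rbind, env$edges)
  lens <- unlist(env$lens)
  tree <- list(
    edge = edge,
    tip.label = env$tips,
    Nnode = env$node_i - nt
  )
  if (any(!is.na(lens))) tree$edge.length <- lens
  if (any(nzchar(env$node_labs))) tree$node.label <- env$node_labs
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree
}

# ---- parser -----------------------------------------------------------------

#' Parse a Newick tree
#'
#' Parses a single Newick statement (terminated by `;`) into an ape
#' [`phylo`][ape::read.tree] object. Branch lengths become `edge.length`,
#' internal-node labels (typically support values) become `node.label`,
#' square-bracket comments are tolerated and ignored, and leaf labels are
#' passed through [normalise_label()]. Malformed input raises an error naming
#' the offending character position.
#'
#' @param text a single character string containing one Newick statement.
#' @return an object of class `phylo`.
#' @seealso [write_newick()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1.0,B:2.0)0.9:3.0,C:4.0);")
#' write_newick(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(s)
  pos <- 1L
  perr <- function(msg, at = pos) {
    stop(sprintf("newick parse error at position %d: %s", at, msg), call. = FALSE)
  }
  skip <- function() {
    repeat {
      while (pos <= n && s[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
      if (pos <= n && s[pos] == "[") {
        start <- pos
        while (pos <= n && s[pos] != "]") pos <<- pos + 1L
        if (pos > n) perr("unterminated '[' comment", start)
        pos <<- pos + 1L
      } else {
        break
      }
    }
  }
  bare_end <- c("(", ")", ",", ":", ";", "[", "'", " ", "\t", "\n", "\r")
  read_label <- function() {
    skip()
    if (pos <= n && s[pos] == "'") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > n) perr("unterminated quoted label", start)
        if (s[pos] == "'") {
          if (pos + 1L <= n && s[pos + 1L] == "'") {
            out <- c(out, "'")
            pos <<- pos + 2L
          } else {
            pos <<- pos + 1L
            break
          }
        } else {
          out <- c(out, s[pos])
          pos <<- pos + 1L
        }
      }
      normalise_label(paste0("'", paste(out, collapse = ""), "'"))
    } else {
      out <- character(0)
      while (pos <= n && !(s[pos] %in% bare_end)) {
        out <- c(out, s[pos])
        pos <<- pos + 1L
      }
      normalise_label(paste(out, collapse = ""))
    }
  }
  read_length <- function() {
    skip()
    if (pos > n || s[pos] != ":") return(NA_real_)
    pos <<- pos + 1L
    skip()
    start <- pos
    out <- character(0)
    while (pos <= n && grepl("[0-9eE+.-]", s[pos])) {
      out <- c(out, s[pos])
      pos <<- pos + 1L
    }
    val <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (length(out) == 0L || is.na(val)) perr("invalid branch length", start)
    val
  }
  parse_node <- function() {
    skip()
    if (pos > n) perr("unexpected end of input")
    if (s[pos] == "(") {
      open_at <- pos
      pos <<- pos + 1L
      children <- list()
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        skip()
        if (pos > n) perr("unbalanced parentheses: '(' not closed", open_at)
        if (s[pos] == ",") {
          pos <<- pos + 1L
        } else if (s[pos] == ")") {
          pos <<- pos + 1L
          break
        } else {
          perr(sprintf("expected ',' or ')' but found '%s'", s[pos]))
        }
      }
      lab <- read_label()
      skip()
      nested_internal(children, lab, read_length())
    } else {
      at <- pos
      lab <- read_label()
      if (!nzchar(lab)) perr("empty leaf label", at)
      skip()
      nested_leaf(lab, read_length())
    }
  }
  root <- parse_node()
  skip()
  if (pos > n || s[pos] != ";") perr("expected ';' terminating the tree")
  pos <- pos + 1L
  skip()
  if (pos <= n) perr("trailing characters after ';'")
  if (is.null(root$children) || length(root$children) < 2L) {
    perr("root must have at least two children", 1L)
  }
  tree <- build_phylo(root)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    perr(sprintf("duplicate leaf label(s): %s", paste(unique(dup), collapse = ", ")), 1L)
  }
  tree
}

# ---- writer -----------------------------------------------------------------

fmt_brlen <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 12)
}

needs_quoting <- function(lab) grepl("[^A-Za-z0-9_.|/-]", lab)

quote_label <- function(lab) {
  ifelse(needs_quoting(lab),
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'"),
    lab
  )
}

#' Write a tree as a canonical Newick string
#'
#' Output is deterministic: at every internal node the children are ordered by
#' the lexicographically smallest leaf label of their subtree, so two
#' topologically identical trees always serialise to the same string. Branch
#' lengths are emitted when present, internal-node labels (supports) after the
#' closing parenthesis, and, if `include_annotations` is set and the tree
#' carries a `node.comment` vector (see [annotate_attachments()]),
#' square-bracket comments after each label.
#'
#' @param tree a `phylo` object.
#' @param include_annotations emit per-node `[&...]` comments from
#'   `tree$node.comment`?
#' @return a single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, include_annotations = FALSE) {
  nt <- length(tree$tip.label)
  ch <- tree_children(tree)
  tipsets <- node_tipsets(tree)
  minlab <- vapply(tipsets, min, character(1))
  len_of <- rep(NA_real_, nt + tree$Nnode)
  if (!is.null(tree$edge.length)) len_of[tree$edge[, 2L]] <- tree$edge.length
  comments <- attr_node_comments(tree)
  rec <- function(id) {
    if (id <= nt) {
      str <- quote_label(tree$tip.label[id])
    } else {
      kids <- ch[[id]][order(minlab[ch[[id]]])]
      lab <- if (!is.null(tree$node.label)) tree$node.label[id - nt] else ""
      if (is.na(lab)) lab <- ""
      str <- paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
                    quote_label_if_any(lab))
    }
    if (include_annotations && !is.null(comments) && nzchar(comments[id])) {
      str <- paste0(str, comments[id])
    }
    if (!is.na(len_of[id])) str <- paste0(str, ":", fmt_brlen(len_of[id]))
    str
  }
  paste0(rec(root_node(tree)), ";")
}

quote_label_if_any <- function(lab) {
  if (!nzchar(lab)) "" else quote_label(lab)
}

attr_node_comments <- function(tree) {
  cm <- tree$node.comment
  if (is.null(cm)) return(NULL)
  n <- length(tree$tip.label) + tree$Nnode
  if (length(cm) != n) stop("node.comment must have one entry per node", call. = FALSE)
  cm
}
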