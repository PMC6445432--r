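# Matrix preparation for Bayesian analysis under the Mk family of models:
# recoding of doubtful scores, gap weighting of continuous characters into
# ordered discrete states, expansion of the state space to match a larger
# reference matrix, and emission of the corresponding MrBayes command block.

#' Recode questionable cells
#'
#' Cells scored as "state observed with doubt" (e.g. `1?`) are resolved either
#' liberally (the doubt is dropped and the observed states kept) or
#' conservatively (the cell becomes missing). All other cells are unchanged.
#'
#' @param mat a `morph_matrix`.
#' @param mode `"liberal"` or `"conservative"`.
#' @return the recoded `morph_matrix`.
#' @export
recode_uncertain <- function(mat, mode = c("liberal", "conservative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "morph_matrix"))
  ty <- cell_type(mat$cells, mat$missing, mat$gap)
  q <- which(ty == "questionable")
  if (length(q) == 0L) return(mat)
  if (mode == "conservative") {
    mat$cells[q] <- mat$missing
  } else {
    mat$cells[q] <- vapply(mat$cells[q], function(tok) {
      st <- sort(cell_states(tok, mat$missing, mat$gap))
      if (length(st) == 1L) st else paste0("{", paste(st, collapse = ""), "}")
    }, character(1))
  }
  mat
}

#' Gap weighting of a continuous character
#'
#' Discretises a continuous character into at most `n_states` ordered states
#' by range scaling: a value `x` maps to
#' `round((x - min) / (max - min) * (n_states - 1))` with ties rounded half
#' up. Missing values stay missing; a zero range maps everything to state 0.
#' The result is an ordered character of source type
#' `"discretised-continuous"`. The mapping is monotone and invariant under
#' affine transformations of the input.
#'
#' @param values named numeric vector (taxon -> measurement), `NA` = missing.
#' @param n_states number of ordered states (at least 2; 6 matches the upper
#'   limit for ordered characters in common Bayesian phylogenetics software).
#' @return named integer vector of states in `0 .. n_states - 1` with `NA`
#'   for missing values, carrying attributes `ordered = TRUE` and
#'   `source = "discretised-continuous"`.
#' @export
gap_weight <- function(values, n_states = 6) {
  stopifnot(is.numeric(values), n_states >= 2)
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop("all values are missing", call. = FALSE)
  rng <- range(obs)
  states <- rep(NA_integer_, length(values))
  if (rng[1] == rng[2]) {
    states[!is.na(values)] <- 0L
  } else {
    x <- (values - rng[1]) / (rng[2] - rng[1]) * (n_states - 1)
    states[!is.na(values)] <- as.integer(floor(x[!is.na(values)] + 0.5))
  }
  names(states) <- names(values)
  attr(states, "ordered") <- TRUE
  attr(states, "source") <- "discretised-continuous"
  attr(states, "n_states") <- as.integer(n_states)
  states
}

#' Expand the state space of characters to a reference maximum
#'
#' When an analysis should account for states that exist in a larger
#' reference matrix but are unobserved among the sampled taxa, the largest
#' observed state label of a character is relabelled to the reference maximum
#' (including inside polymorphic/uncertain sets), so that the declared state
#' space reflects the estimated true one. Characters whose observed maximum
#' already equals the target are unchanged. For ordered characters this
#' deliberately inserts unobserved intermediate states.
#'
#' @param mat a `morph_matrix` with numeric (digit) state symbols.
#' @param target_max named vector (names = 1-based character indices) of
#'   target maximum state labels.
#' @return list with elements `matrix` (the recoded `morph_matrix`) and
#'   `changed` (data frame of characters whose state space changed).
#' @export
expand_state_space <- function(mat, target_max) {
  stopifnot(inherits(mat, "morph_matrix"))
  ids <- as.integer(names(target_max))
  if (anyNA(ids) || any(ids < 1L | ids > ncol(mat$cells))) {
    stop("target_max must be named by valid 1-based character indices", call. = FALSE)
  }
  changed <- list()
  for (k in seq_along(ids)) {
    j <- ids[k]
    M <- as.integer(target_max[k])
    col <- mat$cells[, j]
    obs <- unlist(lapply(col, cell_states, missing = mat$missing, gap = mat$gap))
    obs_num <- suppressWarnings(as.integer(obs))
    if (anyNA(obs_num)) {
      stop(sprintf("character %d has non-numeric state symbols; cannot expand", j), call. = FALSE)
    }
    if (length(obs_num) == 0L) next
    m <- max(obs_num)
    if (M < m) {
      stop(sprintf("character %d: target maximum %d below observed maximum %d", j, M, m),
           call. = FALSE)
    }
    if (M == m) next
    mat$cells[, j] <- gsub(as.character(m), as.character(M), col, fixed = TRUE)
    changed[[length(changed) + 1L]] <- data.frame(index = j, observed_max = m,
                                                  target_max = M)
  }
  new_syms <- as.character(0:max(c(suppressWarnings(as.integer(mat$symbols)),
                                   as.integer(target_max)), na.rm = TRUE))
  mat$symbols <- new_syms
  list(
    matrix = mat,
    changed = if (length(changed) > 0L) do.call(rbind, changed) else
      data.frame(index = integer(0), observed_max = integer(0), target_max = integer(0))
  )
}

#' Emit a MrBayes command block
#'
#' Produces the plain-text command block declaring ordered characters, the
#' coding bias for standard data (matrices scored only for variable
#' characters use `coding=variable`), gamma-distributed among-character rate
#' variation, and the MCMC run settings. The text is meant to be appended to
#' a NEXUS data file and executed by external software; nothing is run here.
#'
#' @param mat a `morph_matrix` (used only for context; may be `NULL`).
#' @param ordered_character_ids integer vector of 1-based indices of ordered
#'   characters (possibly empty).
#' @param settings named list overriding any of `ngen`, `nruns`, `nchains`,
#'   `samplefreq`, `coding`, `rates`.
#' @return a single string of command-block text.
#' @export
mrbayes_commands <- function(mat = NULL, ordered_character_ids = integer(0),
                             settings = list()) {
  defaults <- list(ngen = 50000000, nruns = 4, nchains = 4, samplefreq = 5000,
                   coding = "variable", rates = "gamma")
  s <- utils::modifyList(defaults, settings)
  if (!is.null(mat)) {
    bad <- setdiff(ordered_character_ids, seq_len(ncol(mat$cells)))
    if (length(bad) > 0L) {
      stop(sprintf("ordered character ids out of range: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  lines <- c("begin mrbayes;")
  if (length(ordered_character_ids) > 0L) {
    lines <- c(lines, sprintf("  ctype ordered: %s;",
                              paste(sort(unique(ordered_character_ids)), collapse = " ")))
  }
  lines <- c(lines,
    sprintf("  lset coding=%s rates=%s;", s$coding, s$rates),
    sprintf("  mcmcp ngen=%d nruns=%d nchains=%d samplefreq=%d;",
            as.integer(s$ngen), as.integer(s$nruns), as.integer(s$nchains),
            as.integer(s$samplefreq)),
    "end;")
  paste0(paste(lines, collapse = "\n"), "\n")
}
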