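# NEXUS standard-datatype morphological matrices. Cells are kept as compact
# string tokens: "?" (missing), "-" (inapplicable/gap), a single symbol,
# "(ab)" (polymorphism), "{ab}" (uncertainty), and "a?" for the pre-NEXUS
# "state observed with doubt" convention, which standard NEXUS cannot encode
# natively and which therefore travels through files via a sidecar table
# (see questionable_sidecar()).

#' Classify a matrix cell token
#'
#' @param tok character vector of cell tokens.
#' @param missing,gap the declared missing and gap symbols.
#' @return character vector: `"missing"`, `"gap"`, `"single"`,
#'   `"polymorphic"`, `"uncertain"` or `"questionable"`.
#' @export
cell_type <- function(tok, missing = "?", gap = "-") {
  out <- rep("single", length(tok))
  out[tok == missing] <- "missing"
  out[tok == gap] <- "gap"
  out[startsWith(tok, "(")] <- "polymorphic"
  out[startsWith(tok, "{")] <- "uncertain"
  out[nchar(tok) > 1L & endsWith(tok, "?") & !startsWith(tok, "(") & !startsWith(tok, "{")] <-
    "questionable"
  dim(out) <- dim(tok)
  out
}

#' State labels of a matrix cell token
#'
#' @param tok a single cell token.
#' @inheritParams cell_type
#' @return character vector of state symbols (empty for missing/gap cells).
#' @export
cell_states <- function(tok, missing = "?", gap = "-") {
  if (tok == missing || tok == gap) return(character(0))
  body <- gsub("[(){}?]", "", tok)
  strsplit(body, "", fixed = TRUE)[[1]]
}

new_morph_matrix <- function(taxa, cells, symbols, missing = "?", gap = "-",
                             char_labels = NULL, ordered = NULL, source = NULL) {
  nchar_ <- ncol(cells)
  if (is.null(char_labels)) char_labels <- sprintf("char%d", seq_len(nchar_))
  if (is.null(ordered)) ordered <- rep(FALSE, nchar_)
  if (is.null(source)) source <- rep("discrete", nchar_)
  rownames(cells) <- taxa
  structure(list(
    taxa = taxa,
    cells = cells,
    symbols = symbols,
    missing = missing,
    gap = gap,
    characters = data.frame(index = seq_len(nchar_), label = char_labels,
                            ordered = ordered, source = source,
                            stringsAsFactors = FALSE)
  ), class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  tys <- cell_type(x$cells, x$missing, x$gap)
  cat(sprintf("Morphological matrix: %d taxa x %d characters\n",
              length(x$taxa), ncol(x$cells)))
  cat(sprintf("  symbols {%s}; cells: %s\n", paste(x$symbols, collapse = ""),
              paste(sprintf("%s=%d", names(table(tys)), as.integer(table(tys))),
                    collapse = ", ")))
  invisible(x)
}

#' Parse a NEXUS standard-datatype character matrix
#'
#' Reads a DATA or CHARACTERS block with `DATATYPE=STANDARD`, declared
#' `MISSING` and `GAP` symbols and an optional `SYMBOLS` list, interleaved or
#' not. Polymorphisms `(ab)` and uncertainties `{ab}` are preserved as
#' distinct cell modes. Taxon labels are normalised, square-bracket comments
#' stripped. Errors report the offending taxon and character coordinates.
#'
#' @param path path to a NEXUS file.
#' @return a `morph_matrix` object.
#' @export
parse_nexus_matrix <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#nexus", txt, ignore.case = TRUE)) {
    stop(sprintf("'%s' is not a NEXUS file (missing #NEXUS header)", path), call. = FALSE)
  }
  txt <- gsub("\\[[^]]*\\]", "", txt)
  m <- regmatches(txt, regexpr("(?is)begin\\s+(data|characters)\\s*;.*?\\bend\\s*;", txt, perl = TRUE))
  if (length(m) == 0L) stop(sprintf("no DATA/CHARACTERS block in '%s'", path), call. = FALSE)
  block <- sub("(?is)^begin\\s+(data|characters)\\s*;", "", m, perl = TRUE)
  stmts <- strsplit(block, ";", fixed = TRUE)[[1]]
  ntax <- nchar_ <- NA_integer_
  symbols <- as.character(0:9)
  missing_sym <- "?"
  gap_sym <- "-"
  char_labels <- NULL
  matrix_text <- NULL
  for (st in stmts) {
    st_tr <- trimws(st)
    low <- tolower(st_tr)
    if (startsWith(low, "dimensions")) {
      ntax <- extract_num_option(st_tr, "ntax")
      nchar_ <- extract_num_option(st_tr, "nchar")
    } else if (startsWith(low, "format")) {
      dt <- extract_str_option(st_tr, "datatype")
      if (!is.null(dt) && tolower(dt) != "standard") {
        stop(sprintf("unsupported DATATYPE '%s' (only STANDARD)", dt), call. = FALSE)
      }
      sy <- extract_quoted_option(st_tr, "symbols")
      if (!is.null(sy)) symbols <- strsplit(gsub("[ \t\n]", "", sy), "", fixed = TRUE)[[1]]
      ms <- extract_str_option(st_tr, "missing")
      if (!is.null(ms)) missing_sym <- ms
      gp <- extract_str_option(st_tr, "gap")
      if (!is.null(gp)) gap_sym <- gp
    } else if (startsWith(low, "charstatelabels")) {
      char_labels <- parse_charstatelabels(sub("(?i)^charstatelabels", "", st_tr, perl = TRUE))
    } else if (startsWith(low, "matrix")) {
      matrix_text <- sub("(?i)^matrix", "", st_tr, perl = TRUE)
    }
  }
  if (is.na(ntax) || is.na(nchar_)) stop("DIMENSIONS with NTAX and NCHAR required", call. = FALSE)
  if (is.null(matrix_text)) stop("MATRIX command not found", call. = FALSE)
  rows <- parse_matrix_rows(matrix_text, symbols, missing_sym, gap_sym, nchar_)
  taxa <- names(rows)
  if (length(taxa) != ntax) {
    stop(sprintf("matrix has %d taxa but NTAX=%d", length(taxa), ntax), call. = FALSE)
  }
  bad <- which(lengths(rows) != nchar_)
  if (length(bad) > 0L) {
    stop(sprintf("taxon '%s' has %d characters, expected NCHAR=%d",
                 taxa[bad[1]], lengths(rows)[bad[1]], nchar_), call. = FALSE)
  }
  cells <- matrix(unlist(rows), nrow = ntax, ncol = nchar_, byrow = TRUE)
  labs <- if (!is.null(char_labels)) {
    out <- sprintf("char%d", seq_len(nchar_))
    out[as.integer(names(char_labels))] <- unname(char_labels)
    out
  } else NULL
  new_morph_matrix(taxa, cells, symbols, missing_sym, gap_sym, char_labels = labs)
}

extract_num_option <- function(st, name) {
  m <- regmatches(st, regexec(sprintf("(?i)\\b%s\\s*=\\s*(\\d+)", name), st, perl = TRUE))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

extract_str_option <- function(st, name) {
  m <- regmatches(st, regexec(sprintf("(?i)\\b%s\\s*=\\s*(\\S+)", name), st, perl = TRUE))[[1]]
  if (length(m) == 2L) gsub('"', "", m[2]) else NULL
}

extract_quoted_option <- function(st, name) {
  m <- regmatches(st, regexec(sprintf('(?i)\\b%s\\s*=\\s*"([^"]*)"', name), st, perl = TRUE))[[1]]
  if (length(m) == 2L) m[2] else extract_str_option(st, name)
}

parse_charstatelabels <- function(body) {
  entries <- strsplit(body, ",", fixed = TRUE)[[1]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  out <- character(0)
  for (e in entries) {
    m <- regmatches(e, regexec("^(\\d+)\\s+('[^']*'|\\S+)", e))[[1]]
    if (length(m) == 3L) out[m[2]] <- normalise_label(m[3])
  }
  out
}

# Parse MATRIX rows into a named list of token vectors; lines whose taxon
# repeats (interleaved format) are appended to that taxon's row.
parse_matrix_rows <- function(matrix_text, symbols, missing_sym, gap_sym, nchar_) {
  valid <- c(symbols, missing_sym, gap_sym)
  rows <- list()
  for (line in strsplit(matrix_text, "\n", fixed = TRUE)[[1]]) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "'")) {
      m <- regmatches(line, regexec("^'([^']*)'\\s*(.*)$", line))[[1]]
      if (length(m) != 3L) stop(sprintf("malformed matrix row: %s", line), call. = FALSE)
      taxon <- normalise_label(m[2])
      seq_text <- m[3]
    } else {
      m <- regmatches(line, regexec("^(\\S+)\\s+(.*)$", line))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("malformed matrix row (no whitespace after taxon name): %s", line),
             call. = FALSE)
      }
      taxon <- normalise_label(m[2])
      seq_text <- m[3]
    }
    toks <- tokenize_cells(seq_text, valid, taxon,
                           offset = length(rows[[taxon]] %||% character(0)))
    rows[[taxon]] <- c(rows[[taxon]], toks)
  }
  rows
}

tokenize_cells <- function(seq_text, valid, taxon, offset = 0L) {
  s <- strsplit(seq_text, "", fixed = TRUE)[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(s)) {
    c0 <- s[i]
    if (c0 %in% c(" ", "\t")) {
      i <- i + 1L
    } else if (c0 %in% c("(", "{")) {
      close <- if (c0 == "(") ")" else "}"
      j <- i + 1L
      states <- character(0)
      while (j <= length(s) && s[j] != close) {
        if (!(s[j] %in% c(" ", "\t", ","))) states <- c(states, s[j])
        j <- j + 1L
      }
      if (j > length(s)) {
        stop(sprintf("taxon '%s', character %d: unclosed '%s'", taxon,
                     offset + length(toks) + 1L, c0), call. = FALSE)
      }
      bad <- setdiff(states, valid)
      if (length(bad) > 0L || length(states) == 0L) {
        stop(sprintf("taxon '%s', character %d: invalid state set '%s'", taxon,
                     offset + length(toks) + 1L, paste(states, collapse = "")), call. = FALSE)
      }
      states <- sort(states)
      toks <- c(toks, paste0(c0, paste(states, collapse = ""), close))
      i <- j + 1L
    } else {
      if (!(c0 %in% valid)) {
        stop(sprintf("taxon '%s', character %d: undeclared symbol '%s'", taxon,
                     offset + length(toks) + 1L, c0), call. = FALSE)
      }
      toks <- c(toks, c0)
      i <- i + 1L
    }
  }
  toks
}

#' Write a morphological matrix as NEXUS
#'
#' Emits a standard-datatype DATA block (non-interleaved). Questionable cells
#' ("state observed with doubt"), which standard NEXUS cannot express, are
#' written as uncertainty sets `{...}`; their coordinates can be exported
#' separately with [questionable_sidecar()] and re-applied after parsing with
#' [apply_questionable()]. With `include_mrbayes_block = TRUE`, a MrBayes
#' command block (see [mrbayes_commands()]) is appended.
#'
#' @param mat a `morph_matrix`.
#' @param include_mrbayes_block append an analysis command block?
#' @param settings settings passed to [mrbayes_commands()].
#' @return a single string of NEXUS text.
#' @export
write_nexus_matrix <- function(mat, include_mrbayes_block = FALSE, settings = list()) {
  stopifnot(inherits(mat, "morph_matrix"))
  cells <- mat$cells
  ty <- cell_type(cells, mat$missing, mat$gap)
  q <- ty == "questionable"
  if (any(q)) {
    cells[q] <- vapply(cells[q], function(tok) {
      paste0("{", paste(sort(cell_states(tok, mat$missing, mat$gap)), collapse = ""), "}")
    }, character(1))
  }
  names_out <- quote_label(mat$taxa)
  pad <- max(nchar(names_out)) + 2L
  rows <- sprintf("    %-*s%s", pad, names_out,
                  apply(cells, 1L, paste, collapse = ""))
  out <- c(
    "#NEXUS",
    "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(mat$taxa), ncol(cells)),
    sprintf('  FORMAT DATATYPE=STANDARD MISSING=%s GAP=%s SYMBOLS="%s";',
            mat$missing, mat$gap, paste(mat$symbols, collapse = " ")),
    "  MATRIX",
    rows,
    "  ;",
    "END;"
  )
  if (include_mrbayes_block) {
    out <- c(out, "", mrbayes_commands(mat, which(mat$characters$ordered), settings))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Coordinates of questionable cells
#'
#' @param mat a `morph_matrix`.
#' @return TSV text with columns `taxon`, `character`, `states`, one row per
#'   questionable cell.
#' @export
questionable_sidecar <- function(mat) {
  ty <- cell_type(mat$cells, mat$missing, mat$gap)
  hits <- which(ty == "questionable", arr.ind = TRUE)
  lines <- "taxon\tcharacter\tstates"
  if (nrow(hits) > 0L) {
    ord <- order(hits[, 1L], hits[, 2L])
    hits <- hits[ord, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%s", mat$taxa[hits[, 1L]], hits[, 2L],
                              vapply(mat$cells[hits], function(tok) {
                                paste(cell_states(tok, mat$missing, mat$gap), collapse = "")
                              }, character(1))))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Re-flag questionable cells from a sidecar table
#'
#' @param mat a `morph_matrix`.
#' @param sidecar TSV text as produced by [questionable_sidecar()].
#' @return the matrix with the listed cells re-encoded as questionable.
#' @export
apply_questionable <- function(mat, sidecar) {
  df <- utils::read.delim(text = sidecar, colClasses = c("character", "integer", "character"))
  for (i in seq_len(nrow(df))) {
    r <- match(df$taxon[i], mat$taxa)
    if (is.na(r)) stop(sprintf("unknown taxon '%s' in sidecar", df$taxon[i]), call. = FALSE)
    mat$cells[r, df$character[i]] <- paste0(df$states[i], "?")
  }
  mat
}
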