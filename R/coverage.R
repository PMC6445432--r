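# Taxon coverage of a morphological matrix, reported under two conventions:
# mode A counts polymorphic/uncertain/questionable cells as informative
# (scored); mode B counts them as not scored. Gap (inapplicable) cells carry
# no character information and count as not scored by default; `gap_as =
# "scored"` provides the alternative convention.

#' Coverage statistics of a morphological matrix
#'
#' @param mat a `morph_matrix`.
#' @param fossil_taxa labels of the fossil taxa (for extant/fossil group
#'   summaries and per-fossil extremes); may be empty.
#' @param gap_as `"missing"` (default: gap cells are not scored) or
#'   `"scored"`.
#' @return an object of class `coverage_report`: a list with `per_taxon`
#'   (data frame), `overall` (exact percentages and mean missing count),
#'   `groups` (extant/fossil percentages, when fossils are given) and
#'   `extremes` (least/most completely scored taxon among the fossils, or
#'   among all taxa when no fossils are given). Percentages are exact;
#'   the print method rounds to one decimal, half up.
#' @export
coverage_stats <- function(mat, fossil_taxa = character(0), gap_as = c("missing", "scored")) {
  gap_as <- match.arg(gap_as)
  stopifnot(inherits(mat, "morph_matrix"))
  fossil_taxa <- normalise_label(fossil_taxa)
  unknown <- setdiff(fossil_taxa, mat$taxa)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown fossil taxa: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ty <- cell_type(mat$cells, mat$missing, mat$gap)
  nchar_ <- ncol(mat$cells)
  scored_a_cell <- ty != "missing" & (if (gap_as == "missing") ty != "gap" else TRUE)
  multi_cell <- ty %in% c("polymorphic", "uncertain", "questionable")
  dim(multi_cell) <- dim(scored_a_cell)
  scored_a <- rowSums(scored_a_cell)
  scored_b <- scored_a - rowSums(scored_a_cell & multi_cell)
  per_taxon <- data.frame(
    taxon = mat$taxa,
    fossil = mat$taxa %in% fossil_taxa,
    scored_a = as.integer(scored_a),
    scored_b = as.integer(scored_b),
    missing_a = as.integer(nchar_ - scored_a),
    missing_b = as.integer(nchar_ - scored_b),
    pct_a = 100 * scored_a / nchar_,
    pct_b = 100 * scored_b / nchar_,
    stringsAsFactors = FALSE
  )
  pct <- function(rows, col) 100 * sum(per_taxon[[col]][rows]) / (sum(rows) * nchar_)
  all_rows <- rep(TRUE, nrow(per_taxon))
  overall <- list(
    pct_a = pct(all_rows, "scored_a"),
    pct_b = pct(all_rows, "scored_b"),
    mean_missing_a = mean(per_taxon$missing_a),
    n_taxa = nrow(per_taxon),
    n_characters = nchar_
  )
  groups <- NULL
  if (length(fossil_taxa) > 0L) {
    groups <- list(
      extant = list(pct_a = pct(!per_taxon$fossil, "scored_a"),
                    pct_b = pct(!per_taxon$fossil, "scored_b")),
      fossil = list(pct_a = pct(per_taxon$fossil, "scored_a"),
                    pct_b = pct(per_taxon$fossil, "scored_b"))
    )
  }
  pool <- if (length(fossil_taxa) > 0L) per_taxon[per_taxon$fossil, , drop = FALSE] else per_taxon
  i_min <- which.min(pool$scored_a)
  i_max <- which.max(pool$scored_a)
  extremes <- list(
    least_scored = list(taxon = pool$taxon[i_min], scored = pool$scored_a[i_min],
                        pct_missing = 100 * pool$missing_a[i_min] / nchar_),
    most_scored = list(taxon = pool$taxon[i_max], scored = pool$scored_a[i_max],
                       pct_missing = 100 * pool$missing_a[i_max] / nchar_)
  )
  structure(list(per_taxon = per_taxon, overall = overall, groups = groups,
                 extremes = extremes, gap_as = gap_as),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  r1 <- function(v) format(round_half_up(v, 1), nsmall = 1)
  cat(sprintf("Coverage report (%d taxa x %d characters, gap cells %s)\n",
              x$overall$n_taxa, x$overall$n_characters,
              if (x$gap_as == "missing") "not scored" else "scored"))
  cat(sprintf("  overall: %s%% (polymorphisms informative) / %s%% (otherwise)\n",
              r1(x$overall$pct_a), r1(x$overall$pct_b)))
  cat(sprintf("  mean missing per taxon: %d of %d characters\n",
              round_half_up(x$overall$mean_missing_a, 0), x$overall$n_characters))
  if (!is.null(x$groups)) {
    cat(sprintf("  extant: %s%% / %s%%   fossil: %s%% / %s%%\n",
                r1(x$groups$extant$pct_a), r1(x$groups$extant$pct_b),
                r1(x$groups$fossil$pct_a), r1(x$groups$fossil$pct_b)))
  }
  cat(sprintf("  least scored: %s (%s%% missing, %d scored); most scored: %s (%s%% missing, %d scored)\n",
              x$extremes$least_scored$taxon, r1(x$extremes$least_scored$pct_missing),
              x$extremes$least_scored$scored,
              x$extremes$most_scored$taxon, r1(x$extremes$most_scored$pct_missing),
              x$extremes$most_scored$scored))
  invisible(x)
}

#' Coverage report as TSV
#'
#' @param report a `coverage_report`.
#' @return TSV text of the per-taxon table.
#' @export
coverage_table <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  df <- report$per_taxon
  lines <- c(
    "taxon\tfossil\tscored_a\tscored_b\tmissing_a\tmissing_b\tpct_a\tpct_b",
    sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%.1f\t%.1f", df$taxon, df$fossil,
            df$scored_a, df$scored_b, df$missing_a, df$missing_b,
            round_half_up(df$pct_a, 1), round_half_up(df$pct_b, 1))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}
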