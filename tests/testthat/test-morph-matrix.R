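write_nexus_fixture <- function(lines, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".nex", .local_envir = envir)
  writeLines(lines, f)
  f
}

basic_matrix_lines <- c(
  "#NEXUS",
  "BEGIN DATA;",
  "  DIMENSIONS NTAX=2 NCHAR=3;",
  '  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="0 1";',
  "  MATRIX",
  "    taxA      01?",
  "    'tax B'   1(01)-",
  "  ;",
  "END;"
)

test_that("cells are parsed and classified by kind", {
  m <- parse_nexus_matrix(write_nexus_fixture(basic_matrix_lines))
  expect_identical(m$taxa, c("taxA", "tax_B"))
  expect_identical(dim(m$cells), c(2L, 3L))
  expect_identical(as.vector(cell_type(m$cells[1, ])), c("single", "single", "missing"))
  expect_identical(as.vector(cell_type(m$cells[2, ])), c("single", "polymorphic", "gap"))
  expect_identical(cell_states("(01)"), c("0", "1"))
  expect_identical(cell_states("{12}"), c("1", "2"))
  expect_identical(cell_states("?"), character(0))
})

test_that("parse-write-parse is a fixed point", {
  m <- parse_nexus_matrix(write_nexus_fixture(basic_matrix_lines))
  f2 <- withr::local_tempfile(fileext = ".nex")
  cat(write_nexus_matrix(m), file = f2)
  m2 <- parse_nexus_matrix(f2)
  expect_identical(m2$cells, m$cells)
  expect_identical(m2$taxa, m$taxa)
  expect_identical(m2$symbols, m$symbols)
  # and once more: the emitted text itself is stable
  expect_identical(write_nexus_matrix(m2), write_nexus_matrix(m))
})

test_that("interleaved matrices are reassembled", {
  f <- write_nexus_fixture(c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "  DIMENSIONS NTAX=2 NCHAR=4;",
    '  FORMAT DATATYPE=STANDARD INTERLEAVE MISSING=? GAP=- SYMBOLS="0 1 2";',
    "  MATRIX",
    "    taxA  01",
    "    taxB  12",
    "",
    "    taxA  2?",
    "    taxB  {02}1",
    "  ;",
    "END;"
  ))
  m <- parse_nexus_matrix(f)
  expect_identical(unname(m$cells[1, ]), c("0", "1", "2", "?"))
  expect_identical(unname(m$cells[2, ]), c("1", "2", "{02}", "1"))
})

test_that("malformed matrices are reported with coordinates", {
  bad_dim <- basic_matrix_lines
  bad_dim[3] <- "  DIMENSIONS NTAX=3 NCHAR=3;"
  expect_error(parse_nexus_matrix(write_nexus_fixture(bad_dim)), "NTAX")

  bad_sym <- basic_matrix_lines
  bad_sym[6] <- "    taxA      05?"
  expect_error(parse_nexus_matrix(write_nexus_fixture(bad_sym)),
               "taxon 'taxA', character 2")

  ragged <- basic_matrix_lines
  ragged[6] <- "    taxA      01"
  expect_error(parse_nexus_matrix(write_nexus_fixture(ragged)), "expected NCHAR")
})

test_that("questionable scores recode liberally or conservatively", {
  m <- parse_nexus_matrix(write_nexus_fixture(basic_matrix_lines))
  m$cells[1, 3] <- "1?"
  lib <- recode_uncertain(m, "liberal")
  expect_identical(unname(lib$cells[1, 3]), "1")
  con <- recode_uncertain(m, "conservative")
  expect_identical(unname(con$cells[1, 3]), "?")
  # cells other than questionable ones are untouched, and a matrix without
  # questionable cells is a fixed point under both modes
  clean <- parse_nexus_matrix(write_nexus_fixture(basic_matrix_lines))
  expect_identical(recode_uncertain(clean, "liberal")$cells, clean$cells)
  expect_identical(recode_uncertain(clean, "conservative")$cells, clean$cells)
  # liberal never increases missing cells; conservative never decreases them
  n_missing <- function(x) sum(cell_type(x$cells) == "missing")
  expect_lte(n_missing(lib), n_missing(m))
  expect_gte(n_missing(con), n_missing(m))
})

test_that("questionable cells survive a write/parse cycle via the sidecar", {
  m <- parse_nexus_matrix(write_nexus_fixture(basic_matrix_lines))
  m$cells[1, 3] <- "1?"
  side <- questionable_sidecar(m)
  expect_match(side, "taxA\t3\t1")
  f2 <- withr::local_tempfile()
  cat(write_nexus_matrix(m), file = f2)
  m2 <- apply_questionable(parse_nexus_matrix(f2), side)
  expect_identical(m2$cells, m$cells)
})

test_that("gap weighting discretises by range with round-half-up", {
  expect_identical(as.integer(gap_weight(c(a = 0, b = 10, c = 5), 6)), c(0L, 5L, 3L))
  # half-way cases round up: 5/10 * 5 = 2.5 -> 3
  expect_identical(gap_weight(c(a = 0, b = 10, c = 5), 6)[["c"]], 3L)
  # degenerate range: everything state 0
  expect_identical(as.integer(gap_weight(c(a = 2, b = 2, c = NA), 6)), c(0L, 0L, NA))
  expect_error(gap_weight(c(a = NA_real_)), "missing")
  gw <- gap_weight(c(x = 1, y = 4), 6)
  expect_true(attr(gw, "ordered"))
  expect_identical(attr(gw, "source"), "discretised-continuous")
})

test_that("gap weighting is monotone, bounded and affine-invariant", {
  for (seed in 1:10) {
    v <- stats::setNames(local({set.seed(seed); stats::runif(12, -5, 20)}),
                         sprintf("t%02d", 1:12))
    st <- gap_weight(v, 6)
    expect_true(all(st >= 0L & st <= 5L))
    o <- order(v)
    expect_true(all(diff(st[o]) >= 0L))
    expect_identical(as.integer(gap_weight(3 * v + 7, 6)), as.integer(st))
  }
})

test_that("state-space expansion relabels the observed maximum", {
  f <- write_nexus_fixture(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=3 NCHAR=2;",
    '  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="0 1 2 3";',
    "  MATRIX",
    "    tA  00",
    "    tB  1(01)",
    "    tC  ?1",
    "  ;",
    "END;"
  ))
  m <- parse_nexus_matrix(f)
  ex <- expand_state_space(m, c("1" = 3, "2" = 1))
  expect_identical(ex$matrix$cells[, 1], c(tA = "0", tB = "3", tC = "?"))
  # character 2 already at its target: identity
  expect_identical(ex$matrix$cells[, 2], m$cells[, 2])
  expect_identical(ex$changed$index, 1L)
  # the relabelling reaches inside polymorphic sets
  ex2 <- expand_state_space(m, c("2" = 2))
  expect_identical(unname(ex2$matrix$cells[2, 2]), "(02)")
  # number of distinct labels per character is preserved
  n_distinct <- function(cells, j) length(unique(unlist(lapply(cells[, j], cell_states))))
  expect_identical(n_distinct(ex$matrix$cells, 1), n_distinct(m$cells, 1))
  expect_error(expand_state_space(m, c("1" = 0)), "below observed")
})

test_that("coverage statistics count scored cells under both modes", {
  # 2 x 4 matrix with one "?" and one "(01)": mode A 7/8, mode B 6/8
  f <- write_nexus_fixture(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=4;",
    '  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="0 1";',
    "  MATRIX",
    "    tA  01?1",
    "    tB  1(01)01",
    "  ;",
    "END;"
  ))
  m <- parse_nexus_matrix(f)
  cv <- coverage_stats(m)
  expect_equal(cv$overall$pct_a, 100 * 7 / 8)
  expect_equal(cv$overall$pct_b, 100 * 6 / 8)

  full <- simulate_matrix(5, 8, c(missing = 0), seed = 1)
  cvf <- coverage_stats(full)
  expect_equal(cvf$overall$pct_a, 100)
  expect_equal(cvf$overall$pct_b, 100)
  expect_error(coverage_stats(m, fossil_taxa = "nope"), "unknown fossil")
})

test_that("coverage splits extant and fossil groups and reports extremes", {
  m <- simulate_matrix(10, 50, c(missing = 0.2, polymorphic = 0.1), seed = 3)
  # make two taxa heavily missing, acting as the fossils
  m$cells[1, 1:40] <- "?"
  m$cells[2, 1:20] <- "?"
  cv <- coverage_stats(m, fossil_taxa = m$taxa[1:2])
  expect_identical(cv$extremes$least_scored$taxon, m$taxa[1])
  expect_equal(cv$extremes$least_scored$pct_missing,
               100 * cv$per_taxon$missing_a[1] / 50)
  expect_identical(cv$extremes$most_scored$taxon, m$taxa[2])
  expect_gt(cv$groups$extant$pct_a, cv$groups$fossil$pct_a)
  # mode A dominates mode B for every taxon and group
  expect_true(all(cv$per_taxon$pct_a >= cv$per_taxon$pct_b))
  expect_gte(cv$overall$pct_a, cv$overall$pct_b)
  # gap handling flag: gaps as scored can only increase coverage
  m$cells[3, 1:5] <- "-"
  a <- coverage_stats(m)$overall$pct_a
  b <- coverage_stats(m, gap_as = "scored")$overall$pct_a
  expect_gt(b, a)
})

test_that("the MrBayes command block lists ordered characters and model flags", {
  m <- simulate_matrix(4, 10, seed = 2)
  txt <- mrbayes_commands(m, c(9, 2, 5))
  expect_match(txt, "ctype ordered: 2 5 9;", fixed = TRUE)
  expect_match(txt, "lset coding=variable rates=gamma;", fixed = TRUE)
  expect_match(txt, "mcmcp ngen=50000000 nruns=4 nchains=4", fixed = TRUE)
  # no ctype line without ordered characters
  expect_no_match(mrbayes_commands(m, integer(0)), "ctype")
  expect_error(mrbayes_commands(m, 99), "out of range")
  # appended block on request
  full <- write_nexus_matrix(m, include_mrbayes_block = TRUE,
                             settings = list(ngen = 1000))
  expect_match(full, "begin mrbayes;", fixed = TRUE)
  expect_match(full, "ngen=1000", fixed = TRUE)
})
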