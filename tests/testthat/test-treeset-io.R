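test_that("parse_newick handles minimal trees, lengths and supports", {
  tr <- parse_newick("(A,B);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_null(tr$edge.length)

  tr2 <- parse_newick("((A:1.0,B:2.0)0.9:3.0,C:4.0);")
  expect_identical(write_newick(tr2), "((A:1,B:2)0.9:3,C:4);")
  # round-trip is a fixed point on the normalised string
  expect_identical(write_newick(parse_newick(write_newick(tr2))), write_newick(tr2))
})

test_that("quoted labels are normalised and round-trip stable", {
  tr <- parse_newick("('Xorides sp.',B);")
  expect_setequal(tr$tip.label, c("Xorides_sp.", "B"))
  expect_identical(normalise_label("'Xorides sp.'"), "Xorides_sp.")
  expect_identical(normalise_label("Xorides sp."), normalise_label("'Xorides sp.'"))
  out <- write_newick(tr)
  expect_identical(write_newick(parse_newick(out)), out)
})

test_that("malformed newick raises errors naming the position", {
  expect_error(parse_newick("((A,B);"), "position")
  expect_error(parse_newick("(A,A);"), "duplicate")
  expect_error(parse_newick("(A,,B);"), "empty leaf label")
  expect_error(parse_newick("(A,B)"), "';'")
  expect_error(parse_newick("(A,B); junk"), "trailing")
})

test_that("parse/write round-trip is a fixed point on random trees", {
  for (seed in 1:25) {
    n <- 3 + (seed %% 12)
    tr <- random_tree(sprintf("t%02d", seq_len(n)), seed)
    s1 <- write_newick(tr)
    s2 <- write_newick(parse_newick(s1))
    expect_identical(s2, s1)
  }
})

test_that("canonical output orders children by smallest descendant label", {
  a <- parse_newick("((D,C),(B,A));")
  b <- parse_newick("((A,B),(C,D));")
  expect_identical(write_newick(a), write_newick(b))
  expect_identical(write_newick(b), "((A,B),(C,D));")
})

test_that("support values appear as internal-node labels on output", {
  tr <- parse_newick("((A,B)0.97,(C,D)0.51);")
  expect_identical(write_newick(tr), "((A,B)0.97,(C,D)0.51);")
})

local_mrbayes_t_file <- function(n_trees = 10, newicks = NULL) {
  f <- withr::local_tempfile(fileext = ".t", .local_envir = parent.frame())
  if (is.null(newicks)) newicks <- rep("((1,2),(3,4))", n_trees)
  writeLines(c(
    "#NEXUS",
    "begin trees;",
    "   translate",
    "      1 Xorides_praecatorius,",
    "      2 'Pimpla aquilonia',",
    "      3 Scambus_buolianae,",
    "      4 Netelia_sp.",
    "   ;",
    sprintf("   tree gen.%d = [&U] %s;", seq_along(newicks), newicks),
    "end;"
  ), f)
  f
}

test_that("TRANSLATE tables are resolved and labels normalised", {
  f <- local_mrbayes_t_file(3)
  s <- parse_nexus_trees(f)
  expect_length(s$trees, 3L)
  expect_setequal(s$taxa, c("Xorides_praecatorius", "Pimpla_aquilonia",
                            "Scambus_buolianae", "Netelia_sp."))
})

test_that("missing TRANSLATE keys give a descriptive error", {
  f <- local_mrbayes_t_file(newicks = c("((1,2),(3,9))"))
  expect_error(parse_nexus_trees(f), "no entry for: 9")
})

test_that("burn-in removal and even subsampling are deterministic", {
  f <- local_mrbayes_t_file(10)
  s <- parse_nexus_trees(f, burnin_fraction = 0.5, n_sample = 5)
  expect_identical(s$provenance$index, 6:10)

  # 9 post-burn-in trees, 3 requested: stride 3 gives 1, 4, 7
  f2 <- local_mrbayes_t_file(9)
  s2 <- parse_nexus_trees(f2, burnin_fraction = 0, n_sample = 3)
  expect_identical(s2$provenance$index, c(1L, 4L, 7L))

  # identical inputs give identical samples
  s3 <- parse_nexus_trees(f, burnin_fraction = 0.5, n_sample = 5)
  expect_identical(lapply(s$trees, write_newick), lapply(s3$trees, write_newick))
})

test_that("multiple run files are subsampled evenly and concatenated in order", {
  f <- local_mrbayes_t_file(40)
  s <- parse_nexus_trees(rep(f, 4), burnin_fraction = 0.5, n_sample = 40)
  expect_length(s$trees, 40L)
  expect_identical(as.integer(table(s$provenance$run)), rep(10L, 4))
  # stride floor(20/10) = 2 within the post-burn-in window 21..40
  expect_identical(s$provenance$index[s$provenance$run == 1], seq(21L, 39L, by = 2L))
  expect_error(parse_nexus_trees(f, n_sample = 99), "available")
})

test_that("plain newick files are read one statement per tree", {
  f <- withr::local_tempfile()
  writeLines(c("((A,B),C);", "((A,C),B);"), f)
  s <- parse_nexus_trees(f)
  expect_length(s$trees, 2L)
  expect_setequal(s$taxa, c("A", "B", "C"))
})

test_that("root_at_outgroup roots on the outgroup split", {
  tr <- parse_newick("(A,B,(C,D));")
  r1 <- root_at_outgroup(tr, "A")
  expect_true("B;C;D" %in% names(clade_set(r1)))
  r2 <- root_at_outgroup(tr, c("C", "D"))
  cs <- names(clade_set(r2))
  expect_true("C;D" %in% cs)
  expect_true("A;B" %in% cs)
  expect_error(root_at_outgroup(tr, c("A", "C")), "not monophyletic")
  expect_error(root_at_outgroup(tr, character(0)), "non-empty")
  expect_error(root_at_outgroup(tr, c("A", "B", "C", "D")), "proper subset")
})

test_that("rooting divides the outgroup stem length equally", {
  tr <- parse_newick("(A:1,B:1,(C:1,D:1):2);")
  r <- root_at_outgroup(tr, c("C", "D"))
  rows <- which(r$edge[, 1] == length(r$tip.label) + 1L)
  expect_equal(sort(r$edge.length[rows]), c(1, 1))
})

test_that("prune_taxa merges branch lengths and drops suppressed supports", {
  tr <- parse_newick("((A:1,B:1)0.8:1,(C:1,X:2)0.9:3);")
  pr <- prune_taxa(tr, "X")
  expect_identical(write_newick(pr), "((A:1,B:1)0.8:1,C:4);")
  expect_identical(write_newick(prune_taxa(parse_newick("((A,B),(C,X));"), "X")),
                   "((A,B),C);")
  tr2 <- parse_newick("((A,B),(C,D));")
  expect_identical(write_newick(prune_taxa(tr2, character(0))), write_newick(tr2))
  expect_error(prune_taxa(tr2, c("A", "B", "C")), "at least two")
  expect_error(prune_taxa(tr2, "Z"), "not in tree")
})

test_that("pruned clade sets equal the restriction of the original clade sets", {
  for (seed in 1:15) {
    labs <- sprintf("t%02d", 1:20)
    tr <- random_tree(labs, seed)
    dr <- labs[(seed + c(0, 4, 8, 12)) %% 20 + 1]
    pr <- prune_taxa(tr, dr)
    expect_setequal(pr$tip.label, setdiff(labs, dr))
    # no degree-2 internal nodes remain
    tab <- table(pr$edge[, 1])
    expect_true(all(tab >= 2))
    got <- sort(unique(names(clade_set(pr))))
    restr <- lapply(clade_set(tr), function(s) setdiff(s, dr))
    restr <- restr[lengths(restr) > 0]
    want <- sort(unique(vapply(restr, clade_key, character(1))))
    expect_identical(got, want)
  }
})
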