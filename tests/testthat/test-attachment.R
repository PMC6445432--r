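test_that("attachment_clade reads the rogue's sister set", {
  expect_identical(attachment_clade(parse_newick("((A,X),(B,C));"), "X"), "A")
  expect_identical(attachment_clade(parse_newick("(((A,B),X),C);"), "X"), c("A", "B"))
  # co-rogues are pruned before the sister set is read
  expect_identical(attachment_clade(parse_newick("((A,(X,F)),(B,C));"), "X", "F"), "A")
  # rogue sister to everything else: root attachment, S = all remaining taxa
  expect_identical(attachment_clade(parse_newick("(X,(A,(B,C)));"), "X"), c("A", "B", "C"))
  expect_error(attachment_clade(parse_newick("((A,B),C);"), "X"), "not a leaf")
})

test_that("map_attachment distinguishes direct branches from MRCA buckets", {
  cons <- parse_newick("((A,B),(C,D));")
  m1 <- map_attachment(c("A", "B"), cons)
  expect_identical(m1$kind, "direct")
  expect_identical(m1$clade, c("A", "B"))

  m2 <- map_attachment(c("A", "C"), cons)
  expect_identical(m2$kind, "mrca")
  expect_identical(m2$clade, c("A", "B", "C", "D"))

  # a clade absent because of a consensus polytomy maps to the polytomy node
  cons_poly <- parse_newick("((A,B,C),D);")
  m3 <- map_attachment(c("A", "B"), cons_poly)
  expect_identical(m3$kind, "mrca")
  expect_identical(m3$clade, c("A", "B", "C"))

  expect_error(map_attachment(character(0), cons), "empty")
  expect_error(map_attachment(c("A", "Z"), cons), "unknown")
})

test_that("a rogue always sister to one taxon gets all mass on that branch", {
  topo <- parse_newick("(((A,X),B),(C,D));")
  s <- tree_sample(replicate(20, topo, simplify = FALSE))
  cons <- majority_rule(tree_sample(lapply(s$trees, prune_taxa, drop = "X")))
  d <- rogue_distribution(s, "X", consensus = cons)
  expect_equal(unname(d$direct[["A"]]), 1)
  expect_length(d$mrca, 0L)
  expect_equal(sum(d$direct) + sum(d$mrca), 1)
})

test_that("probabilities are integer multiples of 1/n and sum to one", {
  fix <- make_crown_stem_fixture(n = 100)
  cons <- majority_rule(tree_sample(lapply(fix$trees, prune_taxa, drop = "X")))
  d <- rogue_distribution(fix, "X", consensus = cons)
  all_p <- c(d$direct, d$mrca)
  expect_equal(sum(all_p), 1, tolerance = 1e-12)
  expect_true(all(abs(all_p * d$n_trees - round(all_p * d$n_trees)) < 1e-9))
})

test_that("crown and stem mass partition as in the three-topology toy", {
  fix <- make_crown_stem_fixture(n = 100, f = c(0.50, 0.43, 0.07))
  cons <- majority_rule(tree_sample(lapply(fix$trees, prune_taxa, drop = "X")))
  d <- rogue_distribution(fix, "X", consensus = cons)
  # two direct crown buckets and one collapsed branch summarised at the
  # crown node of genus C
  expect_equal(unname(d$direct[["C1"]]), 0.50)
  expect_equal(unname(d$direct[["C2;C3"]]), 0.43)
  expect_equal(unname(d$mrca[["C1;C2;C3"]]), 0.07)
  expect_equal(sum(d$direct) + sum(d$mrca), 1)
})

test_that("recovered probabilities equal the generator draw log exactly", {
  base <- parse_newick("((A,B),((C,D),(E,F)));")
  w <- c("A" = 0.4, "C;D" = 0.35, "E" = 0.25)
  for (seed in c(3, 17, 101)) {
    sim <- simulate_rogue_sample(base, "X", w, n = 120, seed = seed)
    cons <- majority_rule(tree_sample(lapply(sim$sample$trees, prune_taxa, drop = "X")))
    d <- rogue_distribution(sim$sample, "X", consensus = cons)
    freq <- table(sim$draws) / length(sim$draws)
    expect_length(d$mrca, 0L)
    ref <- stats::setNames(as.list(as.numeric(freq)), names(freq))
    expect_mapequal(as.list(d$direct), ref)
  }
})

test_that("identical fully resolved trees give zero MRCA mass", {
  base <- parse_newick("(((A,B),C),(D,E));")
  sim <- simulate_rogue_sample(base, "X", c("A;B" = 1), n = 30, seed = 5)
  cons <- majority_rule(tree_sample(lapply(sim$sample$trees, prune_taxa, drop = "X")))
  expect_identical(cons$Nnode, 4L)  # fully resolved
  d <- rogue_distribution(sim$sample, "X", consensus = cons)
  expect_length(d$mrca, 0L)
  expect_equal(unname(d$direct[["A;B"]]), 1)
})

test_that("multiple rogues are pruned before reading each attachment", {
  # two rogues X and F; X always sister to A once F is removed
  topo <- parse_newick("(((A,(X,F)),B),(C,D));")
  s <- tree_sample(replicate(10, topo, simplify = FALSE))
  cons <- majority_rule(tree_sample(lapply(s$trees, prune_taxa, drop = c("X", "F"))))
  dX <- rogue_distribution(s, "X", all_rogues = c("X", "F"), consensus = cons)
  expect_equal(unname(dX$direct[["A"]]), 1)
  dF <- rogue_distribution(s, "F", all_rogues = c("X", "F"), consensus = cons)
  expect_equal(unname(dF$direct[["A"]]), 1)
  expect_error(rogue_distribution(s, "X", consensus = cons), "leaf set")
})

test_that("rogue_distribution matches the naive set-enumeration reference", {
  # exhaustive small trees plus random samples over <= 7 non-rogue taxa
  for (seed in 1:20) {
    n_taxa <- 4 + (seed %% 4)  # 4..7 non-rogue taxa
    labs <- sprintf("t%d", seq_len(n_taxa))
    base <- random_tree(labs, seed)
    keys <- setdiff(names(clade_set(base)), clade_key(labs))
    w <- rep(1 / 3, 3)
    names(w) <- keys[(seed + seq_len(3)) %% length(keys) + 1]
    sim <- simulate_rogue_sample(base, "X", w, n = 25, seed = 1000 + seed,
                                 jitter_prob = 0.6, jitter_moves = 2)
    cons <- majority_rule(tree_sample(lapply(sim$sample$trees, prune_taxa, drop = "X")))
    d <- rogue_distribution(sim$sample, "X", consensus = cons)
    ref <- oracle_rogue_distribution(sim$sample$trees, "X", cons)
    expect_mapequal(as.list(d$direct), as.list(ref$direct))
    if (length(d$mrca) > 0 || length(ref$mrca) > 0) {
      expect_mapequal(as.list(d$mrca), as.list(ref$mrca))
    }
  }
})

test_that("aggregate_partial keeps totals at one and truncate does not", {
  base <- parse_newick("((A,(B,(C,D))),(E,(F,(G,H))));")
  sim <- simulate_rogue_sample(base, "X", c("A" = 0.95, "G" = 0.03, "H" = 0.02),
                               n = 100, seed = 7)
  cons <- majority_rule(tree_sample(lapply(sim$sample$trees, prune_taxa, drop = "X")))
  d <- rogue_distribution(sim$sample, "X", consensus = cons)

  # min_prob = 0 is the identity
  id <- aggregate_partial(d, cons, min_prob = 0)
  expect_identical(write_newick(id$tree), write_newick(cons))
  expect_identical(id$distribution$direct, d$direct)

  ap <- aggregate_partial(d, cons, min_prob = 0.05, keep = "E")
  expect_setequal(ap$tree$tip.label, c("A", "E"))
  expect_equal(sum(ap$distribution$direct) + sum(ap$distribution$mrca), 1)
  # the scattered sub-threshold mass reappears at the retained ancestor
  expect_equal(unname(ap$distribution$mrca[["A;E"]]),
               1 - unname(d$direct[["A"]]))

  tr <- aggregate_partial(d, cons, min_prob = 0.05, keep = "E", mode = "truncate")
  expect_lt(sum(tr$distribution$direct) + sum(tr$distribution$mrca), 1)
  expect_equal(sum(tr$distribution$direct), unname(d$direct[["A"]]))

  # everything above threshold: nothing is pruned
  d2 <- rogue_distribution(sim$sample, "X", consensus = cons)
  ap2 <- aggregate_partial(d2, cons, min_prob = 0.001)
  expect_equal(sum(ap2$distribution$direct) + sum(ap2$distribution$mrca), 1)
  expect_setequal(ap2$tree$tip.label,
                  unique(unlist(strsplit(names(c(d2$direct, d2$mrca)), ";", fixed = TRUE))))

  expect_error(aggregate_partial(d, cons, min_prob = 0.999), "retained")
})
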