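---
title: "Rogue-taxon attachment probabilities: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rogue-taxon attachment probabilities: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rogueplot)
```

## The quantity being computed

Given a sample of `n` rooted trees over a taxon set that includes one or more
rogue taxa (taxa whose position varies strongly across the sample, typically
incompletely scored fossils), and a consensus tree `C` over the non-rogue
taxa, the package computes for one rogue `x` a probability distribution over
*attachment targets* on `C`:

* **direct** mass on a branch of `C`: the fraction of sampled trees in which
  the sister set of `x` (after pruning the other rogues) is exactly the clade
  subtended by that branch;
* **MRCA** mass on an internal node of `C`: the fraction of trees in which
  the sister set of `x` is *not* a clade of `C`; such a tree is assigned to
  the smallest clade of `C` that contains the sister set, i.e. the most
  recent common ancestor of those taxa.

Each tree contributes exactly once, so the two kinds of mass always sum to 1,
and with counts accumulated as integers and divided once at the end, every
probability is an exact multiple of `1/n` (this makes equality tests, rather
than tolerance tests, possible throughout the test suite). When the tree
sample comes from a Bayesian posterior, the masses are posterior attachment
probabilities; the machinery applies unchanged to bootstrap samples, with the
usual caveats about interpreting bootstrap frequencies.

In the plot, direct mass colours the branch segments *parallel* to the
direction of a rectangular phylogram and MRCA mass colours the
*perpendicular* connectors — hence the two names.

## Conventions the computation relies on

**Rooted clade semantics.** Clades, splits and MRCA targets are rooted
notions here. All sampled trees must be rooted consistently before
summarisation; `root_at_outgroup()` roots each tree on the split separating a
declared outgroup (for ichneumonid wasps, for instance, Xoridinae versus the
rest). The outgroup split's branch length, when present, is divided equally
between the two root children — an arbitrary but documented convention, as
the root position along that branch is not identifiable.

**Label normalisation.** Tree files assembled from different tools disagree
about quoting: MrBayes TRANSLATE tables may quote a label that a hand-edited
Newick writes with underscores. All labels pass through one rule (strip
surrounding quotes, collapse whitespace to underscores) and comparisons are
exact afterwards. Canonical clade keys sort labels bytewise (C locale) so
that output is identical across platforms and locale settings.

**Other rogues are pruned first.** With several rogues in the same sample
(the motivating studies place each of many fossils against one consensus of
the extant taxa, while all fossils are present in the posterior trees
simultaneously), the sister set of the focal rogue is read only after
removing the other rogues, so attachment targets are always expressed over
the non-rogue taxa.

**Root attachment.** If the rogue is sister to everything else (its parent is
the root with two children), the sister set is the full non-rogue taxon set,
which is the root clade of the consensus: the mass is recorded as direct on
the root and drawn on a stub to the left of the root. A representable bucket
is needed because placements on the stem branch of the whole ingroup do occur
in practice.

**Polytomies in sampled trees.** Should a sampled tree itself contain a
polytomy at the rogue's parent, the sister set is the union of all sibling
subtrees. MCMC samplers emit binary trees, so this is a boundary case, but
the MRCA semantics extends to it naturally.

**Strict majority consensus.** `majority_rule()` retains exactly the clades
with frequency strictly above the threshold (default 0.5). Excluding clades
at exactly 50% guarantees pairwise compatibility without tie-breaking and
matches the "halfcompat" semantics of common MCMC summary tools. An
`allcompat = TRUE` flag adds compatible minority clades in descending
frequency order (ties broken lexicographically by clade key) for users who
want a fully resolved tree; plain majority rule is the reference behaviour
because consensus polytomies are precisely what the MRCA buckets summarise.
An externally built consensus can be supplied instead of the internal one,
after pruning the rogues from it.

**Even subsampling.** Posterior samples from `k` independent runs are reduced
to a target size deterministically: per file, after discarding the burn-in
fraction, every `floor(m/k)`-th tree is kept starting from the first
post-burn-in tree. A deterministic stride was chosen over random thinning so
that a given input always yields the same tree sample; the source documents
such summaries only as "sampled evenly", and this is the package's reading of
it.

**Partial plots.** Large consensus trees are unreadable when the mass sits on
a few branches, so `aggregate_partial()` restricts the plot to branches whose
attachment probability exceeds a cutoff (1% in the figures this mimics), plus
an always-kept set such as the outgroup. Two modes are provided because the
sub-threshold mass can be treated two ways: `"aggregate"` (default)
re-assigns the probability of every removed branch to the MRCA bucket of its
nearest retained ancestor, preserving the sum-to-one contract on the pruned
plot; `"truncate"` simply omits it, matching figures that display only the
branches above the cutoff at the price of a visible total below one. With a
cutoff of 0 the operation is the identity.

## The synthetic-data generator

Because real posterior samples require external MCMC software, the package
carries its own generator, and the generator — not any stored fixture —
defines the conditions under which the method is tested.

`simulate_rogue_sample()` draws, for each of `n` trees, an attachment edge of
a fixed base tree from a user-specified multinomial and inserts the rogue
there; the realised draws are logged. Optionally, with probability
`jitter_prob` per tree, it applies `jitter_moves` nearest-neighbour
interchanges (NNI) restricted to a designated clade. The moves are
constrained never to change the clade subtending the drawn attachment edge
(edges on the path from the root to the attachment are excluded as move
targets), which keeps the ground truth exact: the rogue's sister set in every
emitted tree equals the drawn clade, jitter or not.

Two consequences of this design are worth spelling out. First, with no
jitter, the recovered direct probabilities must equal the draw-log
frequencies *exactly*, and the test suite asserts equality, not closeness.
Second, a single NNI per tree can never drive a clade out of a strict
majority consensus: each move destroys at most the clades on one edge's
neighbourhood, so any given base clade survives in at least half of the
jittered trees. The number of moves is therefore a parameter (default 1),
and the tests that need genuine consensus polytomies — collapsed attachment
branches whose mass must resurface as MRCA mass — use three moves inside a
four-leaf clade, a configuration verified to collapse the targeted branch
across seeds while leaving the rest of the tree intact.

What the generator does *not* emulate: character evolution (trees are drawn
directly, not inferred from simulated matrices), autocorrelation along an
MCMC chain, branch lengths (the method is purely topological), and
fossilisation or preservation bias. Passing tests therefore demonstrate the
correctness of the accounting — sister-set reading, consensus mapping,
sum-to-one, partial-plot re-aggregation — not the behaviour of Bayesian
inference on real morphological data.

`simulate_matrix()` builds character matrices whose cell classes (missing,
inapplicable, polymorphic, uncertain, doubtful) hit their target fractions by
exact count rather than by Bernoulli sampling, so coverage statistics on
synthetic matrices are equality checks.

## Matrix preparation

The matrix tools mirror the preparation pipeline of morphological Mk-model
studies:

* **Gap weighting** (`gap_weight()`): a continuous character (typically a
  ratio of length measurements) is range-scaled and discretised into at most
  six ordered states, `round((x - min)/(max - min) * 5)`; six is the ordered
  -character state limit in the downstream software. Rounding is half-up — a
  choice that has to be made explicit because the original description of the
  procedure does not fix the tie rule. The mapping is monotone and invariant
  under affine transforms of the measurements, both asserted as properties.
* **Doubtful scores** (`recode_uncertain()`): observations recorded as "state
  with doubt" (a pre-NEXUS `1?` convention) are resolved either liberally
  (keep the state) or conservatively (set missing). Standard NEXUS has no
  syntax for this cell kind, so on file output such cells are written as
  uncertainty sets and their coordinates travel in a sidecar table
  (`questionable_sidecar()` / `apply_questionable()`).
* **State-space expansion** (`expand_state_space()`): when a larger reference
  matrix shows that a character has more states than observed among the
  sampled taxa, the largest observed label is relabelled to the reference
  maximum. In a matrix-only encoding this is the only way to enlarge the
  declared state space; for ordered characters it deliberately inserts
  unobserved intermediate states. The reference maxima are explicit inputs.
* **Coverage** (`coverage_stats()`): per-taxon and group-wise scored
  percentages under two conventions — polymorphic/uncertain/doubtful cells
  counted as informative (mode A) or as unscored (mode B). Inapplicable
  ("gap") cells are counted as *not* scored by default, since they carry no
  character information; because published coverage figures rarely state
  their convention, `gap_as = "scored"` provides the alternative, and the
  check against the deposited matrix accepts whichever single convention
  reproduces all printed values. Percentages are kept exact internally and
  rounded half-up to one decimal only for display.
* **Command block** (`mrbayes_commands()`): emits the ordered-character
  declaration (`ctype ordered: ...`), the `coding=variable` bias (appropriate
  when constant characters were never scored), gamma-distributed
  among-character rate variation and the MCMC settings as plain text for
  external software. Running the analysis is out of scope.

## Numerical and testing choices

Problem sizes in the test-suite and the acceptance script are the package's
own choices: the sum-to-one contract is exercised over 200 randomised
generator settings (5–40 taxa, 50–500 trees, jitter probability 0–1); the
brute-force cross-check — an independent implementation in the test helpers
that enumerates sister sets from the edge matrix and tests consensus
membership by naive set comparison — runs over every edge of small base trees
(4–7 taxa) plus 100 randomised mixed samples; draw-frequency recovery is
asserted exactly over 10–20 seeds. The worked three-topology example is
instantiated with frequencies 0.50/0.43/0.07; the individual frequencies are
illustrative, the checked claim is the partition arithmetic (93% crown, 7%
at the crown node, 0 elsewhere).

Tolerances: the only floating-point comparison in the core contract is the
sum-to-one check at `1e-9`; everything else is integer-exact by construction.
SVG rendering is deterministic to the byte (fixed number formatting, no
timestamps), which the suite asserts by re-rendering.

## Known limitations

* Attachment position *along* a branch is not modelled; a branch is one
  bucket.
* Joint placement of several rogues (correlations between fossils' positions)
  is not computed — each rogue is summarised marginally, the others pruned.
* Rogue *detection* (leaf-stability scoring) is out of scope; the user says
  which taxa are rogues.
* The consensus must share its leaf set with the pruned sample; partial
  overlap is rejected rather than reconciled.
* Very large trees render, but the SVG layout (fixed row height) is tuned for
  up to a few hundred tips.
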