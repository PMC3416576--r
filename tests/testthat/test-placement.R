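test_that("an allele sister to one species in all loci lands on its edge", {
  bb <- read_newick(text = "(((A,B),(C,D)),(E,F));")
  # six concordant loci, each the backbone with a cherry (x, C)
  gt <- read_newick(text = "(((A,B),((x,C),D)),(E,F));")
  map <- allele_map(data.frame(
    allele = c(bb$tip.label, "x"),
    accession = c(bb$tip.label, "acc1"),
    species = c(bb$tip.label, "PX"),
    role = c(rep("backbone-diploid", 6), "polyploid-query")))
  p <- place_allele(bb, replicate(6, gt, simplify = FALSE), map, "x")
  expect_identical(p$best_edges, "C")
  expect_equal(p$weight, 1)
  # strict minimum: every other candidate scores higher
  others <- p$scores[setdiff(names(p$scores), "C")]
  expect_true(all(others > p$best_score + 1e-9))

  # agreement with the unconstrained exhaustive search (n <= 6 + query):
  # its best tree restricted to the backbone matches, and so does the edge
  taxa <- c(bb$tip.label, MEst:::.QUERY)
  D <- internode_matrix(
    list(gt), map, taxa,
    override = setNames(MEst:::.QUERY, "x"))
  ex <- exhaustive_bme(D, max_n = 7)
  best <- ex$best_trees[[1]]
  expect_equal(rf(prune_leaves(best, bb$tip.label), bb), 0)
  sis <- best$tip.label[best$edge[best$edge[, 1] ==
    best$edge[best$edge[, 2] == match(MEst:::.QUERY, best$tip.label), 1], 2]]
  expect_true("C" %in% sis)
})

test_that("symmetric distances produce exact ties with equal weights", {
  bb <- quartet_backbone()
  gt <- read_newick(text = "((x,A,B),(C,D));")
  map <- toy_map(query_row("x"))
  p <- place_allele(bb, list(gt), map, "x")
  # frozen hand-computed Pauplin scores for the five candidate edges
  expect_equal(p$scores[c("A", "B", "A|B", "C", "D")],
               c(A = 3.5, B = 3.5, `A|B` = 3.5, C = 4, D = 4))
  expect_setequal(p$best_edges, c("A", "B", "A|B"))
  expect_equal(p$weight, 1 / 3)
  expect_equal(p$weight * length(p$best_edges), 1)
})

test_that("per-allele bookkeeping: pruning others, locus-limited N counts", {
  bb <- quartet_backbone()
  map <- toy_map(rbind(query_row("x"), query_row("y", accession = "acc2")))
  # x occurs at one locus; y at another; y must be pruned when placing x
  g1 <- read_newick(text = "(((x,A),B),(C,D));")
  g2 <- read_newick(text = "(((y,C),D),(A,B));")
  p <- place_allele(bb, list(l1 = g1, l2 = g2), map, "x")
  expect_identical(p$best_edges, "A")
  expect_equal(p$locus, "l1")

  taxa <- c(bb$tip.label, MEst:::.QUERY)
  role <- setNames(map$role, map$allele)
  pruned <- lapply(list(g1, g2), function(tr)
    prune_leaves(tr, tr$tip.label[role[tr$tip.label] != "polyploid-query" |
                                    tr$tip.label == "x"]))
  D <- internode_matrix(pruned, map, taxa,
                        override = setNames(MEst:::.QUERY, "x"))
  # allele-row terms come from 1 locus, diploid pairs from both
  expect_equal(unname(D$N[MEst:::.QUERY, c("A", "B", "C", "D")]),
               rep(1L, 4))
  expect_equal(D$N["A", "B"], 2L)

  expect_error(place_allele(bb, list(g2), map, "x"), "absent from all")
  expect_error(place_allele(bb, list(g1), map, "A"), "role")
})

test_that("place_all is order-independent, deterministic, and skippable", {
  bb <- quartet_backbone()
  map <- toy_map(rbind(query_row("x"), query_row("y", accession = "acc2")))
  g1 <- read_newick(text = "(((x,A),B),(C,D));")
  g2 <- read_newick(text = "(((y,C),D),(A,B));")
  trees <- list(l1 = g1, l2 = g2)

  pl <- place_all(bb, trees, map)
  expect_named(pl, c("x", "y"))
  tab <- placements_table(pl)
  expect_equal(sum(tab$weight), 2)  # each allele's weights sum to 1

  pl_rev <- place_all(bb, trees, map, alleles = c("y", "x"))
  expect_equal(pl_rev$x$scores, pl$x$scores)
  expect_equal(pl_rev$y$best_edges, pl$y$best_edges)

  expect_equal(nrow(placements_table(list())), 0)
  expect_length(place_all(bb, trees, map, alleles = character(0)), 0)

  # skip-and-log: an allele absent from all loci is dropped with a warning
  expect_warning(
    ps <- place_all(bb, list(l1 = g1), map, alleles = c("x", "y"),
                    on_error = "skip"),
    "skipping allele 'y'")
  expect_named(ps, "x")
})

test_that("candidate scoring preserves the backbone restriction", {
  set.seed(21)
  bb <- ape::rtree(7)
  cand <- candidate_set(bb)
  expect_length(cand$grafts, 11)  # 2*7 - 3
  for (g in cand$grafts)
    expect_equal(rf(prune_leaves(g, bb$tip.label), bb), 0)
})

test_that("representative allele is the one nearest the clade root", {
  gt <- read_newick(text = "(((x1,(x2,x3)),o1),o2);")
  expect_equal(select_representative_allele(gt, c("x1", "x2", "x3")), "x1")
  # equidistant alleles: lexicographically smallest id
  gt2 <- read_newick(text = "(((x2,x1),o1),o2);")
  expect_equal(select_representative_allele(gt2, c("x1", "x2")), "x1")
  expect_equal(select_representative_allele(gt, "x2"), "x2")
  # alleles spanning multiple clades: rule does not apply
  gt3 <- read_newick(text = "((x1,o1),(x2,o2));")
  expect_error(select_representative_allele(gt3, c("x1", "x2")),
               "does not apply")
  mrca <- ape::getMRCA(gt, c("x1", "x2"))
  expect_error(select_representative_allele(gt, c("x1", "o2"),
                                            clade_root = mrca),
               "does not apply")
})
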