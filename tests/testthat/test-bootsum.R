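# Small deterministic bootstrap fixtures built from concordant gene trees.
boot_fixture <- function() {
  bb <- quartet_backbone()
  map <- toy_map(rbind(query_row("x"), query_row("y", accession = "acc2"),
                       query_row("z", accession = "acc2")))
  # x sister to A; y sister to C; z sister to D
  g <- read_newick(text = "(((x,A),B),((y,C),(z,D)));")
  list(bb = bb, map = map, g = g)
}

test_that("replicates conserve weight and identical inputs repeat exactly", {
  fx <- boot_fixture()
  g1 <- read_newick(text = "(((x,A),B),((y,C),D));")
  reps <- run_bootstrap(fx$bb, list(list(l1 = g1), list(l1 = g1)), fx$map,
                        alleles = c("x", "y"))
  expect_equal(reps$R, 2)
  expect_identical(reps$detail[[1]], reps$detail[[2]])
  for (tab in reps$detail) expect_equal(sum(tab$weight), 2)

  # a tied allele splits its unit weight across edges
  gt_tie <- read_newick(text = "((x,A,B),(C,D));")
  r2 <- run_bootstrap(fx$bb, list(list(l1 = gt_tie)), fx$map,
                      alleles = "x")
  tab <- r2$detail[[1]]
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$weight), 1)
  expect_true(all(tab$weight == 1 / 3))

  # replicates must agree on the number of loci
  expect_error(run_bootstrap(fx$bb, list(list(l1 = g1),
                                         list(l1 = g1, l2 = g1)),
                             fx$map, alleles = "x"),
               "disagree on the number of loci")
})

test_that("summaries implement the support, median and trim-CI rules", {
  # construct replicate details directly to control the count samples
  mk_reps <- function(counts, edge = "A") {
    detail <- lapply(counts, function(k) {
      if (k == 0)
        return(data.frame(allele = character(), accession = character(),
                          species = character(), locus = character(),
                          edge_id = character(), weight = numeric(),
                          score = numeric()))
      data.frame(allele = paste0("a", seq_len(k)), accession = "acc",
                 species = "S", locus = "l1", edge_id = edge, weight = 1,
                 score = 0)
    })
    structure(list(edge_ids = enumerate_edges(quartet_backbone()),
                   backbone = quartet_backbone(),
                   detail = detail, R = length(counts)),
              class = "mest_replicates")
  }

  # support = % of replicates with >= 1 allele on the edge
  s <- summarize_bootstrap(mk_reps(c(rep(0, 7), rep(1, 93))))
  a <- s[s$id == "A", ]
  expect_equal(a$support_pct, 93)

  # R = 100: drop exactly 5 from each side
  s2 <- summarize_bootstrap(mk_reps(c(rep(0, 5), rep(1, 90), rep(5, 5))))
  a2 <- s2[s2$id == "A", ]
  expect_equal(c(a2$ci_lo, a2$ci_hi), c(1, 1))
  expect_equal(a2$median, 1)
  expect_equal(a2$support_pct, 95)

  # R = 10: floor(0.05 * 10) = 0 dropped per side
  s3 <- summarize_bootstrap(mk_reps(0:9))
  a3 <- s3[s3$id == "A", ]
  expect_equal(c(a3$ci_lo, a3$ci_hi), c(0, 9))

  # with R = 100 and integer counts, CI endpoints are order stats 6 and 95
  set.seed(8)
  counts <- sample(0:12, 100, replace = TRUE)
  s4 <- summarize_bootstrap(mk_reps(counts))
  a4 <- s4[s4$id == "A", ]
  expect_equal(a4$ci_lo, sort(counts)[6])
  expect_equal(a4$ci_hi, sort(counts)[95])
})

test_that("clade counts dominate edge counts and honor the stem flag", {
  bb <- read_newick(text = "(((A,B),(C,D)),out);")
  map <- allele_map(data.frame(
    allele = c(bb$tip.label, "x", "y"),
    accession = c(bb$tip.label, "acc1", "acc1"),
    species = c(bb$tip.label, "PX", "PX"),
    role = c(rep("backbone-diploid", 4), "outgroup",
             "polyploid-query", "polyploid-query")))
  g <- read_newick(text = "((((x,A),B),((y,C),D)),out);")
  reps <- run_bootstrap(bb, list(list(l1 = g)), map,
                        alleles = c("x", "y"))
  cl <- clade_defs(list(AB = c("A", "B"), CD = c("C", "D"),
                        ALL = c("A", "B", "C", "D")))
  s <- summarize_bootstrap(reps, clades = cl)
  expect_equal(s[s$id == "AB", "median"], 1)
  expect_equal(s[s$id == "ALL", "median"], 2)
  # clade count >= max single edge count within it
  emax <- max(s[s$scope == "edge" & s$id %in% c("A", "B"), "median"])
  expect_gte(s[s$id == "AB", "median"], emax)

  # stem inclusion: an allele on the AB stem edge counts for AB only when
  # the stem is included
  g_stem <- read_newick(text = "(((x,(A,B)),((y,C),D)),out);")
  reps2 <- run_bootstrap(bb, list(list(l1 = g_stem)), map,
                         alleles = c("x", "y"))
  s_in <- summarize_bootstrap(reps2, clades = cl)
  s_out <- summarize_bootstrap(reps2,
                               clades = clade_defs(cl$members,
                                                   include_stem = FALSE))
  expect_equal(s_in[s_in$id == "AB", "median"], 1)
  expect_equal(s_out[s_out$id == "AB", "median"], 0)
})

test_that("per-accession summaries partition and add up to pooled counts", {
  fx <- boot_fixture()
  g <- read_newick(text = "(((x,A),B),((y,C),(z,D)));")
  reps <- run_bootstrap(fx$bb, list(list(l1 = g), list(l1 = g)), fx$map,
                        alleles = c("x", "y", "z"))
  pooled <- summarize_bootstrap(reps)
  pa <- per_accession_summaries(reps, fx$map)
  expect_setequal(names(pa), c("acc1", "acc2"))
  # per replicate the accession medians add to the pooled medians
  for (e in reps$edge_ids) {
    tot <- sum(vapply(pa, function(s) s[s$id == e, "median"], numeric(1)))
    expect_equal(tot, pooled[pooled$id == e, "median"])
  }
  # single accession subset equals the pooled summary restricted to it
  solo <- summarize_bootstrap(reps, alleles = c("y", "z"))
  expect_equal(pa$acc2, solo)
})

test_that("rendering honors display thresholds, stars, and clade bars", {
  bb <- quartet_backbone()
  summ <- data.frame(
    scope = c("edge", "edge", "edge", "edge", "edge", "clade"),
    id = c("A", "B", "C", "D", "A|B", "CD"),
    support_pct = c(96, 91, 69, 0, 72, 96),
    median = c(2, 1, 1, 0, 1, 1),
    ci_lo = c(1, 0, 0, 0, 0, 1),
    ci_hi = c(3, 2, 1, 0, 2, 2))
  cl <- clade_defs(list(CD = c("C", "D")))
  out <- render_summary(bb, summ, clades = cl)
  expect_equal(out$table$class, c("**", "*", "", "", "", "**"))
  expect_equal(out$table$displayed, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # 69% edge is absent from the Newick but present in the table
  expect_false(grepl("support=69", out$newick))
  expect_true(grepl("support=96\\*\\*", out$newick))
  expect_true(grepl("support=72,", out$newick))
  # clade CD passes display, no single CD edge does -> bar emitted
  expect_equal(out$clade_bars$id, "CD")
  # if an edge inside the clade is displayed, no bar
  summ2 <- summ
  summ2$support_pct[3] <- 90
  out2 <- render_summary(bb, summ2, clades = cl)
  expect_equal(nrow(out2$clade_bars), 0)
})
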