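# Multispecies-coalescent gene-tree simulator with polyploid alleles planted
# on known donor edges. Within each species-tree branch, lineages coalesce
# with rate k(k-1)/2 per coalescent unit (exponential waiting times, uniform
# pair merging); lineage sets merge at species-tree nodes; a polyploid
# allele enters the population of its donor edge at its attachment time.
# Bootstrap replicates are emulated by independent coalescent draws per
# locus: a structural stand-in for alignment bootstrapping, which would
# require sequence-level inference.

#' A small ultrametric backbone tree for simulations and examples
#'
#' 15 species: an outgroup plus three ingroup clades (cladeA `s01`-`s05`,
#' cladeB `s06`-`s10`, cladeC `s11`-`s14`) mirroring the coarse clade
#' structure the method is used to summarize over. Branch lengths are in
#' coalescent units; internal ingroup branches are about 0.5-1 unit, i.e.
#' moderate incomplete lineage sorting.
#'
#' @param branch_scale Multiply all node times by this factor; large values
#'   (e.g. 50) suppress gene-tree discordance.
#' @return A rooted ultrametric `phylo`.
#' @export
example_backbone <- function(branch_scale = 1) {
  a <- "((s01:1,s02:1):1,(s03:1.5,(s04:1,s05:1):0.5):0.5)"
  b <- "((s06:1,s07:1):1,(s08:1.5,(s09:1,s10:1):0.5):0.5)"
  c <- "((s11:1,s12:1):1,(s13:1,s14:1):1)"
  nwk <- paste0("(out:6,(", a, ":2,(", b, ":1,", c, ":1):1):2);")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * branch_scale
  tr
}

#' Clade definitions matching [example_backbone()]
#' @param include_stem See [clade_defs()].
#' @export
example_clades <- function(include_stem = TRUE) {
  clade_defs(list(cladeA = paste0("s0", 1:5),
                  cladeB = c(paste0("s0", 6:9), "s10"),
                  cladeC = paste0("s1", 1:4)),
             include_stem = include_stem)
}

# Node times (before present, coalescent units) of an ultrametric rooted tree.
.node_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  round(max(depth) - depth, 12)
}

#' Specify a placement simulation
#'
#' @param backbone Rooted ultrametric `phylo`, branch lengths in coalescent
#'   units.
#' @param polyploids `data.frame` with columns `allele`, `accession`,
#'   `species`, `donor_edge` (an id from [enumerate_edges()]) and
#'   `attach_time` (coalescent units before present; must lie within the
#'   donor edge's time span).
#' @param n_loci Number of loci `L` (default 6, the study design this
#'   generator emulates).
#' @param inds_per_species Gene copies sampled per backbone species
#'   (default 1).
#' @param n_replicates Number of emulated bootstrap replicates `R`.
#' @param outgroups Backbone species to mark with role `outgroup`.
#' @param seed RNG seed; every draw flows through R's RNG.
#' @return Object of class `sim_spec`.
#' @export
simulation_spec <- function(backbone, polyploids, n_loci = 6,
                            inds_per_species = 1, n_replicates = 1,
                            outgroups = character(0), seed = 1) {
  stopifnot(n_loci >= 1, n_replicates >= 1, inds_per_species >= 1)
  need <- c("allele", "accession", "species", "donor_edge", "attach_time")
  if (!all(need %in% names(polyploids)))
    stop("polyploids needs columns: ", paste(need, collapse = ", "))
  edge_ids <- enumerate_edges(backbone)
  spans <- .edge_spans(backbone, edge_ids)
  for (i in seq_len(nrow(polyploids))) {
    e <- polyploids$donor_edge[i]
    if (!e %in% edge_ids) stop("unknown donor edge: ", e)
    sp <- spans[[e]]
    t <- polyploids$attach_time[i]
    if (t < sp[1] || t > sp[2])
      stop("attachment time ", t, " outside donor edge span [",
           sp[1], ", ", sp[2], "] for allele ", polyploids$allele[i])
  }
  structure(list(backbone = backbone, polyploids = polyploids,
                 n_loci = n_loci, inds_per_species = inds_per_species,
                 n_replicates = n_replicates, outgroups = outgroups,
                 seed = seed, edge_ids = edge_ids),
            class = "sim_spec")
}

# Time span [t_child, t_parent] of each EdgeId in the rooted backbone; the
# merged root edge spans from its (chosen) child node up to the root.
.edge_spans <- function(backbone, edge_ids) {
  times <- .node_times(backbone)
  below <- .clades_below(backbone)
  fp <- vapply(below, .fingerprint, character(1))
  parent_of <- integer(max(backbone$edge))
  parent_of[backbone$edge[, 2]] <- backbone$edge[, 1]
  out <- lapply(edge_ids, function(id) {
    node <- which(fp == id)[1]
    c(times[node], times[parent_of[node]])
  })
  names(out) <- edge_ids
  out
}

#' Allele map implied by a simulation spec
#' @param spec A [simulation_spec()].
#' @return An [allele_map()] covering every simulated gene-tree leaf.
#' @export
sim_allele_map <- function(spec) {
  species <- spec$backbone$tip.label
  dip <- do.call(rbind, lapply(species, function(s) {
    labs <- if (spec$inds_per_species == 1) s else
      paste0(s, "_", seq_len(spec$inds_per_species))
    data.frame(allele = labs, accession = labs, species = s,
               role = if (s %in% spec$outgroups) "outgroup"
                      else "backbone-diploid")
  }))
  pol <- data.frame(allele = spec$polyploids$allele,
                    accession = spec$polyploids$accession,
                    species = spec$polyploids$species,
                    role = "polyploid-query")
  allele_map(rbind(dip, pol))
}

# Simulate one gene tree. `entries[[child_fp]]` lists (label, time) of extra
# lineages entering the population of that rooted edge at the given time.
.sim_one_tree <- function(backbone, inds_per_species, entries) {
  times <- .node_times(backbone)
  below <- .clades_below(backbone)
  fp <- vapply(below, .fingerprint, character(1))
  n_tip <- length(backbone$tip.label)
  root <- n_tip + 1L
  ord <- ape::reorder.phylo(backbone, "postorder")
  parent_of <- integer(max(backbone$edge))
  parent_of[backbone$edge[, 2]] <- backbone$edge[, 1]

  # a lineage is list(nwk = subtree string, h = height of its top node)
  pop <- vector("list", n_tip + backbone$Nnode)  # lineages arriving at node
  for (i in seq_len(n_tip)) {
    s <- backbone$tip.label[i]
    labs <- if (inds_per_species == 1) s else
      paste0(s, "_", seq_len(inds_per_species))
    pop[[i]] <- lapply(labs, function(l) list(nwk = l, h = 0))
  }

  coalesce_in <- function(lineages, t0, t1, incoming) {
    # incoming: data.frame(label, time) sorted by time, within (t0, t1]
    t <- t0
    i <- 1L
    repeat {
      k <- length(lineages)
      t_entry <- if (i <= nrow(incoming)) incoming$time[i] else Inf
      t_coal <- if (k >= 2) t + rexp(1, rate = k * (k - 1) / 2) else Inf
      if (t_entry <= t_coal && t_entry <= t1) {
        lineages[[k + 1L]] <- list(nwk = incoming$label[i], h = 0)
        t <- t_entry
        i <- i + 1L
      } else if (t_coal <= t1) {
        pair <- sample.int(k, 2)
        a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
        merged <- list(
          nwk = paste0("(", a$nwk, ":", format(t_coal - a$h, digits = 15),
                       ",", b$nwk, ":", format(t_coal - b$h, digits = 15),
                       ")"),
          h = t_coal)
        lineages <- c(lineages[-pair], list(merged))
        t <- t_coal
      } else break
    }
    lineages
  }

  # postorder over edges: simulate each child's branch up to its parent
  done <- logical(n_tip + backbone$Nnode)
  for (r in seq_len(nrow(ord$edge))) {
    child <- ord$edge[r, 2]
    parent <- ord$edge[r, 1]
    inc <- entries[[fp[child]]]
    inc <- if (is.null(inc)) data.frame(label = character(), time = numeric())
           else inc[order(inc$time), , drop = FALSE]
    surv <- coalesce_in(pop[[child]], times[child], times[parent], inc)
    pop[[parent]] <- c(pop[[parent]], surv)
  }
  # ancestral population above the root: coalesce to a single lineage
  lineages <- pop[[root]]
  t <- times[root]
  while (length(lineages) > 1) {
    k <- length(lineages)
    t <- t + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
    merged <- list(
      nwk = paste0("(", a$nwk, ":", format(t - a$h, digits = 15),
                   ",", b$nwk, ":", format(t - b$h, digits = 15), ")"),
      h = t)
    lineages <- c(lineages[-pair], list(merged))
  }
  ape::read.tree(text = paste0(lineages[[1]]$nwk, ";"))
}

#' Simulate replicate gene-tree sets with planted polyploid alleles
#'
#' For each replicate and locus, draws an independent gene tree under the
#' multispecies coalescent on the backbone, with each polyploid allele's
#' lineage entering the population of its donor edge at its attachment time.
#'
#' @param spec A [simulation_spec()].
#' @return List with `replicates` (list of `R` gene-tree sets, each a named
#'   list of `L` `phylo` trees), `allele_map`, and `truth`
#'   (`data.frame(allele, true_edge)`).
#' @export
simulate_gene_trees <- function(spec) {
  set.seed(spec$seed)
  entries <- split(
    data.frame(label = spec$polyploids$allele,
               time = spec$polyploids$attach_time),
    spec$polyploids$donor_edge)
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    trees <- lapply(seq_len(spec$n_loci), function(l)
      .sim_one_tree(spec$backbone, spec$inds_per_species, entries))
    names(trees) <- paste0("locus", seq_len(spec$n_loci))
    trees
  })
  list(replicates = reps,
       allele_map = sim_allele_map(spec),
       truth = data.frame(allele = spec$polyploids$allele,
                          true_edge = spec$polyploids$donor_edge))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' One multi-tree Newick file per locus (replicate r = r-th tree of every
#' file), the allele map TSV, the truth TSV, and a clade TSV when given.
#'
#' @param sim Output of [simulate_gene_trees()].
#' @param dir Output directory (created if needed).
#' @param clades Optional [clade_defs()] to serialize.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, clades = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- names(sim$replicates[[1]])
  for (l in loci) {
    trees <- lapply(sim$replicates, `[[`, l)
    class(trees) <- "multiPhylo"
    write_newick(trees, file.path(dir, paste0(l, ".nwk")))
  }
  write_allele_map(sim$allele_map, file.path(dir, "allele_map.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clades)) {
    df <- data.frame(
      clade = rep(names(clades$members), lengths(clades$members)),
      species = unlist(clades$members, use.names = FALSE))
    utils::write.table(df, file.path(dir, "clades.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Simulate, place, and score recovery against the planted truth
#'
#' Runs the full pipeline on a simulated dataset and reports how often the
#' placement machinery recovers each allele's true donor edge, and (given
#' clade definitions) how much placement weight falls within the true
#' donor's clade.
#'
#' @param spec A [simulation_spec()].
#' @param clades Optional [clade_defs()] for clade-level accuracy; clades
#'   must cover the donor edges they are scored against.
#' @param tol Tie tolerance passed to the placement engine.
#' @return List with `per_allele` (data.frame of per-allele accuracies
#'   averaged over replicates), `edge_accuracy` (mean weight on the true
#'   edge), `exact_unique_rate` (fraction of (allele, replicate) placements
#'   that are unique and exactly the true edge), `clade_accuracy` (mean
#'   weight within the true clade, `NA` without clades), and `replicates`
#'   (the `mest_replicates` object).
#' @export
recovery_experiment <- function(spec, clades = NULL, tol = 1e-9) {
  sim <- simulate_gene_trees(spec)
  reps <- run_bootstrap(spec$backbone, sim$replicates, sim$allele_map,
                        alleles = sim$truth$allele, tol = tol)
  truth <- setNames(sim$truth$true_edge, sim$truth$allele)
  clade_edges <- if (is.null(clades)) NULL else
    .clade_edge_sets(reps$edge_ids, clades)
  true_clade_edges <- if (is.null(clade_edges)) NULL else
    lapply(truth, function(e) {
      hit <- names(clade_edges)[vapply(clade_edges, function(es) e %in% es,
                                       logical(1))]
      if (length(hit) == 0) character(0) else clade_edges[[hit[1]]]
    })

  rows <- lapply(names(truth), function(a) {
    wt_true <- 0; wt_clade <- 0; exact <- 0; nrep <- 0
    for (tab in reps$detail) {
      sub <- tab[tab$allele == a, , drop = FALSE]
      if (nrow(sub) == 0) next
      nrep <- nrep + 1
      wt_true <- wt_true + sum(sub$weight[sub$edge_id == truth[a]])
      if (nrow(sub) == 1 && sub$edge_id == truth[a]) exact <- exact + 1
      if (!is.null(true_clade_edges))
        wt_clade <- wt_clade +
          sum(sub$weight[sub$edge_id %in% true_clade_edges[[a]]])
    }
    data.frame(allele = a, true_edge = truth[a],
               edge_accuracy = wt_true / max(nrep, 1),
               exact_unique_rate = exact / max(nrep, 1),
               clade_accuracy = if (is.null(true_clade_edges)) NA_real_
                                else wt_clade / max(nrep, 1),
               n_replicates = nrep, row.names = NULL)
  })
  per_allele <- do.call(rbind, rows)
  list(per_allele = per_allele,
       edge_accuracy = mean(per_allele$edge_accuracy),
       exact_unique_rate = mean(per_allele$exact_unique_rate),
       clade_accuracy = if (is.null(true_clade_edges)) NA_real_
                        else mean(per_allele$clade_accuracy),
       replicates = reps)
}

#' Default planted-allele design on [example_backbone()]
#'
#' Plants `n` polyploid alleles from `ceiling(n / 2)` two-allele accessions
#' round-robin over a spread of terminal and internal donor edges, each
#' attached mid-edge.
#'
#' @param backbone The backbone the alleles are planted on.
#' @param n Number of alleles.
#' @param donor_edges Optional explicit donor edge ids recycled over
#'   alleles; default picks a deterministic spread over the backbone edges
#'   excluding the outgroup terminal and the merged root edge.
#' @return A `data.frame` suitable for [simulation_spec()].
#' @export
example_polyploids <- function(backbone = example_backbone(), n = 10,
                               donor_edges = NULL) {
  edge_ids <- enumerate_edges(backbone)
  spans <- .edge_spans(backbone, edge_ids)
  if (is.null(donor_edges)) {
    cand <- setdiff(edge_ids, c("out", edge_ids[length(edge_ids)]))
    # exclude the merged root edge (widest span ending at the root time)
    root_t <- max(.node_times(backbone))
    cand <- cand[vapply(cand, function(e) spans[[e]][2] < root_t, logical(1))]
    donor_edges <- cand[(seq_len(n) - 1L) %% length(cand) + 1L]
  } else {
    donor_edges <- donor_edges[(seq_len(n) - 1L) %% length(donor_edges) + 1L]
  }
  acc <- paste0("poly", (seq_len(n) + 1L) %/% 2L)
  data.frame(
    allele = sprintf("q%02d", seq_len(n)),
    accession = acc,
    species = "polyspecies",
    donor_edge = donor_edges,
    attach_time = vapply(donor_edges, function(e) mean(spans[[e]]),
                         numeric(1)))
}
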