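# Shared fixtures and independent oracles for the suite. Everything is
# built in code; no data files.

# Quartet backbone and a minimal allele map around it.
quartet_backbone <- function() read_newick(text = "((A,B),(C,D));")

toy_map <- function(extra = NULL) {
  base <- data.frame(
    allele = c("A", "B", "C", "D"),
    accession = c("A", "B", "C", "D"),
    species = c("A", "B", "C", "D"),
    role = "backbone-diploid")
  allele_map(rbind(base, extra))
}

query_row <- function(allele, accession = "acc1", species = "PX") {
  data.frame(allele = allele, accession = accession, species = species,
             role = "polyploid-query")
}

# Independent internode oracle: breadth-first search on the adjacency list
# of the unrooted tree; counts the internal nodes strictly between the two
# leaves. Shares nothing with .topo_dist/dist.nodes.
oracle_internode <- function(tree, a, b) {
  ur <- ape::unroot(tree)
  n_tip <- length(ur$tip.label)
  adj <- vector("list", n_tip + ur$Nnode)
  for (k in seq_len(nrow(ur$edge))) {
    p <- ur$edge[k, 1]; c <- ur$edge[k, 2]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  start <- match(a, ur$tip.label)
  goal <- match(b, ur$tip.label)
  prev <- rep(NA_integer_, length(adj))
  queue <- start
  prev[start] <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == goal) break
    for (u in adj[[v]]) if (is.na(prev[u])) {
      prev[u] <- v
      queue <- c(queue, u)
    }
  }
  path <- goal
  while (path[1] != start) path <- c(prev[path[1]], path)
  sum(path > n_tip)  # internal nodes on the path (endpoints are tips)
}

# Random unrooted binary tree with positive branch lengths and its exact
# additive distance matrix; the generating tree is the known truth.
random_additive <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  list(tree = tr, D = cophenetic(tr), total = sum(tr$edge.length))
}

rf <- function(t1, t2) phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))

# Gene trees in which every taxon of `species_tree` is replaced by a clade
# of `k` individuals named <taxon>_<i>.
expand_individuals <- function(species_tree, k) {
  txt <- write_newick(species_tree)
  for (s in species_tree$tip.label) {
    clade <- paste0("(", paste0(s, "_", seq_len(k), collapse = ","), ")")
    txt <- gsub(paste0("(?<=[(,])", s, "(?=[,):])"), clade, txt, perl = TRUE)
  }
  read_newick(text = txt)
}

map_for_species <- function(species, inds = 1) {
  labs <- if (inds == 1) species else
    unlist(lapply(species, function(s) paste0(s, "_", seq_len(inds))))
  sp <- if (inds == 1) species else rep(species, each = inds)
  allele_map(data.frame(allele = labs, accession = labs, species = sp,
                        role = "backbone-diploid"))
}
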