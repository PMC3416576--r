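# The placement engine: for one polyploid allele at a time, prune all other
# polyploid alleles from every gene tree, build the internode distance matrix
# over backbone taxa plus the allele, score the allele grafted onto each of
# the 2n-3 backbone edges by balanced ME, and keep the minimal-score edge set
# with equal tie weights.

.QUERY <- ".query."

#' Precompute the candidate graftings for a backbone
#'
#' Grafting the query onto each backbone edge and computing Pauplin weights
#' depends only on the backbone, so it is done once and reused across
#' alleles and bootstrap replicates.
#'
#' @param backbone Rooted binary `phylo` backbone.
#' @return An object of class `mest_candidates`.
#' @export
candidate_set <- function(backbone) {
  edge_ids <- enumerate_edges(backbone)
  grafts <- .graft_all(backbone, .QUERY, edge_ids)
  labs <- sort(c(backbone$tip.label, .QUERY))
  weights <- lapply(grafts, function(g) pauplin_weights(g)[labs, labs])
  structure(list(backbone = backbone,
                 edge_ids = edge_ids,
                 labels = labs,
                 weights = weights,
                 grafts = grafts),
            class = "mest_candidates")
}

# Score every candidate edge for a query row named `.QUERY` in D.
.score_candidates <- function(cand, D) {
  Dl <- D[cand$labels, cand$labels]
  ut <- upper.tri(Dl)
  if (anyNA(Dl[ut])) {
    bad <- which(is.na(Dl) & ut, arr.ind = TRUE)
    stop("undefined distance under strict policy for pair(s): ",
         paste(utils::head(apply(bad, 1, function(ij)
           paste(cand$labels[ij], collapse = "-")), 5), collapse = ", "))
  }
  vapply(cand$weights, function(w) sum(w[ut] * Dl[ut]), numeric(1))
}

#' Place one polyploid allele on the backbone
#'
#' Implements the per-allele analysis: all polyploid alleles except the one
#' of interest are pruned from every gene tree; an internode distance matrix
#' is computed over the backbone taxa plus the allele (backbone-taxon pairs
#' average over all loci, allele rows only over the gene trees containing
#' it); each grafting of the allele onto a backbone edge is scored by
#' [bme_length()]; all edges within `tol` of the minimum are retained with
#' equal weights.
#'
#' @param backbone Rooted binary `phylo` whose leaves are species names of
#'   role `backbone-diploid` or `outgroup`.
#' @param gene_trees List of `phylo` gene trees (leaves = allele ids),
#'   optionally named by locus.
#' @param allele_map An [allele_map()].
#' @param allele Allele id of role `polyploid-query`.
#' @param candidates Optional precomputed [candidate_set()] for `backbone`.
#' @param tol Absolute tie tolerance on scores (default 1e-9; internode
#'   distances are rationals so exact ties are common and must not be split
#'   by floating-point noise).
#' @param missing_pairs Passed to [internode_matrix()].
#' @return An object of class `mest_placement` with the best edge set,
#'   equal tie weights summing to 1, the best score, and the full score
#'   vector.
#' @export
place_allele <- function(backbone, gene_trees, allele_map, allele,
                         candidates = NULL, tol = 1e-9,
                         missing_pairs = "strict") {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  role <- setNames(allele_map$role, allele_map$allele)
  if (is.na(role[allele]))
    stop("allele '", allele, "' not in allele map")
  if (role[allele] != "polyploid-query")
    stop("allele '", allele, "' has role '", role[allele],
         "', expected 'polyploid-query'")
  if (is.null(candidates)) candidates <- candidate_set(backbone)

  has_allele <- vapply(gene_trees, function(t) allele %in% t$tip.label,
                       logical(1))
  if (!any(has_allele))
    stop("allele '", allele, "' absent from all gene trees")

  # prune every other polyploid allele, keep diploid/outgroup alleles + focal
  pruned <- lapply(gene_trees, function(tr) {
    r <- role[tr$tip.label]
    if (anyNA(r))
      stop("gene-tree leaf not in allele map: ",
           paste(utils::head(tr$tip.label[is.na(r)], 5), collapse = ", "))
    keep <- tr$tip.label[role[tr$tip.label] != "polyploid-query" |
                           tr$tip.label == allele]
    if (length(keep) < 2) return(NULL)
    if (length(keep) == length(tr$tip.label)) tr else prune_leaves(tr, keep)
  })
  pruned <- pruned[!vapply(pruned, is.null, logical(1))]

  taxa <- c(backbone$tip.label, .QUERY)
  D <- internode_matrix(pruned, allele_map, taxa,
                        override = setNames(.QUERY, allele),
                        missing_pairs = missing_pairs)
  scores <- .score_candidates(candidates, D$D)
  best <- min(scores)
  best_edges <- names(scores)[scores <= best + tol]

  loci <- if (!is.null(names(gene_trees))) names(gene_trees)[has_allele]
          else which(has_allele)
  row <- allele_map[allele_map$allele == allele, ]
  structure(list(allele = allele,
                 accession = row$accession,
                 species = row$species,
                 locus = paste(loci, collapse = ","),
                 best_edges = best_edges,
                 weight = 1 / length(best_edges),
                 best_score = best,
                 scores = scores),
            class = "mest_placement")
}

#' @export
print.mest_placement <- function(x, ...) {
  cat("Placement of allele", x$allele,
      "(", x$accession, "/", x$species, ")\n")
  cat("  best score", format(x$best_score), "on",
      length(x$best_edges), "edge(s), weight",
      format(x$weight), "each:\n")
  for (e in x$best_edges) cat("   ", e, "\n")
  invisible(x)
}

#' Place a set of polyploid alleles independently
#'
#' @inheritParams place_allele
#' @param alleles Alleles to place; defaults to every `polyploid-query`
#'   allele occurring in at least one gene tree.
#' @param on_error `"stop"` propagates per-allele errors; `"skip"` drops the
#'   failing allele with a warning.
#' @return List of `mest_placement` objects, one per placed allele.
#' @export
place_all <- function(backbone, gene_trees, allele_map, alleles = NULL,
                      candidates = NULL, tol = 1e-9,
                      missing_pairs = "strict",
                      on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (is.null(candidates)) candidates <- candidate_set(backbone)
  if (is.null(alleles)) {
    present <- unique(unlist(lapply(gene_trees, function(t) t$tip.label)))
    alleles <- allele_map$allele[allele_map$role == "polyploid-query" &
                                   allele_map$allele %in% present]
  }
  out <- list()
  for (a in alleles) {
    p <- if (on_error == "stop") {
      place_allele(backbone, gene_trees, allele_map, a,
                   candidates = candidates, tol = tol,
                   missing_pairs = missing_pairs)
    } else {
      tryCatch(place_allele(backbone, gene_trees, allele_map, a,
                            candidates = candidates, tol = tol,
                            missing_pairs = missing_pairs),
               error = function(e) {
                 warning("skipping allele '", a, "': ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    }
    if (!is.null(p)) out[[a]] <- p
  }
  out
}

#' Flatten placements to a table
#'
#' One row per (allele, best edge), with the tie weight and best score.
#'
#' @param placements List of `mest_placement` objects (from [place_all()]).
#' @return A `data.frame` with columns `allele`, `accession`, `species`,
#'   `locus`, `edge_id`, `weight`, `score`.
#' @export
placements_table <- function(placements) {
  if (length(placements) == 0)
    return(data.frame(allele = character(), accession = character(),
                      species = character(), locus = character(),
                      edge_id = character(), weight = numeric(),
                      score = numeric()))
  do.call(rbind, lapply(placements, function(p) {
    data.frame(allele = p$allele, accession = p$accession,
               species = p$species, locus = p$locus,
               edge_id = p$best_edges, weight = p$weight,
               score = p$best_score, row.names = NULL)
  }))
}

#' Representative allele of an accession within a gene-tree clade
#'
#' When several minor allelic variants of one accession fall in the same
#' clade of a gene tree, the representative is the one whose path to the
#' clade's root crosses the fewest internal nodes (lexicographically
#' smallest id on ties).
#'
#' @param gene_tree A rooted `phylo` gene tree.
#' @param alleles Allele leaf labels of one accession.
#' @param clade_root Internal node number defining the clade; defaults to
#'   the MRCA of `alleles`. All `alleles` must descend from it.
#' @return The representative allele label.
#' @export
select_representative_allele <- function(gene_tree, alleles,
                                         clade_root = NULL) {
  alleles <- sort(unique(alleles))
  missing <- setdiff(alleles, gene_tree$tip.label)
  if (length(missing) > 0)
    stop("allele(s) not in gene tree: ", paste(missing, collapse = ", "))
  if (length(alleles) == 1) return(alleles)
  n_tip <- length(gene_tree$tip.label)
  if (is.null(clade_root)) {
    clade_root <- ape::getMRCA(gene_tree, alleles)
    if (is.null(clade_root) || clade_root == n_tip + 1L)
      stop("alleles span multiple clades; representative rule does not apply")
  }
  below <- .clades_below(gene_tree)[[clade_root]]
  outside <- setdiff(alleles, below)
  if (length(outside) > 0)
    stop("alleles span multiple clades; representative rule does not apply")
  # internal nodes strictly between leaf and clade root = edges on path - 1
  depth <- vapply(alleles, function(a) {
    node <- match(a, gene_tree$tip.label)
    steps <- 0L
    while (node != clade_root) {
      node <- gene_tree$edge[gene_tree$edge[, 2] == node, 1]
      steps <- steps + 1L
    }
    steps - 1L
  }, integer(1))
  alleles[which.min(depth)]  # which.min takes the first, i.e. smallest id
}
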