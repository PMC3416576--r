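# NJst internode distances: the number of internal nodes on the path between
# two leaves of an unrooted gene tree, averaged over gene trees and over all
# cross pairs of individuals from the two taxa.

# Topological leaf-to-leaf distances (number of edges on the path) of an
# unrooted version of `tree`. Internode count = edge count - 1 because both
# path endpoints are leaves.
.topo_dist <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip == 2) {
    # a 2-leaf tree is a single edge once the degree-2 root is suppressed
    d <- matrix(c(0, 1, 1, 0), 2,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(d)
  }
  ur <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ur$edge.length <- rep(1, nrow(ur$edge))
  d <- ape::dist.nodes(ur)
  n <- length(ur$tip.label)
  d <- d[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(ur$tip.label, ur$tip.label)
  d
}

#' Internode count between two leaves
#'
#' Number of internal nodes on the unique path between two leaves, the tree
#' being treated as unrooted (a degree-2 root is suppressed first). Two
#' leaves forming a cherry are one internode apart. Polytomies are allowed;
#' internal nodes count regardless of degree.
#'
#' @param tree A `phylo` object.
#' @param leaf_a,leaf_b Leaf labels.
#' @return A non-negative integer.
#' @export
internode_count <- function(tree, leaf_a, leaf_b) {
  missing <- setdiff(c(leaf_a, leaf_b), tree$tip.label)
  if (length(missing) > 0)
    stop("leaf not in tree: ", paste(missing, collapse = ", "))
  if (leaf_a == leaf_b) return(0L)
  d <- .topo_dist(tree)
  as.integer(d[leaf_a, leaf_b] - 1)
}

#' Average internode distance matrix between taxa
#'
#' The NJst distance: for taxa `i`, `j`, the mean internode count over every
#' gene tree containing at least one individual of both taxa and every cross
#' pair of individuals, as one flat mean over all (tree, pair) terms.
#'
#' Gene-tree leaves are resolved to taxa through the allele map's `species`
#' column; `override` (allele id -> taxon name) takes precedence and is how a
#' single polyploid allele is treated as its own taxon. Counts are measured
#' on each gene tree exactly as given: leaves resolving to a taxon outside
#' `taxa` contribute no pair terms but still sit on paths and shape the
#' counts. Callers that want them gone must prune first — which is what the
#' placement engine does with non-focal polyploid alleles.
#'
#' @param gene_trees A list of `phylo` objects (or a `multiPhylo`).
#' @param allele_map An [allele_map()].
#' @param taxa Character vector of taxon names for the matrix.
#' @param override Named character vector mapping allele ids to taxon names.
#' @param missing_pairs `"strict"` leaves pairs with no contributing term as
#'   `NA` (downstream scoring errors on them); `"impute_max"` fills them with
#'   the matrix maximum, with a message.
#' @return An object of class `internode_dist`: list with `taxa`, `D`
#'   (average internode counts, `NA` where undefined), and `N` (number of
#'   contributing (tree, pair) terms).
#' @export
internode_matrix <- function(gene_trees, allele_map, taxa,
                             override = NULL,
                             missing_pairs = c("strict", "impute_max")) {
  missing_pairs <- match.arg(missing_pairs)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  taxa <- as.character(taxa)
  k <- length(taxa)
  S <- matrix(0, k, k, dimnames = list(taxa, taxa))
  N <- matrix(0L, k, k, dimnames = list(taxa, taxa))
  lookup <- setNames(allele_map$species, allele_map$allele)
  if (!is.null(override)) lookup[names(override)] <- override

  for (tr in gene_trees) {
    leaf_tax <- lookup[tr$tip.label]
    if (anyNA(leaf_tax))
      stop("gene-tree leaf not resolvable: ",
           paste(tr$tip.label[is.na(leaf_tax)], collapse = ", "))
    if (sum(leaf_tax %in% taxa) < 2) next
    d <- .topo_dist(tr) - 1
    ti <- match(lookup[rownames(d)], taxa)
    # vectorized accumulation over all cross pairs of individuals
    iu <- which(upper.tri(d), arr.ind = TRUE)
    ia <- ti[iu[, 1]]; ib <- ti[iu[, 2]]
    cross <- !is.na(ia) & !is.na(ib) & ia != ib
    if (!any(cross)) next
    key <- (pmin(ia, ib)[cross] - 1L) * k + pmax(ia, ib)[cross]
    sums <- rowsum(d[iu][cross], key)
    cnts <- rowsum(rep(1L, sum(cross)), key)
    kk <- as.integer(rownames(sums))
    idx <- cbind(((kk - 1L) %/% k) + 1L, ((kk - 1L) %% k) + 1L)
    S[idx] <- S[idx] + sums[, 1]
    N[idx] <- N[idx] + cnts[, 1]
  }
  S <- S + t(S)
  N <- N + t(N)
  D <- ifelse(N > 0, S / pmax(N, 1L), NA_real_)
  diag(D) <- 0
  diag(N) <- 0L
  if (missing_pairs == "impute_max" && anyNA(D)) {
    mx <- max(D, na.rm = TRUE)
    message("imputing ", sum(is.na(D[upper.tri(D)])),
            " undefined taxon pair(s) with matrix maximum ", mx)
    D[is.na(D)] <- mx
  }
  structure(list(taxa = taxa, D = D, N = N), class = "internode_dist")
}

#' @export
print.internode_dist <- function(x, ...) {
  cat("Internode distance matrix over", length(x$taxa), "taxa\n")
  undef <- sum(is.na(x$D[upper.tri(x$D)]))
  cat("contributing terms per pair: ",
      paste(range(x$N[upper.tri(x$N)]), collapse = "-"),
      "; undefined pairs: ", undef, "\n", sep = "")
  invisible(x)
}

#' Export a distance matrix as square TSV or PHYLIP
#'
#' @param x An `internode_dist` or a plain numeric matrix with dimnames.
#' @param file Output path.
#' @param format `"tsv"` (taxon header row and column) or `"phylip"`
#'   (square PHYLIP distance format).
#' @export
write_distance_matrix <- function(x, file, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  D <- if (inherits(x, "internode_dist")) x$D else x
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(D), D, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste0(formatC(rownames(D)[i], width = -10),
                        paste(sprintf("%.6f", D[i, ]), collapse = "  ")),
                 con)
    }
  }
  invisible(file)
}
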