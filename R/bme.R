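# Balanced minimum evolution (Pauplin) scoring of a fixed topology against a
# distance matrix, plus the oracles used to validate it: neighbor joining and
# exhaustive search over all unrooted binary topologies at small n.

#' Pauplin weights of a binary unrooted tree
#'
#' `w[i, j] = 2^(1 - tau_ij)` where `tau_ij` is the number of edges on the
#' leaf path from `i` to `j`. For every leaf of a binary unrooted tree the
#' off-diagonal row sum is exactly 1.
#'
#' @param tree A `phylo` object; must be binary once unrooted.
#' @return Symmetric numeric matrix with zero diagonal, leaf labels as
#'   dimnames.
#' @export
pauplin_weights <- function(tree) {
  ur <- ape::unroot(tree)
  if (!ape::is.binary(ur))
    stop("Pauplin weights require a binary unrooted tree")
  if (length(ur$tip.label) < 3) stop("need at least 3 leaves")
  tau <- .topo_dist(ur)
  w <- 2^(1 - tau)
  diag(w) <- 0
  w
}

#' Balanced minimum evolution length of a tree under a distance matrix
#'
#' `l(T) = sum_{i<j} w[i, j] * D[i, j]` with Pauplin weights `w`. When `D` is
#' the additive (path-length) matrix of the tree itself, `l(T)` equals the
#' total branch length. Terms are accumulated in sorted leaf-pair order so
#' that exact rational ties are reproduced bit-for-bit across edge
#' enumeration orders.
#'
#' @param tree A `phylo` object, binary once unrooted.
#' @param D An [internode_matrix()] result or a symmetric numeric matrix with
#'   leaf labels as dimnames; must cover every leaf pair of `tree`.
#' @return The scalar tree length estimate.
#' @export
bme_length <- function(tree, D) {
  if (inherits(D, "internode_dist")) D <- D$D
  labs <- sort(tree$tip.label)
  missing <- setdiff(labs, rownames(D))
  if (length(missing) > 0)
    stop("distance matrix missing taxa: ", paste(missing, collapse = ", "))
  Dl <- D[labs, labs]
  ut <- upper.tri(Dl)
  if (anyNA(Dl[ut]))
    stop("undefined distance for pair(s): ",
         paste(utils::head(apply(which(is.na(Dl) & ut, arr.ind = TRUE), 1,
                    function(ij) paste(labs[ij], collapse = "-")), 5),
               collapse = ", "))
  w <- pauplin_weights(tree)[labs, labs]
  sum(w[ut] * Dl[ut])
}

#' Neighbor joining on an internode distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); used as the greedy
#' balanced-ME baseline and consistency oracle.
#'
#' @param D An `internode_dist` or symmetric matrix; must be fully defined.
#' @return An unrooted binary `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "internode_dist")) D <- D$D
  if (anyNA(D[upper.tri(D)]))
    stop("neighbor joining requires a fully defined distance matrix")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  ape::nj(stats::as.dist(D))
}

#' Exhaustive balanced-ME search over all unrooted binary topologies
#'
#' Enumerates all `(2n - 5)!!` topologies by stepwise leaf addition and
#' returns every topology attaining the minimal [bme_length()] (ties within
#' `tol`). A test oracle: refuse `n > max_n`.
#'
#' @param D An `internode_dist` or symmetric matrix covering `taxa`.
#' @param taxa Taxa to place; defaults to the rows of `D`.
#' @param max_n Hard cap on the number of taxa (default 8).
#' @param tol Absolute tie tolerance on scores (default 1e-9).
#' @return List with `best_trees` (list of `phylo`), `best_score`,
#'   and `n_topologies` enumerated.
#' @export
exhaustive_bme <- function(D, taxa = NULL, max_n = 8, tol = 1e-9) {
  if (inherits(D, "internode_dist")) D <- D$D
  if (is.null(taxa)) taxa <- rownames(D)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  if (n > max_n) stop("n = ", n, " exceeds max_n = ", max_n)
  base <- ape::read.tree(text = paste0("(", taxa[1], ",", taxa[2], ",",
                                       taxa[3], ");"))
  trees <- list(base)
  if (n > 3) {
    for (k in seq(4, n)) {
      trees <- unlist(lapply(trees, function(tr) {
        lapply(seq_len(nrow(tr$edge)), function(e)
          .graft_edge(tr, e, taxa[k]))
      }), recursive = FALSE)
    }
  }
  scores <- vapply(trees, bme_length, numeric(1), D = D)
  best <- min(scores)
  keep <- which(scores <= best + tol)
  list(best_trees = trees[keep],
       best_score = best,
       n_topologies = length(trees))
}
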