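# -- Newick I/O ---------------------------------------------------------------

#' Read trees from a Newick file or string
#'
#' Thin wrapper around [ape::read.tree()] that adds early syntax diagnostics
#' (byte offset of the first unbalanced parenthesis) and rejects duplicate
#' leaf labels, which silently corrupt distance averaging downstream.
#'
#' @param file Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string(s); overrides `file`.
#' @param multi If `TRUE`, always return a list of trees (class `multiPhylo`)
#'   in file order, even for a single tree.
#' @return A `phylo` object, or a `multiPhylo` list when the input holds
#'   several trees or `multi = TRUE`.
#' @export
read_newick <- function(file = NULL, text = NULL, multi = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  .check_newick_syntax(text)
  trees <- ape::read.tree(text = text)
  if (is.null(trees)) stop("Newick parse failure: no tree found")
  tl <- if (inherits(trees, "phylo")) list(trees) else trees
  for (tr in tl) {
    dup <- tr$tip.label[duplicated(tr$tip.label)]
    if (length(dup) > 0)
      stop("duplicate leaf label: ", paste(unique(dup), collapse = ", "))
  }
  if (multi && inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  trees
}

# Balanced-parenthesis scan; reports the byte offset of the first mismatch.
.check_newick_syntax <- function(text) {
  chars <- charToRaw(text)
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == charToRaw("(")) depth <- depth + 1L
    if (ch == charToRaw(")")) {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse failure at byte offset ", i,
             ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("Newick parse failure at byte offset ", length(chars),
         ": ", depth, " unclosed '('")
  invisible(TRUE)
}

#' Write trees to Newick
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Output path; when `NULL` the Newick string(s) are returned.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# -- Pruning ------------------------------------------------------------------

#' Restrict a tree to a set of leaves
#'
#' Degree-2 nodes created by the removal are suppressed and branch lengths
#' along suppressed paths are summed (via [ape::keep.tip()]).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain, `length >= 2`.
#' @return The induced `phylo` tree on `keep`.
#' @export
prune_leaves <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("'keep' must contain at least 2 labels")
  ape::keep.tip(tree, keep)
}

# -- Edge identifiers ---------------------------------------------------------

# Leaf set below each node of a rooted tree, as a list indexed by node id.
.clades_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  below <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    c <- tr$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  lapply(below, sort)
}

.fingerprint <- function(labels) paste(sort(labels), collapse = "|")

#' Enumerate the unrooted edges of a rooted backbone tree
#'
#' Each edge is identified by the sorted leaf set below its child node in the
#' rooted input, joined with `"|"`. The two edges incident to the root are the
#' same unrooted edge and are merged into a single identifier, taken from the
#' root child with the smaller clade (lexicographic fingerprint on ties).
#' Order follows the postorder traversal of the rooted input, so identifiers
#' are stable across runs.
#'
#' @param backbone A rooted `phylo` tree, binary after unrooting.
#' @param allow_nonbinary Resolve multifurcations arbitrarily (with a warning)
#'   instead of refusing. Candidate enumeration and Pauplin weights assume a
#'   binary tree, so this is off by default.
#' @return Character vector of edge identifiers, length `2n - 3`.
#' @export
enumerate_edges <- function(backbone, allow_nonbinary = FALSE) {
  backbone <- .ensure_binary(backbone, allow_nonbinary)
  n_tip <- length(backbone$tip.label)
  root <- n_tip + 1L
  below <- .clades_below(backbone)
  tr <- ape::reorder.phylo(backbone, "postorder")
  root_children <- tr$edge[tr$edge[, 1] == root, 2]
  if (n_tip >= 3 && length(root_children) == 2) {
    sizes <- lengths(below[root_children])
    fps <- vapply(below[root_children], .fingerprint, character(1))
    pick <- if (sizes[1] != sizes[2]) which.min(sizes) else which.min(rank(fps))
    drop_child <- root_children[-pick]
  } else {
    drop_child <- integer(0)
  }
  ids <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2]
    if (child %in% drop_child) next
    ids <- c(ids, .fingerprint(below[[child]]))
  }
  ids
}

.ensure_binary <- function(tree, allow_nonbinary = FALSE) {
  if (ape::is.binary(ape::unroot(tree))) return(tree)
  if (!allow_nonbinary)
    stop("backbone is not binary (after unrooting); ",
         "set allow_nonbinary = TRUE to resolve polytomies arbitrarily")
  warning("backbone polytomies resolved arbitrarily; ",
          "candidate enumeration assumes a binary tree")
  ape::multi2di(tree)
}

# Map each EdgeId to the matching edge row of an unrooted version of the
# backbone. Matching is by bipartition: the leaf set below the edge's child
# equals the fingerprint set or its complement.
.edge_rows <- function(unrooted, edge_ids) {
  all_leaves <- sort(unrooted$tip.label)
  below <- .clades_below(unrooted)  # treats basal node as root; fine for sets
  fp_below <- vapply(seq_len(nrow(unrooted$edge)), function(k) {
    .fingerprint(below[[unrooted$edge[k, 2]]])
  }, character(1))
  fp_above <- vapply(seq_len(nrow(unrooted$edge)), function(k) {
    .fingerprint(setdiff(all_leaves, below[[unrooted$edge[k, 2]]]))
  }, character(1))
  rows <- vapply(edge_ids, function(id) {
    hit <- which(fp_below == id | fp_above == id)
    if (length(hit) != 1)
      stop("unknown EdgeId: ", id)
    hit
  }, integer(1))
  rows
}

# -- Grafting -----------------------------------------------------------------

# Subdivide edge row `iedge` of a phylo tree with a new internal node and
# attach a new leaf there. Purely topological: branch lengths are dropped.
.graft_edge <- function(tree, iedge, new_label) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  # shift node ids to make room for the new tip (id n_tip + 1)
  edge[edge > n_tip] <- edge[edge > n_tip] + 1L
  new_tip <- n_tip + 1L
  new_node <- n_tip + 1L + n_node + 1L
  p <- edge[iedge, 1]
  c <- edge[iedge, 2]
  edge <- edge[-iedge, , drop = FALSE]
  edge <- rbind(edge,
                c(p, new_node),
                c(new_node, c),
                c(new_node, new_tip))
  out <- list(edge = edge,
              tip.label = c(tree$tip.label, new_label),
              Nnode = n_node + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Graft a new leaf onto a backbone edge
#'
#' Returns the unrooted tree in which `new_label` is attached by a new node
#' subdividing the chosen edge. By construction the induced subtree on the
#' original leaves equals the backbone (the subtree constraint of the
#' placement search).
#'
#' @param backbone A rooted (or unrooted) `phylo` tree, binary after
#'   unrooting.
#' @param edge An edge identifier from [enumerate_edges()].
#' @param new_label Leaf label to attach; must not already be present.
#' @return An unrooted `phylo` tree with `n + 1` leaves, without branch
#'   lengths (the placement machinery is purely topological).
#' @export
graft_leaf <- function(backbone, edge, new_label) {
  if (new_label %in% backbone$tip.label)
    stop("leaf '", new_label, "' already present")
  ur <- ape::unroot(backbone)
  ur$edge.length <- NULL
  row <- .edge_rows(ur, edge)
  .graft_edge(ur, row, new_label)
}

# All 2n-3 graftings at once, as a named list keyed by EdgeId.
.graft_all <- function(backbone, new_label, edge_ids = NULL) {
  if (is.null(edge_ids)) edge_ids <- enumerate_edges(backbone)
  ur <- ape::unroot(backbone)
  ur$edge.length <- NULL
  rows <- .edge_rows(ur, edge_ids)
  out <- lapply(rows, function(r) .graft_edge(ur, r, new_label))
  names(out) <- edge_ids
  out
}

# -- Allele map ---------------------------------------------------------------

.allele_roles <- c("backbone-diploid", "polyploid-query", "outgroup")

#' Read an allele map
#'
#' Four-column tab-separated table with header
#' `allele\taccession\tspecies\trole`, mapping every gene-tree leaf to its
#' accession, species and role (`backbone-diploid`, `polyploid-query`, or
#' `outgroup`).
#'
#' @param file Path to the TSV file.
#' @return A validated `data.frame` of class `allele_map`.
#' @export
read_allele_map <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  allele_map(df)
}

#' Construct and validate an allele map
#'
#' @param df Data frame with columns `allele`, `accession`, `species`, `role`.
#' @export
allele_map <- function(df) {
  need <- c("allele", "accession", "species", "role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("allele map missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(lapply(df[need], function(x) trimws(as.character(x))),
                      stringsAsFactors = FALSE)
  dup <- df$allele[duplicated(df$allele)]
  if (length(dup) > 0)
    stop("duplicate allele id(s) in allele map: ",
         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$role), .allele_roles)
  if (length(bad) > 0)
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.allele_roles, collapse = ", "), ")")
  class(df) <- c("allele_map", "data.frame")
  df
}

#' Write an allele map to TSV
#' @param map An `allele_map`.
#' @param file Output path.
#' @export
write_allele_map <- function(map, file) {
  utils::write.table(map, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Cross-check an allele map against a backbone and a set of gene trees:
# every gene-tree leaf must resolve, and every backbone leaf must be a
# species of role backbone-diploid or outgroup.
.validate_inputs <- function(backbone, gene_trees, map) {
  leaves <- unique(unlist(lapply(gene_trees, function(t) t$tip.label)))
  unresolved <- setdiff(leaves, map$allele)
  if (length(unresolved) > 0)
    stop("gene-tree leaf not in allele map: ",
         paste(utils::head(unresolved, 5), collapse = ", "))
  backbone_species <- map$species[map$role %in% c("backbone-diploid", "outgroup")]
  orphan <- setdiff(backbone$tip.label, backbone_species)
  if (length(orphan) > 0)
    stop("backbone leaf without backbone-diploid/outgroup species entry: ",
         paste(orphan, collapse = ", "))
  invisible(TRUE)
}
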