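# Bootstrap orchestration and summarization: re-place every allele on each
# replicate gene-tree set, then summarize per edge and per clade the support
# for at least one allele of parental origin there, the median allele count,
# and a trimmed 90% bootstrap confidence interval.

#' Define clades on the backbone
#'
#' @param members Named list: clade name -> character vector of member
#'   species (backbone leaf labels). Clades need not be disjoint.
#' @param include_stem Count the clade's stem edge as within the clade
#'   (default `TRUE`: an origin on the stem is indistinguishable from an
#'   origin inside the clade at this grain).
#' @return An object of class `clade_defs`.
#' @export
clade_defs <- function(members, include_stem = TRUE) {
  stopifnot(is.list(members), !is.null(names(members)))
  structure(list(members = lapply(members, sort),
                 include_stem = include_stem),
            class = "clade_defs")
}

#' Read clade definitions from a two-column TSV (`clade`, `species`)
#' @param file Path to the TSV.
#' @param include_stem See [clade_defs()].
#' @export
read_clades <- function(file, include_stem = TRUE) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("clade", "species") %in% names(df)))
    stop("clade file needs columns 'clade' and 'species'")
  clade_defs(split(df$species, df$clade), include_stem = include_stem)
}

# Edge ids of the backbone lying within each clade. An edge is within a
# clade when the leaf set below it (its fingerprint) is a subset of the
# clade members; the stem edge is the one whose set equals the members.
.clade_edge_sets <- function(edge_ids, clades) {
  lapply(clades$members, function(mem) {
    keep <- vapply(strsplit(edge_ids, "|", fixed = TRUE), function(lv) {
      all(lv %in% mem) && (clades$include_stem || length(lv) < length(mem))
    }, logical(1))
    edge_ids[keep]
  })
}

#' Run the placement pipeline over bootstrap replicates
#'
#' Each replicate supplies one gene tree per locus; [place_all()] is run per
#' replicate and the per-allele edge weights retained. Per replicate the
#' edge weights of each allele sum to 1, so total edge weight equals the
#' number of alleles placed (asserted).
#'
#' @param backbone Rooted binary `phylo` backbone.
#' @param replicate_sets List of length `R`; each element a list of `phylo`
#'   gene trees, one per locus (named by locus).
#' @param allele_map An [allele_map()].
#' @param alleles Optional subset of alleles to place.
#' @param tol,missing_pairs,on_error Passed to [place_all()].
#' @return Object of class `mest_replicates`: per-replicate placement
#'   details plus the backbone edge ids.
#' @export
run_bootstrap <- function(backbone, replicate_sets, allele_map,
                          alleles = NULL, tol = 1e-9,
                          missing_pairs = "strict",
                          on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  cand <- candidate_set(backbone)
  n_loci <- unique(lengths(replicate_sets))
  if (length(n_loci) != 1)
    stop("replicates disagree on the number of loci: ",
         paste(n_loci, collapse = ", "))
  detail <- vector("list", length(replicate_sets))
  for (r in seq_along(replicate_sets)) {
    pl <- place_all(backbone, replicate_sets[[r]], allele_map,
                    alleles = alleles, candidates = cand, tol = tol,
                    missing_pairs = missing_pairs, on_error = on_error)
    tab <- placements_table(pl)
    total <- sum(tab$weight)
    if (abs(total - length(pl)) > 1e-9)
      stop("conservation violated in replicate ", r, ": edge weights sum to ",
           total, " for ", length(pl), " alleles")
    detail[[r]] <- tab
  }
  structure(list(edge_ids = cand$edge_ids,
                 backbone = backbone,
                 detail = detail,
                 R = length(replicate_sets)),
            class = "mest_replicates")
}

# Per-replicate per-edge (or per-clade) allele-weight totals and presence
# flags, from one replicate's placement table.
.replicate_counts <- function(tab, edge_ids, clade_edges) {
  ecount <- setNames(numeric(length(edge_ids)), edge_ids)
  s <- rowsum(tab$weight, tab$edge_id)
  ecount[rownames(s)] <- s[, 1]
  epresent <- setNames(logical(length(edge_ids)), edge_ids)
  epresent[unique(tab$edge_id)] <- TRUE
  ccount <- vapply(clade_edges, function(es) sum(ecount[es]), numeric(1))
  cpresent <- vapply(clade_edges, function(es) any(epresent[es]), logical(1))
  list(ecount = ecount, epresent = epresent,
       ccount = ccount, cpresent = cpresent)
}

# Trimmed 90% bootstrap interval: drop floor(0.05 R) smallest and largest.
.ci90 <- function(x) {
  k <- floor(0.05 * length(x))
  s <- unname(sort(x))
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  c(lo = s[1], hi = s[length(s)])
}

#' Summarize bootstrap placements per edge and per clade
#'
#' For each edge (and clade): the bootstrap support for at least one allele
#' having a parental origin there, the median allele count over replicates,
#' and the 90% confidence interval obtained by excluding the 5% lowest and
#' 5% highest replicate counts.
#'
#' @param replicates A `mest_replicates` object from [run_bootstrap()].
#' @param clades Optional [clade_defs()].
#' @param support_rule `"presence"` (default): a replicate supports an edge
#'   if any allele assigns it positive weight. `"weight_ge_1"`: requires the
#'   summed fractional weight to reach 1.
#' @param alleles Optional allele subset (used by the per-accession rerun).
#' @return `data.frame` with columns `scope` (`edge`/`clade`), `id`,
#'   `support_pct`, `median`, `ci_lo`, `ci_hi`.
#' @export
summarize_bootstrap <- function(replicates, clades = NULL,
                                support_rule = c("presence", "weight_ge_1"),
                                alleles = NULL) {
  support_rule <- match.arg(support_rule)
  edge_ids <- replicates$edge_ids
  clade_edges <- if (is.null(clades)) list() else
    .clade_edge_sets(edge_ids, clades)
  R <- replicates$R
  per <- lapply(replicates$detail, function(tab) {
    if (!is.null(alleles)) tab <- tab[tab$allele %in% alleles, , drop = FALSE]
    .replicate_counts(tab, edge_ids, clade_edges)
  })
  ecounts <- do.call(rbind, lapply(per, `[[`, "ecount"))
  ccounts <- do.call(rbind, lapply(per, `[[`, "ccount"))
  efire <- if (support_rule == "presence")
    do.call(rbind, lapply(per, `[[`, "epresent")) else ecounts >= 1
  cfire <- if (support_rule == "presence")
    do.call(rbind, lapply(per, `[[`, "cpresent")) else ccounts >= 1

  one <- function(scope, id, counts, fires) {
    ci <- .ci90(counts)
    data.frame(scope = scope, id = id,
               support_pct = 100 * sum(fires) / R,
               median = stats::median(counts),
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               row.names = NULL)
  }
  out <- do.call(rbind, c(
    lapply(seq_along(edge_ids), function(i)
      one("edge", edge_ids[i], ecounts[, i], efire[, i])),
    if (length(clade_edges) > 0)
      lapply(seq_along(clade_edges), function(i)
        one("clade", names(clade_edges)[i], ccounts[, i], cfire[, i]))
  ))
  out
}

#' Per-accession bootstrap summaries
#'
#' Reruns the summarization after partitioning the placed alleles by
#' accession, to check whether accessions contribute equally to the pooled
#' placements. Per replicate, accession counts add up to the pooled counts.
#'
#' @inheritParams summarize_bootstrap
#' @param allele_map The [allele_map()] used for the run.
#' @return Named list of summary `data.frame`s, one per accession.
#' @export
per_accession_summaries <- function(replicates, allele_map, clades = NULL,
                                    support_rule = "presence") {
  placed <- unique(unlist(lapply(replicates$detail, function(t) t$allele)))
  acc_of <- setNames(allele_map$accession, allele_map$allele)
  groups <- split(placed, acc_of[placed])
  if (length(groups) == 0) {
    warning("no placed alleles; empty per-accession summary")
    return(list())
  }
  lapply(groups, function(as)
    summarize_bootstrap(replicates, clades = clades,
                        support_rule = support_rule, alleles = as))
}

# -- Rendering ----------------------------------------------------------------

.star_class <- function(support, thresholds) {
  ifelse(support >= thresholds$double_star, "**",
         ifelse(support >= thresholds$star, "*", ""))
}

# Recursive Newick writer that appends [&support=..] comments on the edges
# named in `ann` (a named character vector EdgeId -> comment).
.annotated_newick <- function(backbone, ann) {
  below <- .clades_below(backbone)
  n_tip <- length(backbone$tip.label)
  kids <- split(backbone$edge[, 2], backbone$edge[, 1])
  rec <- function(node) {
    lab <- if (node <= n_tip) backbone$tip.label[node] else
      paste0("(", paste(vapply(kids[[as.character(node)]], rec,
                               character(1)), collapse = ","), ")")
    fp <- .fingerprint(below[[node]])
    if (!is.na(ann[fp])) lab <- paste0(lab, ann[fp])
    lab
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Render a bootstrap summary as annotated Newick, table and clade bars
#'
#' Edges whose support reaches the display threshold are annotated on the
#' backbone Newick with support, median and CI; supports in the star band
#' get `*`, in the double-star band `**`. Clades passing the display
#' threshold while no single member edge does are reported separately (the
#' "vertical bar spanning the whole clade" of the figure convention).
#'
#' @param backbone The rooted backbone `phylo`.
#' @param summary Output of [summarize_bootstrap()].
#' @param clades The [clade_defs()] used for the summary, needed to decide
#'   which displayed clades lack a displayed member edge.
#' @param thresholds List with `display`, `star`, `double_star` support
#'   percentages (defaults 70 / 90 / 95).
#' @return List with `newick` (annotated string), `table` (the summary with
#'   `class` and `displayed` columns), and `clade_bars` (clade rows drawn as
#'   whole-clade bars).
#' @export
render_summary <- function(backbone, summary, clades = NULL,
                           thresholds = list(display = 70, star = 90,
                                             double_star = 95)) {
  summary$class <- .star_class(summary$support_pct, thresholds)
  summary$displayed <- summary$support_pct >= thresholds$display
  edges <- summary[summary$scope == "edge", , drop = FALSE]
  shown <- edges[edges$displayed, , drop = FALSE]
  ann <- setNames(rep(NA_character_, nrow(edges)), edges$id)
  if (nrow(shown) > 0)
    ann[shown$id] <- sprintf("[&support=%g%s,median=%g,ci=%g-%g]",
                             shown$support_pct, shown$class, shown$median,
                             shown$ci_lo, shown$ci_hi)
  crows <- summary[summary$scope == "clade" & summary$displayed, ,
                   drop = FALSE]
  if (nrow(crows) > 0 && !is.null(clades)) {
    member <- .clade_edge_sets(edges$id, clades)
    bar <- vapply(crows$id, function(cn)
      !any(shown$id %in% member[[cn]]), logical(1))
    bars <- crows[bar, , drop = FALSE]
  } else {
    bars <- crows[0, , drop = FALSE]
  }
  list(newick = .annotated_newick(backbone, ann),
       table = summary,
       clade_bars = bars)
}
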