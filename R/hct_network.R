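HCT_NODE_TYPES <- c("formula", "disease", "herb", "compound", "target")
HCT_EDGE_TYPES <- c("disease_target", "formula_herb", "herb_compound",
                    "compound_target")

#' Build the disease-herb-compound-target network
#'
#' Typed network linking a formula node to its herbs, herbs to their
#' screened compounds, compounds to their predicted targets (restricted
#' to a core target set, e.g. the PPI hub genes or the disease
#' intersection), and a disease node to every core target.  A compound
#' with no herb assignment is a fatal error; compounds keep their herb
#' edge even when none of their targets survive the core restriction.
#'
#' @param herb_compound_map `data.frame` with columns `herb_source` and
#'   `compound` (compound name or id) covering every compound in
#'   `compound_target_links`.
#' @param compound_target_links `data.frame` with columns `compound`
#'   and `gene` (normalized), one row per predicted link; restrict to
#'   screened passers before calling.
#' @param core_targets `gene_set` or character vector of core targets
#'   (non-empty).
#' @param disease_label name of the disease node.
#' @param formula_label name of the formula node.
#' @return an object of class `hct_network`: list with `nodes`
#'   (`data.frame` name/type) and `edges` (`data.frame` from/to/type).
#' @export
build_hct <- function(herb_compound_map, compound_target_links,
                      core_targets, disease_label = "disease",
                      formula_label = "formula") {
  core <- if (inherits(core_targets, "gene_set")) core_targets$genes else
    sort(unique(toupper(core_targets)))
  if (!length(core)) stop("core target set is empty")
  stopifnot(all(c("herb_source", "compound") %in% names(herb_compound_map)),
            all(c("compound", "gene") %in% names(compound_target_links)))
  compounds <- sort(unique(c(herb_compound_map$compound,
                             compound_target_links$compound)))
  unassigned <- setdiff(compounds, herb_compound_map$compound)
  if (length(unassigned)) {
    stop("compound(s) without a herb assignment: ",
         paste(unassigned, collapse = ", "))
  }
  herbs <- sort(unique(herb_compound_map$herb_source))
  ct <- unique(compound_target_links[, c("compound", "gene")])
  ct$gene <- toupper(ct$gene)
  ct <- ct[ct$gene %in% core, , drop = FALSE]
  nodes <- rbind(
    data.frame(name = formula_label, type = "formula"),
    data.frame(name = disease_label, type = "disease"),
    data.frame(name = herbs, type = "herb"),
    data.frame(name = compounds, type = "compound"),
    data.frame(name = core, type = "target"))
  hc <- unique(herb_compound_map[, c("herb_source", "compound")])
  edges <- rbind(
    data.frame(from = disease_label, to = core, type = "disease_target"),
    data.frame(from = formula_label, to = herbs, type = "formula_herb"),
    data.frame(from = hc$herb_source, to = hc$compound, type = "herb_compound"),
    if (nrow(ct)) data.frame(from = ct$compound, to = ct$gene,
                             type = "compound_target"))
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "hct_network")
}

#' @export
print.hct_network <- function(x, ...) {
  tn <- table(x$nodes$type)
  te <- table(x$edges$type)
  cat("<hct_network> ", nrow(x$nodes), " nodes (",
      paste(names(tn), tn, sep = ":", collapse = ", "), "), ",
      nrow(x$edges), " edges (",
      paste(names(te), te, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Rank compounds by degree and select main active compounds
#'
#' Computes each compound's degree in the herb-compound-target network
#' and selects the compounds with degree strictly above the cohort
#' median (even counts use the mean of the two central order
#' statistics).  Compounds sitting exactly at the median are flagged in
#' `at_median` rather than selected.  Raising the median can only
#' shrink the selection.
#'
#' @param network an `hct_network`.
#' @param degree_scope `"target_edges_only"` (default: a compound's
#'   degree counts its compound-target edges, i.e. its connectivity to
#'   the core targets) or `"all_edges"` (herb-compound edges count
#'   too).  Published rank tables are consistent with the
#'   target-only reading; both are exported for auditing.
#' @return an object of class `compound_degree_rank` (see
#'   [rank_compound_degrees()]).
#' @export
compound_degree_rank <- function(network,
                                 degree_scope = c("target_edges_only",
                                                  "all_edges")) {
  degree_scope <- match.arg(degree_scope)
  stopifnot(inherits(network, "hct_network"))
  compounds <- network$nodes$name[network$nodes$type == "compound"]
  if (!length(compounds)) stop("network contains no compounds")
  e <- network$edges
  keep_types <- if (degree_scope == "target_edges_only") "compound_target"
    else c("compound_target", "herb_compound")
  e <- e[e$type %in% keep_types, , drop = FALSE]
  incident <- c(e$from, e$to)
  deg <- vapply(compounds, function(cp) sum(incident == cp), integer(1))
  rank_compound_degrees(deg, degree_scope = degree_scope)
}

#' Rank a named vector of compound degrees
#'
#' The median-rule selection on its own: useful when the degrees come
#' from an externally produced rank table rather than from
#' [build_hct()].
#'
#' @param degrees named integer vector (compound -> degree).
#' @param degree_scope bookkeeping tag for the scope used.
#' @return an object of class `compound_degree_rank`: list with
#'   `ranking` (`data.frame` name/degree sorted by degree descending,
#'   ties by name), `median_degree`, `selected` (names strictly above
#'   the median) and `at_median` (names exactly at it).
#' @export
rank_compound_degrees <- function(degrees, degree_scope = "external") {
  stopifnot(length(degrees) >= 1L, !is.null(names(degrees)))
  ranking <- data.frame(name = names(degrees),
                        degree = as.numeric(degrees),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$degree, ranking$name), , drop = FALSE]
  rownames(ranking) <- NULL
  med <- stats::median(ranking$degree)
  structure(list(ranking = ranking,
                 median_degree = med,
                 selected = ranking$name[ranking$degree > med],
                 at_median = ranking$name[ranking$degree == med],
                 degree_scope = degree_scope),
            class = "compound_degree_rank")
}

#' @export
print.compound_degree_rank <- function(x, ...) {
  cat("<compound_degree_rank> ", nrow(x$ranking), " compounds, median ",
      x$median_degree, "; ", length(x$selected),
      " strictly above the median\n", sep = "")
  invisible(x)
}

#' Restrict an HCT network to a compound subset
#'
#' Removes compounds outside the subset together with their exclusive
#' edges.  Core targets left without any incident compound edge stay in
#' the network (their disease link remains) but are flagged in
#' `orphaned_targets` for downstream re-intersection.
#'
#' @param network an `hct_network`.
#' @param compound_subset non-empty character vector of compound names,
#'   all present in the network.
#' @return an `hct_network` with an extra element `orphaned_targets`.
#' @export
subset_network <- function(network, compound_subset) {
  stopifnot(inherits(network, "hct_network"))
  if (!length(compound_subset)) stop("compound subset is empty")
  compounds <- network$nodes$name[network$nodes$type == "compound"]
  unknown <- setdiff(compound_subset, compounds)
  if (length(unknown)) {
    stop("unknown compound(s) in subset: ", paste(unknown, collapse = ", "))
  }
  drop <- setdiff(compounds, compound_subset)
  nodes <- network$nodes[!(network$nodes$type == "compound" &
                             network$nodes$name %in% drop), , drop = FALSE]
  e <- network$edges
  e <- e[!(e$type == "herb_compound" & e$to %in% drop), , drop = FALSE]
  e <- e[!(e$type == "compound_target" & e$from %in% drop), , drop = FALSE]
  targets <- nodes$name[nodes$type == "target"]
  still_hit <- unique(e$to[e$type == "compound_target"])
  rownames(nodes) <- rownames(e) <- NULL
  out <- structure(list(nodes = nodes, edges = e), class = "hct_network")
  out$orphaned_targets <- sort(setdiff(targets, still_hit))
  out
}

#' Export an HCT network with node types
#'
#' Writes the edge list (SIF or TSV with an edge-type column) plus a
#' node-attribute TSV carrying the node `type`.
#'
#' @param network an `hct_network`.
#' @param path output path for the edge file.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_hct_network <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "hct_network"))
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste(network$edges$from, network$edges$type,
                     network$edges$to, sep = "\t"), path)
  }
  utils::write.table(network$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
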