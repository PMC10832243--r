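#' Induce a PPI subnetwork on a gene set
#'
#' Restricts the interaction network to a gene set of interest: the
#' node set is the full gene set (members absent from the PPI, or left
#' without qualifying interactions, are retained as degree-0 isolates
#' and counted separately), and the edges are those of the source
#' network with both endpoints in the set.
#'
#' @param ppi a [ppi_network()].
#' @param genes a `gene_set` or character vector (non-empty).
#' @return a `ppi_network` with an extra element `n_isolates`.
#' @export
induce_network <- function(ppi, genes) {
  stopifnot(inherits(ppi, "ppi_network"))
  members <- if (inherits(genes, "gene_set")) genes$genes else
    sort(unique(toupper(genes)))
  if (!length(members)) stop("cannot induce a network on an empty gene set")
  e <- ppi$edges
  e <- e[e$gene_a %in% members & e$gene_b %in% members, , drop = FALSE]
  out <- ppi_network(e, nodes = members, dialect = ppi$dialect)
  connected <- unique(c(out$edges$gene_a, out$edges$gene_b))
  out$n_isolates <- length(setdiff(out$nodes, connected))
  out
}

#' Node degree
#'
#' Neighbor count per node.  Two conventions are supported: `"simple"`
#' (the textbook neighbor count, satisfying the handshake lemma) and
#' `"doubled"` (twice the neighbor count).  Network viewers that import
#' undirected interactions as two directed arcs report the doubled
#' value, and published hub tables produced that way contain only even
#' degrees; the doubled convention reproduces such tables.
#'
#' @param network a `ppi_network`.
#' @param convention `"simple"` or `"doubled"`.
#' @return named integer vector over all nodes (isolates score 0).
#' @export
degree_centrality <- function(network, convention = c("simple", "doubled")) {
  convention <- match.arg(convention)
  g <- as_igraph(network)
  d <- igraph::degree(g, mode = "all", loops = FALSE)
  d <- d[network$nodes]
  if (convention == "doubled") d <- 2L * d
  stats::setNames(as.integer(d), network$nodes)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node,
#' normalized by `(n - 1)(n - 2) / 2` where `n` is the network size;
#' networks with fewer than three nodes score 0 everywhere.  Edges are
#' treated as unweighted.
#'
#' @param network a `ppi_network`.
#' @return named numeric vector in \[0, 1\] over all nodes.
#' @export
betweenness_centrality <- function(network) {
  n <- length(network$nodes)
  if (n < 3L) return(stats::setNames(rep(0, n), network$nodes))
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA,
                           normalized = TRUE)
  b <- b[network$nodes]
  b[!is.finite(b)] <- 0
  stats::setNames(as.numeric(b), network$nodes)
}

#' Closeness centrality
#'
#' For a node in a connected component of size `k >= 2`:
#' `(k - 1) / sum(d)` over its distances `d` to the other nodes of the
#' component (the within-component convention, keeping values in
#' \[0, 1\] on disconnected networks).  Isolates score 0.
#'
#' @param network a `ppi_network`.
#' @param component_policy only `"within_component"` is implemented;
#'   the argument records the convention explicitly.
#' @return named numeric vector in \[0, 1\] over all nodes.
#' @export
closeness_centrality <- function(network,
                                 component_policy = "within_component") {
  component_policy <- match.arg(component_policy, "within_component")
  n <- length(network$nodes)
  if (n == 0L) return(stats::setNames(numeric(), character()))
  g <- as_igraph(network)
  cl <- suppressWarnings(
    igraph::closeness(g, mode = "all", weights = NA, normalized = TRUE))
  cl <- cl[network$nodes]
  cl[!is.finite(cl)] <- 0
  stats::setNames(as.numeric(cl), network$nodes)
}

#' Per-node centrality table
#'
#' Computes the three topological measures used for hub selection for
#' every node of the network.
#'
#' @param network a `ppi_network`.
#' @param convention degree convention (see [degree_centrality()]);
#'   defaults to `"doubled"`, the convention of viewer-exported hub
#'   tables.
#' @return `data.frame` with columns `gene`, `degree`, `betweenness`,
#'   `closeness`, sorted by degree descending (ties by betweenness
#'   descending, then symbol).
#' @export
centrality_table <- function(network, convention = c("doubled", "simple")) {
  convention <- match.arg(convention)
  tab <- data.frame(
    gene = network$nodes,
    degree = degree_centrality(network, convention),
    betweenness = betweenness_centrality(network),
    closeness = closeness_centrality(network),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, -tab$betweenness, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Median cutoffs of a centrality table
#'
#' Per-measure median over the full pre-selection table (even counts
#' use the arithmetic mean of the two central order statistics, R's
#' default convention).
#'
#' @param table a centrality `data.frame` with columns `degree`,
#'   `betweenness`, `closeness`.
#' @return named list of the three medians.
#' @export
median_cutoffs <- function(table) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("cannot take medians of an empty centrality table")
  }
  list(degree = stats::median(table$degree),
       betweenness = stats::median(table$betweenness),
       closeness = stats::median(table$closeness))
}

#' Select hub genes by median cutoffs
#'
#' Hubs are the nodes exceeding (`strictness = "strict"`, the default)
#' or meeting (`"inclusive"`) the median cutoff on all three measures
#' simultaneously.  Under the strict policy the selection is always a
#' subset of the inclusive selection on the same table.  Output is
#' sorted by degree descending, ties by betweenness descending, then
#' symbol, for deterministic reports.
#'
#' @param table a centrality `data.frame` (see [centrality_table()]).
#' @param medians cutoffs, normally [median_cutoffs()] of the same
#'   table; passing cutoffs computed elsewhere is allowed for
#'   reproducing published tables.
#' @param strictness `"strict"` (`>`) or `"inclusive"` (`>=`).
#' @return an object of class `hub_selection`: list with `medians`,
#'   `strictness` and `hubs` (the selected rows).
#' @export
select_hub_genes <- function(table, medians = median_cutoffs(table),
                             strictness = c("strict", "inclusive")) {
  strictness <- match.arg(strictness)
  cmp <- if (strictness == "strict") `>` else `>=`
  keep <- cmp(table$degree, medians$degree) &
    cmp(table$betweenness, medians$betweenness) &
    cmp(table$closeness, medians$closeness)
  hubs <- table[keep, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, -hubs$betweenness, hubs$gene), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(medians = medians, strictness = strictness, hubs = hubs),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("<hub_selection> ", nrow(x$hubs), " hubs (", x$strictness,
      " cutoffs: degree ", x$medians$degree, ", betweenness ",
      signif(x$medians$betweenness, 5), ", closeness ",
      signif(x$medians$closeness, 5), ")\n", sep = "")
  invisible(x)
}

#' Write a hub selection as TSV plus JSON metadata
#'
#' @param selection a `hub_selection`.
#' @param path output TSV path; the medians and strictness go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_hub_selection <- function(selection, path) {
  stopifnot(inherits(selection, "hub_selection"))
  utils::write.table(selection$hubs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(medians = selection$medians, strictness = selection$strictness,
         n_hubs = nrow(selection$hubs)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
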