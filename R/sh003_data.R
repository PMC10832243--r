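#' Curated SH003 reference tables
#'
#' Small curated tables for the three-herb formula SH003 (Astragalus
#' membranaceus, AM; Angelica gigas, AG; Trichosanthes kirilowii
#' Maximowicz, TK) in the non-small cell lung cancer context, shipped
#' as plain TSV under `inst/extdata/`:
#'
#' * `sh003_active_compounds()` — the 20 orally active compounds with
#'   their PubChem CIDs and eight ADME properties (TCMSP-style values).
#' * `sh003_compound_degrees()` — the degree of each active compound in
#'   the herb-compound-target network.
#' * `sh003_hub_table("full")` — the 79-row centrality table (degree,
#'   betweenness, closeness; viewer-exported doubled degrees) of the
#'   hub genes selected from the full compound set.
#' * `sh003_hub_table("validated")` — the 64-row table for the four
#'   compounds detected in the extract by LC-MS (hispidulin, luteolin,
#'   baicalein, chrysoeriol).
#'
#' @return a `data.frame`.
#' @name sh003_data
NULL

sh003_extdata <- function(file) {
  path <- system.file("extdata", file, package = "netpharm")
  if (!nzchar(path)) stop("reference table '", file, "' not installed")
  path
}

#' @rdname sh003_data
#' @export
sh003_active_compounds <- function() {
  read_compound_table(sh003_extdata("sh003_active_compounds.tsv"))
}

#' @rdname sh003_data
#' @export
sh003_compound_degrees <- function() {
  utils::read.delim(sh003_extdata("sh003_compound_degrees.tsv"),
                    sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname sh003_data
#' @param which `"full"` for the 79-gene table of the full compound
#'   set, `"validated"` for the 64-gene table of the four
#'   extract-validated compounds.
#' @export
sh003_hub_table <- function(which = c("full", "validated")) {
  which <- match.arg(which)
  file <- if (which == "full") "sh003_hub_genes.tsv" else
    "sh003_hub_genes_4cpd.tsv"
  utils::read.delim(sh003_extdata(file), sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Published median cutoffs of the full SH003/NSCLC PPI analysis
#'
#' The median degree, betweenness and closeness of the 239-node induced
#' PPI network from which the 79 hub genes were selected.  The full
#' 239-row centrality table is not redistributable here, so these
#' cutoffs are shipped as constants for replaying the hub selection on
#' the curated hub table.
#'
#' @return named list with `degree`, `betweenness`, `closeness`.
#' @export
sh003_median_cutoffs <- function() {
  list(degree = 20, betweenness = 0.00156, closeness = 0.38889)
}
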