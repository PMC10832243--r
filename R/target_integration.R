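TARGET_SOURCES <- c("pharmmapper", "swisstarget", "stitch", "other")

#' Default per-source score thresholds for compound-target links
#'
#' Each prediction source reports a native confidence in \[0, 1\]
#' (PharmMapper normalized fit score, SwissTargetPrediction probability,
#' STITCH combined score).  The conventional high-confidence cutoff is
#' 0.7 on each scale, applied strictly (`score > threshold`).
#'
#' @return named numeric vector of thresholds.
#' @export
default_source_thresholds <- function() {
  c(pharmmapper = 0.7, swisstarget = 0.7, stitch = 0.7, other = 0.7)
}

#' Read a compound-target link table
#'
#' Tab-separated with columns `compound_id`, `gene_raw`, `source_db`
#' and `score` (source-native confidence in \[0, 1\]).
#'
#' @param path input path.
#' @return a `data.frame` of links.
#' @export
read_target_links <- function(path) {
  links <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("compound_id", "gene_raw", "source_db", "score")
  missing_cols <- setdiff(need, names(links))
  if (length(missing_cols)) {
    stop("link table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  links$compound_id <- as.character(links$compound_id)
  links$score <- as.numeric(links$score)
  validate_target_links(links)
  links[, need]
}

validate_target_links <- function(links) {
  bad_src <- setdiff(unique(links$source_db), TARGET_SOURCES)
  if (length(bad_src)) {
    stop("unknown source_db: ", paste(bad_src, collapse = ", "))
  }
  if (any(is.na(links$score)) || any(links$score < 0 | links$score > 1)) {
    stop("link scores must lie in [0, 1]")
  }
  invisible(links)
}

#' Aggregate compound targets across prediction sources
#'
#' Unions, over all sources, the targets of links whose score is
#' strictly above that source's threshold; symbols are normalized and
#' deduplicated.  Per-gene provenance (which sources contributed) is
#' kept, and the thresholded per-compound links are attached as
#' attribute `"links"` (with a normalized `gene` column) for the
#' herb-compound-target network stage, which needs compound-level
#' resolution that the flat gene set deliberately discards.
#'
#' Raising any threshold never adds genes (monotonicity).
#'
#' @param links link `data.frame` (see [read_target_links()]).
#' @param per_source_thresholds named numeric vector covering every
#'   `source_db` present; a link with an unknown source is fatal.
#' @param symbol_map optional alias table (see [read_symbol_map()]).
#' @return a [gene_set()] named `"formula_targets"`, with a
#'   `gene_sources` element (`data.frame` gene/source) and the filtered
#'   links in `attr(, "links")`.
#' @export
aggregate_targets <- function(links,
                              per_source_thresholds = default_source_thresholds(),
                              symbol_map = NULL) {
  validate_target_links(links)
  present <- unique(links$source_db)
  missing_thr <- setdiff(present, names(per_source_thresholds))
  if (length(missing_thr)) {
    stop("no threshold defined for source_db: ",
         paste(missing_thr, collapse = ", "))
  }
  keep <- links$score > per_source_thresholds[links$source_db]
  kept <- links[keep, , drop = FALSE]
  # per-link normalized symbol (gene-by-gene, not set-level)
  uniq <- unique(kept$gene_raw)
  mapped <- vapply(uniq, function(g) normalize_symbols(g, symbol_map)$symbols, "")
  kept$gene <- unname(mapped[match(kept$gene_raw, uniq)])
  gs <- gene_set(kept$gene, name = "formula_targets",
                 provenance = sort(unique(kept$source_db)))
  srcs <- unique(kept[, c("gene", "source_db")])
  gs$gene_sources <- srcs[order(srcs$gene, srcs$source_db), , drop = FALSE]
  rownames(gs$gene_sources) <- NULL
  rownames(kept) <- NULL
  attr(gs, "links") <- kept
  gs
}

#' Union disease gene lists from several databases
#'
#' Normalized union with per-source provenance; membership is
#' unweighted (a gene listed by any source is a disease gene).
#'
#' @param gene_lists named list of character vectors, one per source
#'   database.
#' @param symbol_map optional alias table.
#' @return a [gene_set()] named `"disease_genes"` with a `gene_sources`
#'   `data.frame`.
#' @export
union_disease_genes <- function(gene_lists, symbol_map = NULL) {
  stopifnot(is.list(gene_lists), length(gene_lists) >= 1L)
  if (is.null(names(gene_lists)) || any(!nzchar(names(gene_lists)))) {
    names(gene_lists) <- paste0("source", seq_along(gene_lists))
  }
  per_source <- lapply(gene_lists, function(g) normalize_symbols(g, symbol_map)$symbols)
  gs <- gene_set(unlist(per_source), name = "disease_genes",
                 provenance = names(gene_lists))
  gene_sources <- do.call(rbind, lapply(names(per_source), function(s) {
    if (!length(per_source[[s]])) return(NULL)
    data.frame(gene = per_source[[s]], source_db = s, stringsAsFactors = FALSE)
  }))
  if (is.null(gene_sources)) {
    gene_sources <- data.frame(gene = character(), source_db = character(),
                               stringsAsFactors = FALSE)
  }
  gs$gene_sources <- gene_sources[order(gene_sources$gene, gene_sources$source_db), ,
                                  drop = FALSE]
  rownames(gs$gene_sources) <- NULL
  gs
}

#' Intersect formula targets with disease genes
#'
#' The Venn intersection whose members are the putative disease targets
#' of the formula.  Commutative; members are sorted for deterministic
#' output.
#'
#' @param formula_targets a `gene_set` (or character vector) of
#'   compound targets.
#' @param disease_genes a `gene_set` (or character vector) of disease
#'   genes.
#' @return an object of class `venn_report`: list with `size_a`,
#'   `size_b`, `size_intersection` and `members_intersection` (a
#'   `gene_set`).
#' @export
intersect_targets <- function(formula_targets, disease_genes) {
  a <- if (inherits(formula_targets, "gene_set")) formula_targets$genes else
    sort(unique(toupper(formula_targets)))
  b <- if (inherits(disease_genes, "gene_set")) disease_genes$genes else
    sort(unique(toupper(disease_genes)))
  members <- sort(intersect(a, b))
  report <- structure(
    list(size_a = length(a), size_b = length(b),
         size_intersection = length(members),
         members_intersection = gene_set(members, name = "venn_intersection")),
    class = "venn_report")
  stopifnot(report$size_intersection <= min(report$size_a, report$size_b))
  report
}

#' @export
print.venn_report <- function(x, ...) {
  cat("<venn_report> |A| = ", x$size_a, ", |B| = ", x$size_b,
      ", |A ∩ B| = ", x$size_intersection, "\n", sep = "")
  invisible(x)
}

#' Serialize a Venn report as JSON
#'
#' @param report a `venn_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_venn_report <- function(report, path) {
  stopifnot(inherits(report, "venn_report"))
  jsonlite::write_json(
    list(size_a = report$size_a, size_b = report$size_b,
         size_intersection = report$size_intersection,
         members = report$members_intersection$genes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
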