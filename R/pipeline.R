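#' Build a pipeline configuration
#'
#' Collects every input path and every analysis choice in one validated
#' object.  Defaults mirror the conventional study settings: the eight
#' ADME criteria of [adme_criteria()], per-source target thresholds of
#' 0.7 (strict), STRING-dialect PPI scores filtered strictly above 700,
#' doubled degree convention, strict hub cutoffs, compound degree
#' counted over compound-target edges only, and enrichment at
#' BH-adjusted p < 0.001 against the annotation background.
#'
#' @param compounds path to the compound property TSV.
#' @param target_links path to the compound-target link TSV.
#' @param disease_gene_lists named character vector of gene-list paths
#'   (one per source database).
#' @param ppi_edges path to the PPI edge list.
#' @param annotation_gmt named character vector of GMT paths; names are
#'   namespaces (`BP`, `MF`, `CC`, `KEGG`).
#' @param symbol_map optional path to an alias table.
#' @param outdir output directory for intermediate tables and the run
#'   report.
#' @param criteria an [adme_criteria()] object.
#' @param source_thresholds per-source link thresholds.
#' @param ppi_dialect,ppi_min_score score dialect and strict retention
#'   threshold for the PPI edge list.
#' @param degree_convention `"doubled"` or `"simple"`.
#' @param hub_strictness `"strict"` or `"inclusive"`.
#' @param degree_scope compound-degree scope (see
#'   [compound_degree_rank()]).
#' @param alpha enrichment significance cutoff (strict, on adjusted p).
#' @param background_policy enrichment background policy.
#' @param compound_subset optional character vector of compound names
#'   for a restricted re-analysis.
#' @param disease_label,formula_label node labels for the
#'   herb-compound-target network.
#' @param seed seed recorded for any stochastic step (the pipeline
#'   itself is deterministic; generators use it).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(compounds, target_links, disease_gene_lists,
                            ppi_edges, annotation_gmt = character(),
                            symbol_map = NULL, outdir = tempfile("npharm_run_"),
                            criteria = adme_criteria(),
                            source_thresholds = default_source_thresholds(),
                            ppi_dialect = "string_0_1000",
                            ppi_min_score = 700,
                            degree_convention = "doubled",
                            hub_strictness = "strict",
                            degree_scope = "target_edges_only",
                            alpha = 0.001,
                            background_policy = "annotation",
                            compound_subset = NULL,
                            disease_label = "disease",
                            formula_label = "formula",
                            seed = 1L) {
  paths <- c(compounds = compounds, target_links = target_links,
             disease_gene_lists, ppi_edges = ppi_edges, annotation_gmt,
             if (!is.null(symbol_map)) c(symbol_map = symbol_map))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("configured input file(s) not found: ",
         paste(missing_files, collapse = ", "))
  }
  if (length(annotation_gmt)) {
    stopifnot(!is.null(names(annotation_gmt)),
              all(names(annotation_gmt) %in% ANNOTATION_NAMESPACES))
  }
  stopifnot(!is.null(names(disease_gene_lists)))
  structure(list(compounds = compounds, target_links = target_links,
                 disease_gene_lists = disease_gene_lists,
                 ppi_edges = ppi_edges, annotation_gmt = annotation_gmt,
                 symbol_map = symbol_map, outdir = outdir,
                 criteria = criteria, source_thresholds = source_thresholds,
                 ppi_dialect = ppi_dialect, ppi_min_score = ppi_min_score,
                 degree_convention = degree_convention,
                 hub_strictness = hub_strictness,
                 degree_scope = degree_scope, alpha = alpha,
                 background_policy = background_policy,
                 compound_subset = compound_subset,
                 disease_label = disease_label,
                 formula_label = formula_label,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].  Relative input paths are resolved against
#'   the file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(p)
    out <- ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
    stats::setNames(out, names(p))
  }
  for (k in c("compounds", "target_links", "ppi_edges", "symbol_map")) {
    y[[k]] <- fix(y[[k]])
  }
  y$disease_gene_lists <- fix(unlist(y$disease_gene_lists))
  if (!is.null(y$annotation_gmt)) y$annotation_gmt <- fix(unlist(y$annotation_gmt))
  do.call(pipeline_config, y)
}

run_stage <- function(stage, outdir, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage '", stage, "': ", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  attr(value, "elapsed") <- proc.time()[["elapsed"]] - t0
  value
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the stages in order: ADME screen -> target aggregation ->
#' disease union -> Venn intersection -> induced PPI network ->
#' centralities -> median-cutoff hub selection -> herb-compound-target
#' network and compound ranking -> over-representation analysis of the
#' hub genes.  Every intermediate table is written under
#' `config$outdir` and the run report is serialized as
#' `run_report.json`.  Identical config and inputs yield identical
#' outputs; a failing stage aborts with the stage named and leaves a
#' `FAILED` marker beside the partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: per-stage counts, the
#'   config snapshot, package version and per-stage wall-clock seconds.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config$outdir, "FAILED"))
  out <- function(...) file.path(config$outdir, ...)
  timings <- list()
  symbol_map <- if (!is.null(config$symbol_map))
    read_symbol_map(config$symbol_map) else NULL

  records <- run_stage("read_compounds", config$outdir,
                       read_compound_table(config$compounds))
  screen <- run_stage("screen", config$outdir, {
    s <- screen_compounds(records, config$criteria)
    write_compound_table(s$passing, out("active_compounds.tsv"))
    screen_audit_table(s, records, config$criteria, out("adme_audit.tsv"))
    s
  })
  timings$screen <- attr(screen, "elapsed")

  links_all <- run_stage("read_links", config$outdir,
                         read_target_links(config$target_links))
  targets <- run_stage("aggregate_targets", config$outdir, {
    keep <- links_all$compound_id %in% screen$passing$compound_id
    gs <- aggregate_targets(links_all[keep, , drop = FALSE],
                            config$source_thresholds, symbol_map)
    writeLines(c("gene", gs$genes), out("formula_targets.txt"))
    gs
  })
  timings$aggregate_targets <- attr(targets, "elapsed")

  disease <- run_stage("union_disease", config$outdir, {
    lists <- lapply(config$disease_gene_lists, read_gene_list)
    gs <- union_disease_genes(lists, symbol_map)
    writeLines(c("gene", gs$genes), out("disease_genes.txt"))
    gs
  })
  timings$union_disease <- attr(disease, "elapsed")

  venn <- run_stage("intersect", config$outdir, {
    v <- intersect_targets(targets, disease)
    write_venn_report(v, out("venn.json"))
    v
  })
  timings$intersect <- attr(venn, "elapsed")

  induced <- run_stage("induce_network", config$outdir, {
    ppi <- read_ppi_edges(config$ppi_edges, config$ppi_dialect,
                          config$ppi_min_score)
    net <- induce_network(ppi, venn$members_intersection)
    write_network(net, out("induced_network.tsv"), format = "tsv")
    net
  })
  timings$induce_network <- attr(induced, "elapsed")

  hubs <- run_stage("hub_selection", config$outdir, {
    tab <- centrality_table(induced, config$degree_convention)
    utils::write.table(tab, out("centrality_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sel <- select_hub_genes(tab, median_cutoffs(tab), config$hub_strictness)
    write_hub_selection(sel, out("hub_genes.tsv"))
    sel
  })
  timings$hub_selection <- attr(hubs, "elapsed")

  hct <- run_stage("hct_network", config$outdir, {
    passing <- screen$passing
    if (!is.null(config$compound_subset)) {
      passing <- passing[passing$name %in% config$compound_subset, ,
                         drop = FALSE]
    }
    links <- attr(targets, "links")
    links <- links[links$compound_id %in% passing$compound_id, , drop = FALSE]
    links$compound <- passing$name[match(links$compound_id,
                                         passing$compound_id)]
    herb_map <- data.frame(herb_source = passing$herb_source,
                           compound = passing$name,
                           stringsAsFactors = FALSE)
    net <- build_hct(herb_map, links, hubs$hubs$gene,
                     disease_label = config$disease_label,
                     formula_label = config$formula_label)
    write_hct_network(net, out("hct_network.tsv"))
    rank <- compound_degree_rank(net, config$degree_scope)
    utils::write.table(rank$ranking, out("compound_rank.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(network = net, rank = rank)
  })
  timings$hct_network <- attr(hct, "elapsed")

  enrich <- run_stage("enrichment", config$outdir, {
    if (!length(config$annotation_gmt)) {
      NA
    } else {
      res <- do.call(rbind, lapply(names(config$annotation_gmt), function(ns) {
        db <- read_gmt(config$annotation_gmt[[ns]], namespace = ns)
        enrich_gene_set(hubs$hubs$gene, db,
                        background_policy = config$background_policy,
                        alpha = config$alpha)
      }))
      write_enrichment(res, out("enrichment.tsv"))
      res
    }
  })
  timings$enrichment <- attr(enrich, "elapsed")

  report <- structure(list(
    counts = list(
      candidates = nrow(records),
      passers = nrow(screen$passing),
      per_herb = as.list(screen$per_herb_counts),
      target_union = length(targets$genes),
      disease_union = length(disease$genes),
      venn_intersection = venn$size_intersection,
      network_nodes = length(induced$nodes),
      network_edges = nrow(induced$edges),
      network_isolates = induced$n_isolates,
      medians = hubs$medians,
      hub_genes = nrow(hubs$hubs),
      compound_degree_median = hct$rank$median_degree,
      selected_compounds = length(hct$rank$selected),
      significant_terms = if (!is.data.frame(enrich)) NA_integer_ else
        nrow(enrich)),
    config = config,
    version = as.character(utils::packageVersion("netpharm")),
    timings = timings),
    class = "run_report")
  jsonlite::write_json(
    list(counts = report$counts, version = report$version,
         timings = timings,
         config = list(
           ppi_dialect = config$ppi_dialect,
           ppi_min_score = config$ppi_min_score,
           degree_convention = config$degree_convention,
           hub_strictness = config$hub_strictness,
           degree_scope = config$degree_scope,
           alpha = config$alpha,
           background_policy = config$background_policy,
           seed = config$seed)),
    out("run_report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  c <- x$counts
  cat("<run_report>\n",
      "  candidates: ", c$candidates, ", passers: ", c$passers, "\n",
      "  target union: ", c$target_union, ", disease union: ",
      c$disease_union, ", intersection: ", c$venn_intersection, "\n",
      "  network: ", c$network_nodes, " nodes / ", c$network_edges,
      " edges, hubs: ", c$hub_genes, "\n",
      "  compound median: ", c$compound_degree_median, ", selected: ",
      c$selected_compounds, ", significant terms: ",
      c$significant_terms, "\n", sep = "")
  invisible(x)
}

#' Re-run the downstream analysis on a compound subset
#'
#' The two-pass workflow: after a first full run, restrict the screened
#' passers to a validated subset (e.g. the compounds detected in the
#' physical extract) and re-derive targets, the induced network, the
#' median cutoffs, the hub genes and the enrichment for that subset.
#' Outputs go to a sibling directory `<outdir>_subset`.
#'
#' @param config a [pipeline_config()].
#' @param compound_subset non-empty character vector of compound names,
#'   all among the screened passers.
#' @return a `run_report` for the subset run.
#' @export
run_subset_reanalysis <- function(config, compound_subset) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(compound_subset)) stop("compound subset is empty")
  records <- read_compound_table(config$compounds)
  screen <- screen_compounds(records, config$criteria)
  unknown <- setdiff(compound_subset, screen$passing$name)
  if (length(unknown)) {
    stop("subset compound(s) not among the screened passers: ",
         paste(unknown, collapse = ", "))
  }
  sub_cfg <- config
  sub_cfg$outdir <- paste0(sub("/+$", "", config$outdir), "_subset")
  # restrict the link table to the subset compounds, then rerun as-is
  dir.create(sub_cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  links <- read_target_links(config$target_links)
  ids <- screen$passing$compound_id[screen$passing$name %in% compound_subset]
  links <- links[links$compound_id %in% ids, , drop = FALSE]
  link_path <- file.path(sub_cfg$outdir, "subset_links.tsv")
  utils::write.table(links, link_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sub_cfg$target_links <- link_path
  sub_cfg$compound_subset <- compound_subset
  run_pipeline(sub_cfg)
}
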