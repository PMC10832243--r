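#' Define a synthetic-data scenario
#'
#' One object holds every knob of the synthetic inputs so each
#' generator is a pure function of the scenario: the same scenario
#' yields byte-identical outputs.  The defaults emulate the study
#' conditions of the reference SH003/NSCLC data set at desk scale: 965
#' candidate compounds of which 20 pass the ADME screen, a target union
#' of 290 genes, a planted Venn overlap of 239 with the disease set, a
#' 200-node PPI graph with 10 planted hubs, and a 50-term annotation
#' database with one planted enriched term.
#'
#' @param seed integer seed driving every random draw.
#' @param n_compounds number of candidate compounds.
#' @param pass_fraction fraction of compounds passing the default ADME
#'   criteria by construction (`round(n_compounds * pass_fraction)`
#'   records pass).
#' @param herb_weights named mixing weights over herb sources.
#' @param gene_universe_size size of the gene universe from which
#'   targets, disease genes and annotation terms are drawn.
#' @param target_union_size number of distinct genes in the aggregated
#'   (above-threshold) target union.
#' @param extra_targets_per_gene mean number of additional compounds
#'   (beyond the first) linked to each target gene; shapes the
#'   bipartite degree distribution.
#' @param disease_set_size number of disease genes.
#' @param planted_overlap_size exact size of the target/disease
#'   intersection.
#' @param ppi list: `n_nodes`, `n_planted_hubs`, `p_within_hub_core`
#'   (edge probability from a planted hub to any node) and
#'   `p_background` (all other pairs).
#' @param annotation list: `n_terms`, `term_size_range`, `n_planted`
#'   and `enrichment_odds` (sampling odds of a query gene inside a
#'   planted term).
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_compounds = 965L,
                               pass_fraction = 20 / 965,
                               herb_weights = c(AM = 1/3, AG = 1/3, TK = 1/3),
                               gene_universe_size = 3000L,
                               target_union_size = 290L,
                               extra_targets_per_gene = 0.6,
                               disease_set_size = 2000L,
                               planted_overlap_size = 239L,
                               ppi = list(n_nodes = 200L,
                                          n_planted_hubs = 10L,
                                          p_within_hub_core = 0.5,
                                          p_background = 0.02),
                               annotation = list(n_terms = 50L,
                                                 term_size_range = c(20L, 60L),
                                                 n_planted = 1L,
                                                 enrichment_odds = 20)) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1,
            ppi$p_within_hub_core >= 0, ppi$p_within_hub_core <= 1,
            ppi$p_background >= 0, ppi$p_background <= 1,
            ppi$n_planted_hubs < ppi$n_nodes)
  if (planted_overlap_size > min(target_union_size, disease_set_size)) {
    stop("planted overlap larger than the smaller of the two sets")
  }
  if (target_union_size + disease_set_size - planted_overlap_size >
      gene_universe_size) {
    stop("target and disease sets do not fit in the gene universe")
  }
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 pass_fraction = pass_fraction, herb_weights = herb_weights,
                 gene_universe_size = as.integer(gene_universe_size),
                 target_union_size = as.integer(target_union_size),
                 extra_targets_per_gene = extra_targets_per_gene,
                 disease_set_size = as.integer(disease_set_size),
                 planted_overlap_size = as.integer(planted_overlap_size),
                 ppi = ppi, annotation = annotation),
            class = "synthetic_scenario")
}

# seed the RNG for the calling function's scope and restore the global
# stream on exit, so every generator is a pure function of its scenario
local_scoped_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
}

# gene universe shared by the disease/target and annotation generators
scenario_universe <- function(scenario) {
  sprintf("GENE%05d", seq_len(scenario$gene_universe_size))
}

# the planted target/disease split, reproducible on its own so that the
# PPI generator can anchor its nodes on the overlap genes
scenario_planted_sets <- function(scenario) {
  local_scoped_seed(scenario$seed + 303L)
  universe <- scenario_universe(scenario)
  n_t <- scenario$target_union_size
  n_d <- scenario$disease_set_size
  n_o <- scenario$planted_overlap_size
  picked <- sample(universe, n_t + n_d - n_o)
  list(overlap = picked[seq_len(n_o)],
       target_only = picked[n_o + seq_len(n_t - n_o)],
       disease_only = picked[n_t + seq_len(n_d - n_o)])
}

# draw within [lo, hi]; integer draws use sample() for exactness
runifr <- function(n, lo, hi) stats::runif(n, lo, hi)

#' Generate a compound table with known ADME verdicts
#'
#' Exactly `round(n_compounds * pass_fraction)` records satisfy the
#' default [adme_criteria()] by construction; property values for
#' passers are drawn from ranges bracketing those observed in real
#' screened flavonoid-class compounds (MW 240-320 Da, ALogP 1-3, OB
#' 30-70 %, DL 0.18-0.35, ...).  Each failing record violates exactly
#' one randomly chosen criterion, so every verdict branch is
#' exercised.  The truth manifest lists the intended verdict and the
#' violated criterion per compound.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `records` (compound `data.frame`) and `manifest`
#'   (`data.frame` compound_id / expected_pass / violated).
#' @export
gen_compound_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_compounds
  n_pass <- round(n * scenario$pass_fraction)
  if (n_pass < 0 || n_pass > n) stop("infeasible pass_fraction")
  local_scoped_seed(scenario$seed + 101L)
  herbs <- sample(names(scenario$herb_weights), n, replace = TRUE,
                  prob = scenario$herb_weights)
  rec <- data.frame(
    compound_id = as.character(9000000L + seq_len(n)),
    name = sprintf("syncpd%04d", seq_len(n)),
    herb_source = herbs,
    mw = runifr(n, 240, 320),
    alogp = runifr(n, 1, 3),
    hdon = sample(0:4, n, replace = TRUE),
    hacc = sample(2:9, n, replace = TRUE),
    ob = runifr(n, 30, 70),
    caco2 = runifr(n, -0.3, 1),
    dl = runifr(n, 0.18, 0.35),
    rbn = sample(0:10, n, replace = TRUE),
    stringsAsFactors = FALSE)
  is_pass <- rep(FALSE, n)
  is_pass[sample.int(n, n_pass)] <- TRUE
  violated <- rep(NA_character_, n)
  fail_idx <- which(!is_pass)
  if (length(fail_idx)) {
    violated[fail_idx] <- sample(ADME_PROPERTIES, length(fail_idx),
                                 replace = TRUE)
    for (i in fail_idx) {
      rec[i, violated[i]] <- switch(
        violated[i],
        mw = runifr(1, 500, 900),
        alogp = runifr(1, 5, 9),
        hdon = sample(5:9, 1),
        hacc = sample(10:15, 1),
        ob = runifr(1, 1, 29.5),
        caco2 = runifr(1, -2, -0.45),
        dl = runifr(1, 0.01, 0.17),
        rbn = sample(11:20, 1))
    }
  }
  validate_compound_records(rec)
  manifest <- data.frame(compound_id = rec$compound_id,
                         expected_pass = is_pass,
                         violated = violated,
                         stringsAsFactors = FALSE)
  list(records = rec, manifest = manifest)
}

#' Generate a PPI network with planted hubs
#'
#' Core-periphery random graph: the planted hubs are wired to every
#' node independently with probability `p_within_hub_core`, all other
#' pairs with probability `p_background`.  Planting requires
#' `p_within_hub_core > p_background`, otherwise the hubs are
#' unidentifiable and the call is fatal.  Edge scores are drawn above
#' the conventional 700 cutoff on the STRING 0-1000 scale so the whole
#' graph survives a high-confidence filter.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `network` (a `ppi_network`) and `manifest`
#'   (character vector of planted hub genes).
#' @export
gen_ppi_with_planted_hubs <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  p <- scenario$ppi
  if (p$p_within_hub_core <= p$p_background) {
    stop("p_within_hub_core must exceed p_background for planting to be identifiable")
  }
  # anchor nodes on the planted overlap genes so the graph is the
  # synthetic counterpart of the induced disease-target subnetwork
  sets <- scenario_planted_sets(scenario)
  pool <- c(sets$overlap,
            setdiff(scenario_universe(scenario), sets$overlap))
  local_scoped_seed(scenario$seed + 202L)
  nodes <- pool[seq_len(p$n_nodes)]
  hubs <- sort(sample(nodes, p$n_planted_hubs))
  pairs <- utils::combn(nodes, 2)
  is_hub_pair <- pairs[1, ] %in% hubs | pairs[2, ] %in% hubs
  prob <- ifelse(is_hub_pair, p$p_within_hub_core, p$p_background)
  keep <- stats::runif(ncol(pairs)) < prob
  edges <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                      score = round(runifr(sum(keep), 701, 999)),
                      stringsAsFactors = FALSE)
  net <- ppi_network(edges, nodes = nodes, dialect = "string_0_1000")
  list(network = net, manifest = hubs)
}

#' Generate disease genes and compound-target links with a planted overlap
#'
#' Builds a target union of `target_union_size` genes and a disease set
#' of `disease_set_size` genes from the shared universe such that their
#' intersection has exactly `planted_overlap_size` members.  The target
#' genes are distributed over the passing compounds of
#' [gen_compound_table()] (each gene gets one carrier compound plus a
#' Poisson number of extras, shaping the bipartite degree
#' distribution), with above-threshold scores; sub-threshold decoy
#' links to non-target genes are added to exercise the score filter.
#' The disease genes are split over three pseudo-sources with
#' overlapping membership, so the union step is non-trivial.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `disease_lists` (named list of character vectors),
#'   `links` (compound-target `data.frame`), `compounds` (the passing
#'   compound ids used as carriers) and `manifest` (list with
#'   `target_union`, `disease_set`, `overlap`).
#' @export
gen_disease_and_targets <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  universe <- scenario_universe(scenario)
  sets <- scenario_planted_sets(scenario)
  targets <- c(sets$overlap, sets$target_only)
  disease <- c(sets$overlap, sets$disease_only)
  local_scoped_seed(scenario$seed + 305L)
  # three overlapping pseudo-source lists covering the disease set
  covers <- lapply(1:3, function(i) {
    base <- disease[seq(i, length(disease), by = 3)]
    extra <- sample(disease, round(length(disease) * 0.2))
    unique(c(base, extra))
  })
  names(covers) <- c("ctd_like", "disgenet_like", "genecards_like")
  # carrier compounds: the manifest passers of the compound generator
  cpds <- gen_compound_table(scenario)
  carriers <- cpds$records$compound_id[cpds$manifest$expected_pass]
  if (!length(carriers)) stop("scenario has no passing compounds to carry targets")
  n_extra <- stats::rpois(length(targets), scenario$extra_targets_per_gene)
  link_rows <- lapply(seq_along(targets), function(i) {
    carrier_set <- unique(c(sample(carriers, 1),
                            sample(carriers, min(n_extra[i], length(carriers)))))
    data.frame(compound_id = carrier_set, gene_raw = targets[i],
               stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, link_rows)
  links$source_db <- sample(c("pharmmapper", "swisstarget", "stitch"),
                            nrow(links), replace = TRUE)
  links$score <- runifr(nrow(links), 0.71, 0.99)
  # decoys: below-threshold links to genes outside the target union
  n_decoy <- max(1L, round(nrow(links) * 0.3))
  decoy_pool <- setdiff(universe, targets)
  decoys <- data.frame(
    compound_id = sample(carriers, n_decoy, replace = TRUE),
    gene_raw = sample(decoy_pool, n_decoy, replace = TRUE),
    source_db = sample(c("pharmmapper", "swisstarget", "stitch"),
                       n_decoy, replace = TRUE),
    score = runifr(n_decoy, 0.05, 0.69),
    stringsAsFactors = FALSE)
  links <- rbind(links, decoys)
  links <- links[order(links$compound_id, links$gene_raw, links$source_db), ]
  rownames(links) <- NULL
  list(disease_lists = covers, links = links, compounds = carriers,
       manifest = list(target_union = sort(targets),
                       disease_set = sort(disease),
                       overlap = sort(sets$overlap)))
}

#' Generate an annotation database with planted enriched terms
#'
#' Null terms sample their genes uniformly from the background; planted
#' terms over-sample the supplied query genes at the configured odds
#' (> 1, otherwise planting is meaningless and the call is fatal).  The
#' manifest lists the planted term ids and their realized hit counts.
#'
#' @param scenario a [synthetic_scenario()].
#' @param query character vector of query genes (inside the universe).
#' @return list with `db` (an `annotation_db` over the scenario
#'   universe) and `manifest` (`data.frame` term_id / planted /
#'   hits_in_query).
#' @export
gen_annotation_with_planted_terms <- function(scenario, query) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  a <- scenario$annotation
  if (a$n_planted > 0 && a$enrichment_odds <= 1) {
    stop("planted enrichment odds must exceed 1")
  }
  universe <- scenario_universe(scenario)
  query <- intersect(toupper(query), universe)
  if (a$n_planted > 0 && !length(query)) {
    stop("query has no genes inside the scenario universe")
  }
  if (max(a$term_size_range) > length(universe)) {
    stop("term sizes exceed the gene universe")
  }
  local_scoped_seed(scenario$seed + 404L)
  sizes <- sample(a$term_size_range[1]:a$term_size_range[2], a$n_terms,
                  replace = TRUE)
  planted <- seq_len(a$n_planted)
  weights <- ifelse(universe %in% query, a$enrichment_odds, 1)
  genes <- lapply(seq_len(a$n_terms), function(i) {
    w <- if (i %in% planted) weights else rep(1, length(universe))
    sample(universe, sizes[i], prob = w)
  })
  terms <- data.frame(term_id = sprintf("TERM:%04d", seq_len(a$n_terms)),
                      term_name = sprintf("synthetic term %04d", seq_len(a$n_terms)),
                      namespace = "BP",
                      stringsAsFactors = FALSE)
  terms$genes <- genes
  db <- annotation_db(terms, background = universe)
  manifest <- data.frame(
    term_id = terms$term_id,
    planted = seq_len(a$n_terms) %in% planted,
    hits_in_query = vapply(genes, function(g) length(intersect(g, query)),
                           integer(1)),
    stringsAsFactors = FALSE)
  list(db = db, manifest = manifest)
}

#' Draw a reproducible query gene set from a scenario's universe
#'
#' Convenience for enrichment experiments: a uniform sample of the
#' scenario's gene universe, reproducible from the scenario seed and
#' independent of the other generators' draws.
#'
#' @param scenario a [synthetic_scenario()].
#' @param size query size.
#' @return sorted character vector of gene symbols.
#' @export
scenario_query <- function(scenario, size) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            size <= scenario$gene_universe_size)
  local_scoped_seed(scenario$seed + 505L)
  sort(sample(scenario_universe(scenario), size))
}

#' Hub recovery score against a planted manifest
#'
#' Compares the leading entries of a hub selection's ranking with the
#' planted hubs of [gen_ppi_with_planted_hubs()].  The median rule, by
#' construction, always admits a sizeable fraction of the cohort
#' (roughly everything above the median on all three correlated
#' measures), so recovery is judged where it is decidable: do the
#' planted hubs occupy the top of the ranking?  The score is the
#' Jaccard index between the first `length(planted)` ranked hubs and
#' the planted set.
#'
#' @param selection a `hub_selection` (or its `hubs` table).
#' @param planted character vector of planted hub genes.
#' @return Jaccard index in \[0, 1\].
#' @export
hub_recovery_jaccard <- function(selection, planted) {
  hubs <- if (inherits(selection, "hub_selection")) selection$hubs else selection
  top <- utils::head(hubs$gene, length(planted))
  length(intersect(top, planted)) / length(union(top, planted))
}

#' Write a scenario's generated bundle to a directory
#'
#' Materializes every synthetic input in the same on-disk dialects the
#' readers consume (compound TSV, link TSV, gene-list text, PPI edge
#' TSV, GMT), plus the scenario as YAML and the manifests as JSON —
#' ready for [run_pipeline()].
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @param query optional query gene set for the annotation generator;
#'   defaults to the planted target/disease overlap.
#' @return invisible list of the generated objects and manifests.
#' @export
write_scenario_bundle <- function(scenario, dir, query = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpds <- gen_compound_table(scenario)
  dt <- gen_disease_and_targets(scenario)
  ppi <- gen_ppi_with_planted_hubs(scenario)
  if (is.null(query)) query <- dt$manifest$overlap
  ann <- gen_annotation_with_planted_terms(scenario, query)
  write_compound_table(cpds$records, file.path(dir, "compounds.tsv"))
  utils::write.table(dt$links, file.path(dir, "target_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(dt$disease_lists)) {
    writeLines(c("gene", dt$disease_lists[[s]]),
               file.path(dir, paste0("disease_", s, ".txt")))
  }
  utils::write.table(ppi$network$edges, file.path(dir, "ppi_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(ann$db, file.path(dir, "annotation_bp.gmt"))
  yaml::write_yaml(unclass(scenario), file.path(dir, "scenario.yaml"))
  jsonlite::write_json(
    list(adme = cpds$manifest, overlap = dt$manifest,
         ppi_hubs = ppi$manifest, annotation = ann$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(compounds = cpds, disease_targets = dt, ppi = ppi,
                 annotation = ann))
}
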