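#' netpharm: network pharmacology of multi-herb formulas
#'
#' Tools to screen herbal compounds for oral activity, intersect their
#' predicted targets with disease gene sets, select hub genes from
#' protein-protein interaction (PPI) networks, rank compounds in
#' herb-compound-target networks, and test annotation-term
#' over-representation.  All stages read and write plain tab-separated
#' text, and every stage has a matching seed-reproducible synthetic-data
#' generator with known ground truth.
#'
#' @docType package
#' @name netpharm-package
#' @keywords internal
"_PACKAGE"

# canonical names of the eight ADME properties used throughout
ADME_PROPERTIES <- c("mw", "alogp", "hdon", "hacc", "ob", "caco2", "dl", "rbn")

COMPOUND_FIELDS <- c("compound_id", "name", "herb_source", ADME_PROPERTIES)

#' Read a compound property table
#'
#' Reads a tab-separated table of compounds with the eight ADME properties
#' used for oral-activity screening: molecular weight (`mw`, Da), ALogP
#' (`alogp`), H-bond donors (`hdon`) and acceptors (`hacc`), oral
#' bioavailability (`ob`, percent), Caco-2 permeability (`caco2`, log
#' scale), drug-likeness (`dl`, in \[0,1\]) and rotatable bond count
#' (`rbn`), plus identity columns `compound_id`, `name` and `herb_source`.
#'
#' Malformed numeric cells become `NA` (explicitly missing, never silently
#' zero) and are counted in a warning.  A header-only file yields an empty
#' table with a warning; a missing mandatory column is a fatal error.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map optional named character vector mapping canonical
#'   field names (names) to the column names used in the file (values).
#'   Fields not listed are looked up under their canonical name.
#' @return a `data.frame` with columns `compound_id`, `name`,
#'   `herb_source` and the eight ADME properties, one row per compound.
#' @export
read_compound_table <- function(path, column_map = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  wanted <- stats::setNames(COMPOUND_FIELDS, COMPOUND_FIELDS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), COMPOUND_FIELDS)
    if (length(bad)) stop("unknown fields in column_map: ",
                          paste(bad, collapse = ", "))
    wanted[names(column_map)] <- column_map
  }
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols)) {
    stop("compound table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("compound table '", basename(path), "' has a header but no rows")
  }
  out <- raw[, unname(wanted), drop = FALSE]
  names(out) <- names(wanted)
  n_bad <- 0L
  for (p in ADME_PROPERTIES) {
    was_na <- is.na(out[[p]]) | !nzchar(trimws(out[[p]]))
    num <- suppressWarnings(as.numeric(out[[p]]))
    n_bad <- n_bad + sum(is.na(num) & !was_na)
    out[[p]] <- num
  }
  if (n_bad > 0L) {
    warning(n_bad, " malformed numeric cell(s) recorded as missing")
  }
  validate_compound_records(out)
  rownames(out) <- NULL
  out
}

#' Write a compound property table
#'
#' Inverse of [read_compound_table()]: writes tab-separated text that
#' round-trips through the reader.
#'
#' @param records compound `data.frame` as returned by
#'   [read_compound_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path) {
  stopifnot(all(COMPOUND_FIELDS %in% names(records)))
  utils::write.table(records[, COMPOUND_FIELDS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# invariant checks shared by the reader and the synthetic generator
validate_compound_records <- function(records) {
  with(records, {
    if (any(mw <= 0, na.rm = TRUE)) stop("mw must be positive")
    for (p in c("hdon", "hacc", "rbn")) {
      v <- records[[p]]
      if (any(v < 0 | v != round(v), na.rm = TRUE)) {
        stop(p, " must be a non-negative integer count")
      }
    }
    if (any(dl < 0 | dl > 1, na.rm = TRUE)) stop("dl must lie in [0, 1]")
  })
  invisible(records)
}

#' Read an alias-to-canonical gene symbol map
#'
#' @param path tab-separated file with columns `alias` and `canonical`
#'   (or any two columns in that order).
#' @return a `data.frame` with columns `alias` and `canonical`.
#' @export
read_symbol_map <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  if (ncol(m) < 2L) stop("symbol map needs two columns: alias, canonical")
  m <- m[, 1:2]
  names(m) <- c("alias", "canonical")
  m
}

#' Normalize gene symbols against an alias table
#'
#' Uppercases all symbols and maps aliases to canonical symbols using a
#' user-supplied table (no live lookups).  Symbols without a mapping pass
#' through uppercased and are listed in the `unmapped` report rather than
#' dropped, so downstream set sizes stay auditable.  Aliases that map to
#' more than one canonical symbol resolve to the lexicographically first
#' and are reported in `ambiguous`.
#'
#' The operation is idempotent and order-independent: normalizing twice
#' equals normalizing once, and the returned set is sorted and
#' deduplicated.
#'
#' @param symbols character vector of raw gene symbols.
#' @param symbol_map `data.frame` with columns `alias` and `canonical`
#'   (see [read_symbol_map()]), or `NULL` for uppercase-only
#'   normalization.
#' @return a list with `symbols` (sorted unique canonical symbols),
#'   `unmapped` (sorted unique uppercased inputs with no map entry) and
#'   `ambiguous` (`data.frame` of alias/chosen pairs).
#' @export
normalize_symbols <- function(symbols, symbol_map = NULL) {
  symbols <- toupper(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  ambiguous <- data.frame(alias = character(), chosen = character(),
                          stringsAsFactors = FALSE)
  if (is.null(symbol_map) || nrow(symbol_map) == 0L) {
    return(list(symbols = sort(unique(symbols)),
                unmapped = sort(unique(symbols)),
                ambiguous = ambiguous))
  }
  alias <- toupper(symbol_map$alias)
  canonical <- toupper(symbol_map$canonical)
  # resolve ambiguous aliases to the lexicographically first canonical
  tab <- unique(data.frame(alias = alias, canonical = canonical,
                           stringsAsFactors = FALSE))
  tab <- tab[order(tab$alias, tab$canonical), ]
  dup <- duplicated(tab$alias)
  if (any(dup)) {
    amb_aliases <- unique(tab$alias[dup])
    first <- tab[!duplicated(tab$alias), ]
    ambiguous <- data.frame(
      alias = amb_aliases,
      chosen = first$canonical[match(amb_aliases, first$alias)],
      stringsAsFactors = FALSE)
    tab <- first
  }
  idx <- match(symbols, tab$alias)
  mapped <- symbols
  mapped[!is.na(idx)] <- tab$canonical[idx[!is.na(idx)]]
  list(symbols = sort(unique(mapped)),
       unmapped = sort(unique(symbols[is.na(idx)])),
       ambiguous = ambiguous)
}

#' Construct a gene set
#'
#' A named, deduplicated, sorted set of normalized gene symbols with
#' provenance tags recording where the genes came from.
#'
#' @param genes character vector of symbols (normalized by the caller or
#'   via `symbol_map`).
#' @param name set label.
#' @param provenance character vector of source tags.
#' @param symbol_map optional alias table applied before deduplication.
#' @return an object of class `gene_set`: list with `name`, `genes`,
#'   `provenance` and the normalization report in `unmapped`.
#' @export
gene_set <- function(genes, name = "gene_set", provenance = character(),
                     symbol_map = NULL) {
  norm <- normalize_symbols(genes, symbol_map)
  structure(list(name = name, genes = norm$symbols,
                 provenance = provenance, unmapped = norm$unmapped),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes",
      if (length(x$provenance)) paste0(" [", paste(x$provenance, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

PPI_DIALECTS <- c("string_0_1000", "unit_interval")

#' Construct a PPI network
#'
#' An undirected, scored interaction network over normalized gene symbols:
#' no self-loops, each unordered pair at most once (duplicates collapse to
#' the maximum score).  The score dialect is recorded explicitly —
#' `string_0_1000` for STRING-style combined scores in \[0, 1000\],
#' `unit_interval` for probabilities in \[0, 1\] — and never guessed.
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `score`.
#' @param nodes optional character vector of node names; defaults to the
#'   genes present in `edges`.  Extra names become isolated nodes.
#' @param dialect score dialect, one of `"string_0_1000"`,
#'   `"unit_interval"`.
#' @param self_loops_dropped count carried from the reader, for auditing.
#' @return an object of class `ppi_network`.
#' @export
ppi_network <- function(edges, nodes = NULL,
                        dialect = c("string_0_1000", "unit_interval"),
                        self_loops_dropped = 0L) {
  dialect <- match.arg(dialect)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  edges$gene_a <- toupper(as.character(edges$gene_a))
  edges$gene_b <- toupper(as.character(edges$gene_b))
  loop <- edges$gene_a == edges$gene_b
  self_loops_dropped <- self_loops_dropped + sum(loop)
  edges <- edges[!loop, , drop = FALSE]
  # canonical unordered orientation, then collapse duplicates to max score
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  if (nrow(edges)) {
    key <- paste(a, b, sep = "\r")
    mx <- tapply(edges$score, key, max)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$score <- as.numeric(mx[paste(edges$gene_a, edges$gene_b, sep = "\r")])
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  }
  nodes <- sort(unique(c(toupper(as.character(nodes)),
                         edges$gene_a, edges$gene_b)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, dialect = dialect,
                 self_loops_dropped = as.integer(self_loops_dropped)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (dialect: ", x$dialect, ")\n", sep = "")
  invisible(x)
}

#' Read a STRING-style PPI edge list
#'
#' Expects a tab-separated file whose first three columns are gene A,
#' gene B and a combined confidence score.  Only edges with score
#' strictly above `min_score` (on the declared dialect's scale) are
#' retained; self-loops are dropped with a count and duplicate unordered
#' pairs collapse to the maximum score.  Nodes are taken from the
#' retained edges only.  A score outside the declared scale is a fatal
#' dialect error.
#'
#' @inheritParams ppi_network
#' @param path path to the edge-list file (header row expected).
#' @param min_score retention threshold, strictly exceeded, on the same
#'   scale as `dialect` (e.g. 700 for the conventional "high confidence
#'   0.7" with STRING's 0–1000 scores).
#' @return a `ppi_network`.
#' @export
read_ppi_edges <- function(path, dialect = c("string_0_1000", "unit_interval"),
                           min_score) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path), is.numeric(min_score))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("PPI edge list needs three columns: gene_a, gene_b, score")
  edges <- data.frame(gene_a = as.character(raw[[1]]),
                      gene_b = as.character(raw[[2]]),
                      score = as.numeric(raw[[3]]),
                      stringsAsFactors = FALSE)
  hi <- if (dialect == "string_0_1000") 1000 else 1
  if (any(is.na(edges$score)) || any(edges$score < 0 | edges$score > hi)) {
    stop("combined score outside the declared '", dialect,
         "' scale [0, ", hi, "]")
  }
  edges <- edges[edges$score > min_score, , drop = FALSE]
  ppi_network(edges, dialect = dialect)
}

#' Export a network for external viewers
#'
#' Writes a `ppi_network` (or any object with `nodes` and an edge table)
#' in SIF, GraphML or plain edge-list TSV, plus a node-attribute TSV next
#' to it (`<path>.nodes.tsv`).  Re-reading the export with
#' [read_network()] reconstructs the same node and edge sets.
#'
#' @param network a `ppi_network`.
#' @param path output path for the edge file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param node_attrs optional `data.frame` with a `name` column and
#'   further attribute columns; defaults to the bare node list.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e)) paste(e$gene_a, "pp", e$gene_b, sep = "\t") else character()
    writeLines(lines, path)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  if (is.null(node_attrs)) {
    node_attrs <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  }
  stopifnot("name" %in% names(node_attrs))
  utils::write.table(node_attrs, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-import a network written by [write_network()]
#'
#' @param path path passed to [write_network()].
#' @param format the format it was written in.
#' @param dialect score dialect to stamp on the result (SIF and GraphML
#'   carry no scores; edges get score 1 on the unit scale by default).
#' @return a `ppi_network`.
#' @export
read_network <- function(path, format = c("tsv", "sif", "graphml"),
                         dialect = "unit_interval") {
  format <- match.arg(format)
  nodes_path <- paste0(path, ".nodes.tsv")
  nodes <- if (file.exists(nodes_path)) {
    utils::read.delim(nodes_path, sep = "\t", stringsAsFactors = FALSE)$name
  } else character()
  if (format == "tsv") {
    e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    return(ppi_network(e, nodes = nodes, dialect = dialect))
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(ppi_network(NULL, nodes = nodes, dialect = dialect))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    e <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 3L),
                    score = 1, stringsAsFactors = FALSE)
    return(ppi_network(e, nodes = nodes, dialect = dialect))
  }
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(gene_a = e$from, gene_b = e$to,
                      score = if ("score" %in% names(e)) e$score else 1,
                      stringsAsFactors = FALSE)
  ppi_network(edges, nodes = c(nodes, igraph::V(g)$name), dialect = dialect)
}

#' Convert a `ppi_network` to an igraph graph
#'
#' @param network a `ppi_network`.
#' @return an undirected `igraph` graph with an edge attribute `score`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b", "score")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

#' Read a one-symbol-per-line gene list
#'
#' Accepts plain text with one symbol per line or a single-column TSV
#' with a header named `gene` or `symbol`.
#'
#' @param path input path.
#' @return character vector of raw symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(lines[1]) %in% c("gene", "symbol", "genes")) {
    lines <- lines[-1]
  }
  lines
}
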