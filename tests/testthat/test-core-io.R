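test_that("compound tables round-trip through write and read", {
  sc <- synthetic_scenario(seed = 11, n_compounds = 40, pass_fraction = 0.5)
  rec <- gen_compound_table(sc)$records
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(rec, path)
  back <- read_compound_table(path)
  expect_equal(back, rec, tolerance = 1e-12)
})

test_that("compound reader flags malformed cells and degenerate files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("compound_id", "name", "herb_source", "mw", "alogp",
                       "hdon", "hacc", "ob", "caco2", "dl", "rbn"),
                     collapse = "\t"),
               "c1\tx\tAM\toops\t2\t1\t4\t40\t0.5\t0.2\t1"), path)
  expect_warning(rec <- read_compound_table(path), "malformed")
  expect_true(is.na(rec$mw))
  expect_equal(rec$alogp, 2)

  header_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("compound_id", "name", "herb_source", "mw", "alogp",
                     "hdon", "hacc", "ob", "caco2", "dl", "rbn"),
                   collapse = "\t"), header_only)
  expect_warning(empty <- read_compound_table(header_only), "no rows")
  expect_equal(nrow(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tname", "c1\tx"), bad)
  expect_error(read_compound_table(bad), "mandatory column")
})

test_that("column_map remaps headers onto canonical fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("CID", "name", "herb_source", "MW", "alogp", "hdon",
                       "hacc", "ob", "caco2", "dl", "rbn"), collapse = "\t"),
               "42\tx\tAM\t300\t2\t1\t4\t40\t0.5\t0.2\t1"), path)
  rec <- read_compound_table(path, column_map = c(compound_id = "CID", mw = "MW"))
  expect_equal(rec$compound_id, "42")
  expect_equal(rec$mw, 300)
})

test_that("symbol normalization collapses aliases and reports the unmapped", {
  map <- data.frame(alias = "P53", canonical = "TP53")
  out <- normalize_symbols(c("Tp53", "p53"), map)
  expect_equal(out$symbols, "TP53")
  expect_equal(out$unmapped, "TP53")  # Tp53 itself has no map entry

  empty <- normalize_symbols(character(), map)
  expect_equal(empty$symbols, character())
  expect_equal(empty$unmapped, character())
})

test_that("symbol normalization is idempotent and order-independent", {
  set.seed(42)
  for (rep in 1:5) {
    alias <- sample(sprintf("g%02d", 1:30), 15)
    map <- data.frame(alias = alias,
                      canonical = sample(sprintf("CANON%02d", 1:10), 15,
                                         replace = TRUE))
    syms <- sample(sprintf("G%02d", 1:40), 25, replace = TRUE)
    once <- normalize_symbols(syms, map)$symbols
    twice <- normalize_symbols(once, map)$symbols
    shuffled <- normalize_symbols(sample(syms), map)$symbols
    expect_identical(twice, once)
    expect_identical(shuffled, once)
  }
})

test_that("ambiguous aliases resolve to the lexicographically first canonical", {
  map <- data.frame(alias = c("AKA", "AKA"), canonical = c("ZZZ", "AAA"))
  out <- normalize_symbols("aka", map)
  expect_equal(out$symbols, "AAA")
  expect_equal(out$ambiguous$alias, "AKA")
  expect_equal(out$ambiguous$chosen, "AAA")
})

test_that("PPI reader filters, deduplicates and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t900", "B\tA\t850", "C\tC\t990"),
             path)
  net <- read_ppi_edges(path, "string_0_1000", 700)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "A")
  expect_equal(net$edges$gene_b, "B")
  expect_equal(net$edges$score, 900)
  expect_equal(net$self_loops_dropped, 1L)

  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t600", "B\tC\t700"), path)
  none <- read_ppi_edges(path, "string_0_1000", 700)
  expect_equal(nrow(none$edges), 0L)
  expect_equal(none$nodes, character())

  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t1200"), path)
  expect_error(read_ppi_edges(path, "string_0_1000", 700), "scale")
  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t0.9"), path)
  expect_error(read_ppi_edges(path, "unit_interval", 1.5), NA)
})

test_that("PPI network is invariant to row order and endpoint swaps", {
  set.seed(7)
  for (rep in 1:5) {
    nodes <- sprintf("N%02d", 1:12)
    e <- data.frame(gene_a = sample(nodes, 40, TRUE),
                    gene_b = sample(nodes, 40, TRUE),
                    score = round(runif(40, 0, 1000)))
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    n1 <- read_ppi_edges(path, "string_0_1000", 300)
    swapped <- data.frame(gene_a = e$gene_b, gene_b = e$gene_a,
                          score = e$score)[sample(nrow(e)), ]
    write.table(swapped, path, sep = "\t", quote = FALSE, row.names = FALSE)
    n2 <- read_ppi_edges(path, "string_0_1000", 300)
    expect_identical(n1$edges, n2$edges)
    expect_identical(n1$nodes, n2$nodes)
    # edge count matches a brute-force count of distinct qualifying pairs
    keep <- e$score > 300 & e$gene_a != e$gene_b
    pairs <- unique(paste(pmin(e$gene_a, e$gene_b)[keep],
                          pmax(e$gene_a, e$gene_b)[keep]))
    expect_equal(nrow(n1$edges), length(pairs))
  }
})

test_that("network exports round-trip in every format", {
  net <- rand_ppi(10, 0.4, seed = 3)
  for (fmt in c("tsv", "sif", "graphml")) {
    path <- withr::local_tempfile()
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges[, c("gene_a", "gene_b")],
                     net$edges[, c("gene_a", "gene_b")])
    if (fmt == "tsv") expect_equal(back$edges$score, net$edges$score)
  }
  # 3-node path to SIF: two interaction lines
  path3 <- ppi_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                  score = 1), dialect = "unit_interval")
  f <- withr::local_tempfile()
  write_network(path3, f, format = "sif")
  expect_length(readLines(f), 2L)
  # empty graph: empty SIF, header-only attribute file
  empty <- ppi_network(NULL, dialect = "unit_interval")
  write_network(empty, f, format = "sif")
  expect_length(readLines(f), 0L)
  expect_length(readLines(paste0(f, ".nodes.tsv")), 1L)
  expect_error(write_network(net, f, format = "dot"), "arg")
})

test_that("GMT files round-trip and are validated", {
  terms <- data.frame(term_id = c("T1", "T2"),
                      term_name = c("term one", "term two"),
                      namespace = "KEGG", stringsAsFactors = FALSE)
  terms$genes <- list(c("A", "B", "C"), c("B", "D"))
  db <- annotation_db(terms)
  expect_setequal(db$background, c("A", "B", "C", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  back <- read_gmt(path, namespace = "KEGG")
  expect_equal(back$terms$term_id, db$terms$term_id)
  expect_identical(back$terms$genes, db$terms$genes)

  terms$genes <- list(character(), "B")
  expect_error(annotation_db(terms), "at least one gene")
  expect_error(annotation_db(terms[0, ]), "no terms")
  writeLines("T1\tonly two fields", path)
  expect_error(read_gmt(path, "BP"), "fewer than three")
})

test_that("gene lists accept bare and single-column formats", {
  path <- withr::local_tempfile()
  writeLines(c("gene", "TP53", "EGFR", ""), path)
  expect_equal(read_gene_list(path), c("TP53", "EGFR"))
  writeLines(c("TP53", "EGFR"), path)
  expect_equal(read_gene_list(path), c("TP53", "EGFR"))
})
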