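test_that("hypergeometric tail matches exact enumeration on small urns", {
  # whole sample space
  expect_identical(hypergeom_pvalue(0, 3, 5, 10), 1)
  # all three draws marked: C(5,3)/C(10,3) = 10/120
  expect_equal(hypergeom_pvalue(3, 3, 5, 10), 10 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(3, 3, 5, 10),
               enum_hypergeom_tail(3, 5, 10)[4], tolerance = 1e-12)
  # a spread of random small instances against the enumeration oracle
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    tail <- enum_hypergeom_tail(n, K, N)
    expect_equal(hypergeom_pvalue(0:min(n, K), n, K, N), tail,
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(5, 3, 5, 10), "inconsistent")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "inconsistent")
})

test_that("the tail is non-increasing in the hit count", {
  for (rep in 1:10) {
    set.seed(rep)
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    p <- hypergeom_pvalue(0:min(n, K), n, K, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment reproduces the step-up closed forms", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 6)), rep(0.02, 6))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH adjustment is order-invariant and never below the raw p", {
  set.seed(14)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("over-representation handles certain and impossible hits", {
  terms <- data.frame(term_id = c("ALL", "T2"),
                      term_name = c("everything", "small"),
                      namespace = "BP", stringsAsFactors = FALSE)
  terms$genes <- list(sprintf("G%02d", 1:20), c("G01", "G02"))
  db <- annotation_db(terms)
  res <- enrich_gene_set(c("G01", "G02", "G03"), db, alpha = 1)
  expect_equal(res$p_raw[res$term_id == "ALL"], 1)
  expect_equal(res$query_size, rep(3L, nrow(res)))

  none <- enrich_gene_set(c("ZZZ1", "ZZZ2"), db, alpha = 1)
  expect_equal(nrow(none), 0L)
})

test_that("a strongly planted term ranks first", {
  sc <- synthetic_scenario(seed = 3)
  set.seed(33)
  query <- sample(sprintf("GENE%05d", 1:3000), 100)
  ann <- gen_annotation_with_planted_terms(sc, query)
  res <- enrich_gene_set(query, ann$db, alpha = 1)
  expect_equal(res$term_id[1], ann$manifest$term_id[ann$manifest$planted])
})

test_that("significance filtering is strict on the adjusted p within namespaces", {
  set.seed(15)
  bg <- sprintf("G%03d", 1:300)
  terms <- data.frame(term_id = sprintf("T%02d", 1:12),
                      term_name = sprintf("term %02d", 1:12),
                      namespace = rep(c("BP", "KEGG"), each = 6),
                      stringsAsFactors = FALSE)
  query <- sample(bg, 40)
  terms$genes <- c(list(sample(query, 25)),  # strongly enriched
                   lapply(2:12, function(i) sample(bg, 30)))
  db <- annotation_db(terms, background = bg)
  all_res <- enrich_gene_set(query, db, alpha = 1)
  # BH is applied per namespace: adjusted values match a manual pass
  for (ns in c("BP", "KEGG")) {
    sub <- all_res[all_res$namespace == ns, ]
    expect_equal(sub$p_adj, unname(bh_adjust(sub$p_raw)))
  }
  sig <- enrich_gene_set(query, db, alpha = 0.001)
  expect_true(all(sig$p_adj < 0.001))
  expect_equal(sig$term_id[1], "T01")
  # invariants of the result rows
  expect_true(all(all_res$p_adj >= all_res$p_raw - 1e-15))
  expect_true(all(all_res$hit_count <=
                    pmin(all_res$term_size, all_res$query_size)))
  expect_true(all(all_res$pct_associated > 0 & all_res$pct_associated <= 100))
})

test_that("bubble tables carry the plotting columns", {
  terms <- data.frame(term_id = "T1", term_name = "one", namespace = "KEGG",
                      stringsAsFactors = FALSE)
  terms$genes <- list(sprintf("G%02d", 1:20))
  db <- annotation_db(terms, background = sprintf("G%02d", 1:80))
  res <- enrich_gene_set(sprintf("G%02d", 1:10), db, alpha = 1)
  res$p_adj <- 0.001  # fixed value to check the transform
  class(res) <- c("enrichment_result", "data.frame")
  bub <- bubble_data(res)
  expect_equal(bub$neg_log10_p_adj, 3)
  expect_equal(bub$pct_associated, 100 * res$hit_count / res$term_size)
  # round trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read.delim(path)
  expect_equal(back$hit_count, res$hit_count)
})
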