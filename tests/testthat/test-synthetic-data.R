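test_that("generators are pure functions of the scenario", {
  sc <- synthetic_scenario(seed = 42, n_compounds = 60, pass_fraction = 0.25)
  expect_identical(gen_compound_table(sc), gen_compound_table(sc))
  expect_identical(gen_ppi_with_planted_hubs(sc),
                   gen_ppi_with_planted_hubs(sc))
  expect_identical(gen_disease_and_targets(sc), gen_disease_and_targets(sc))
  q <- gen_disease_and_targets(sc)$manifest$overlap
  expect_identical(gen_annotation_with_planted_terms(sc, q),
                   gen_annotation_with_planted_terms(sc, q))
  # generators leave the global RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_compound_table(sc)); after <- runif(1)
  expect_identical(before, after)
})

test_that("scenario validation rejects infeasible settings", {
  expect_error(synthetic_scenario(planted_overlap_size = 300,
                                  target_union_size = 290),
               "overlap larger")
  expect_error(synthetic_scenario(gene_universe_size = 100,
                                  disease_set_size = 90,
                                  target_union_size = 50,
                                  planted_overlap_size = 10),
               "do not fit")
  sc <- synthetic_scenario(ppi = list(n_nodes = 50, n_planted_hubs = 5,
                                      p_within_hub_core = 0.01,
                                      p_background = 0.02))
  expect_error(gen_ppi_with_planted_hubs(sc), "identifiable")
  sc2 <- synthetic_scenario(annotation = list(n_terms = 5,
                                              term_size_range = c(5L, 10L),
                                              n_planted = 1L,
                                              enrichment_odds = 1))
  expect_error(gen_annotation_with_planted_terms(sc2, "GENE00001"),
               "exceed 1")
})

test_that("compound generation plants the exact number of passers", {
  sc <- synthetic_scenario(seed = 7, n_compounds = 100, pass_fraction = 0.2)
  out <- gen_compound_table(sc)
  res <- screen_compounds(out$records)
  expect_equal(nrow(res$passing), 20L)
  expect_setequal(res$passing$compound_id,
                  out$manifest$compound_id[out$manifest$expected_pass])
  # each failer violates exactly the recorded criterion
  fails <- out$manifest[!out$manifest$expected_pass, ]
  for (i in seq_len(nrow(fails))) {
    v <- res$verdicts[fails$compound_id[i], 1:8]
    expect_equal(names(v)[!v], fails$violated[i])
  }

  none <- gen_compound_table(
    synthetic_scenario(seed = 7, n_compounds = 50, pass_fraction = 0))
  expect_false(any(screen_compounds(none$records)$verdicts[, "pass"]))
})

test_that("planted hubs dominate the degree ranking", {
  sc <- synthetic_scenario(seed = 11)
  out <- gen_ppi_with_planted_hubs(sc)
  tab <- centrality_table(induce_network(out$network, out$network$nodes))
  expect_setequal(head(tab$gene, 10), out$manifest)
  expect_gte(hub_recovery_jaccard(select_hub_genes(tab), out$manifest), 0.8)
})

test_that("zero background probability leaves a union of hub stars", {
  sc <- synthetic_scenario(ppi = list(n_nodes = 40, n_planted_hubs = 4,
                                      p_within_hub_core = 0.6,
                                      p_background = 0))
  out <- gen_ppi_with_planted_hubs(sc)
  e <- out$network$edges
  expect_true(all(e$gene_a %in% out$manifest | e$gene_b %in% out$manifest))
})

test_that("the planted Venn overlap is recovered exactly", {
  sc <- synthetic_scenario(seed = 19)
  out <- gen_disease_and_targets(sc)
  targets <- aggregate_targets(out$links)
  disease <- union_disease_genes(out$disease_lists)
  venn <- intersect_targets(targets, disease)
  expect_equal(venn$size_intersection, 239L)
  expect_identical(venn$members_intersection$genes, out$manifest$overlap)

  none <- synthetic_scenario(seed = 19, planted_overlap_size = 0)
  out0 <- gen_disease_and_targets(none)
  v0 <- intersect_targets(aggregate_targets(out0$links),
                          union_disease_genes(out0$disease_lists))
  expect_equal(v0$size_intersection, 0L)
})

test_that("scenario bundles materialize every reader dialect", {
  sc <- synthetic_scenario(seed = 23, n_compounds = 50, pass_fraction = 0.2,
                           target_union_size = 60, disease_set_size = 100,
                           planted_overlap_size = 40,
                           ppi = list(n_nodes = 60, n_planted_hubs = 5,
                                      p_within_hub_core = 0.5,
                                      p_background = 0.03))
  dir <- withr::local_tempdir()
  write_scenario_bundle(sc, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "compounds.tsv", "target_links.tsv", "ppi_edges.tsv",
    "annotation_bp.gmt", "scenario.yaml", "manifest.json")))))
  expect_equal(nrow(read_compound_table(file.path(dir, "compounds.tsv"))), 50L)
  expect_s3_class(read_ppi_edges(file.path(dir, "ppi_edges.tsv"),
                                 "string_0_1000", 700), "ppi_network")
  expect_s3_class(read_gmt(file.path(dir, "annotation_bp.gmt"), "BP"),
                  "annotation_db")
})
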