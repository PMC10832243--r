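tiny_net <- function(edges, nodes = NULL) {
  ppi_network(edges, nodes = nodes, dialect = "unit_interval")
}

path3 <- tiny_net(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                             score = 1))

test_that("network induction keeps isolates and filters edges", {
  triangle <- tiny_net(data.frame(gene_a = c("A", "A", "B"),
                                  gene_b = c("B", "C", "C"), score = 1))
  sub <- induce_network(triangle, c("A", "B"))
  expect_equal(sub$nodes, c("A", "B"))
  expect_equal(nrow(sub$edges), 1L)
  expect_equal(sub$n_isolates, 0L)

  apart <- induce_network(triangle, c("X", "Y"))
  expect_equal(apart$nodes, c("X", "Y"))
  expect_equal(nrow(apart$edges), 0L)
  expect_equal(apart$n_isolates, 2L)

  expect_error(induce_network(triangle, character()), "empty gene set")

  set.seed(23)
  for (rep in 1:5) {
    net <- rand_ppi(20, 0.3, seed = rep)
    keep <- sample(net$nodes, 8)
    sub <- induce_network(net, keep)
    brute <- net$edges[net$edges$gene_a %in% keep &
                         net$edges$gene_b %in% keep, ]
    expect_setequal(paste(sub$edges$gene_a, sub$edges$gene_b),
                    paste(brute$gene_a, brute$gene_b))
  }
})

test_that("degree follows its convention and the handshake lemma", {
  expect_equal(degree_centrality(path3, "simple")[["B"]], 2L)
  expect_equal(degree_centrality(path3, "doubled")[["B"]], 4L)
  iso <- tiny_net(NULL, nodes = "X")
  expect_equal(degree_centrality(iso, "simple")[["X"]], 0L)
  expect_equal(degree_centrality(iso, "doubled")[["X"]], 0L)
  for (seed in 1:5) {
    net <- rand_ppi(sample(5:25, 1), runif(1, 0.1, 0.5), seed = seed)
    expect_equal(sum(degree_centrality(net, "simple")), 2L * nrow(net$edges))
  }
})

test_that("betweenness matches its closed forms", {
  b <- betweenness_centrality(path3)
  expect_equal(b[["B"]], 1.0)
  expect_equal(b[["A"]], 0.0)

  star <- tiny_net(data.frame(gene_a = "HUB", gene_b = paste0("L", 1:4),
                              score = 1))
  bs <- betweenness_centrality(star)
  expect_equal(bs[["HUB"]], 1.0)
  expect_equal(unname(bs[paste0("L", 1:4)]), rep(0, 4))

  pair <- tiny_net(data.frame(gene_a = "A", gene_b = "B", score = 1))
  expect_equal(unname(betweenness_centrality(pair)), c(0, 0))
})

test_that("closeness matches its closed forms and scores isolates zero", {
  cl <- closeness_centrality(path3)
  expect_equal(cl[["B"]], 1.0)
  expect_equal(cl[["A"]], 2 / 3)

  path4 <- tiny_net(data.frame(gene_a = c("A", "B", "C"),
                               gene_b = c("B", "C", "D"), score = 1))
  expect_equal(closeness_centrality(path4)[["A"]], 0.5)

  with_iso <- tiny_net(data.frame(gene_a = "A", gene_b = "B", score = 1),
                       nodes = c("A", "B", "Z"))
  expect_equal(closeness_centrality(with_iso)[["Z"]], 0)
})

test_that("centralities agree with exhaustive brute-force oracles", {
  for (seed in 1:25) {
    net <- rand_ppi(sample(4:30, 1), runif(1, 0.05, 0.6), seed = 1000 + seed)
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-9)
    expect_equal(closeness_centrality(net), oracle_closeness(net),
                 tolerance = 1e-9)
    expect_identical(degree_centrality(net, "simple"), oracle_degree(net))
  }
})

test_that("tree leaves have zero betweenness and a dominating node closeness 1", {
  set.seed(8)
  # random tree by sequential attachment
  n <- 15
  parent <- c(NA, sample.int(n - 1, n - 1, replace = TRUE))
  parent[2:n] <- vapply(2:n, function(i) sample(seq_len(i - 1), 1), 1L)
  nodes <- sprintf("T%02d", 1:n)
  tree <- tiny_net(data.frame(gene_a = nodes[2:n], gene_b = nodes[parent[2:n]],
                              score = 1))
  deg <- degree_centrality(tree, "simple")
  b <- betweenness_centrality(tree)
  expect_true(all(b[names(deg)[deg == 1]] == 0))

  star <- tiny_net(data.frame(gene_a = "HUB", gene_b = paste0("L", 1:6),
                              score = 1))
  expect_equal(closeness_centrality(star)[["HUB"]], 1.0)
  expect_true(all(betweenness_centrality(star) >= 0 &
                    betweenness_centrality(star) <= 1))
})

test_that("median cutoffs use the even-count mean convention", {
  tab <- data.frame(gene = letters[1:3], degree = c(1, 2, 3),
                    betweenness = c(0.1, 0.2, 0.3), closeness = c(0.4, 0.5, 0.6))
  expect_equal(median_cutoffs(tab)$degree, 2)
  tab4 <- rbind(tab, data.frame(gene = "d", degree = 4, betweenness = 0.4,
                                closeness = 0.7))
  expect_equal(median_cutoffs(tab4)$degree, 2.5)
  expect_error(median_cutoffs(tab[0, ]), "empty")

  set.seed(9)
  for (rep in 1:5) {
    x <- sample(1:100, 11)
    t1 <- data.frame(gene = sprintf("g%02d", 1:11), degree = x,
                     betweenness = runif(11), closeness = runif(11))
    m <- median_cutoffs(t1)
    expect_equal(m$degree, sort(x)[6])  # sort-and-pick oracle, odd count
    expect_equal(m$betweenness, mean(sort(t1$betweenness)[6]))
  }
})

test_that("hub selection respects strictness and deterministic ordering", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    degree = c(10, 10, 10, 10),
                    betweenness = c(0.2, 0.2, 0.2, 0.2),
                    closeness = c(0.5, 0.5, 0.5, 0.5))
  med <- median_cutoffs(tab)
  expect_equal(nrow(select_hub_genes(tab, med, "strict")$hubs), 0L)
  expect_equal(nrow(select_hub_genes(tab, med, "inclusive")$hubs), 4L)

  set.seed(10)
  for (rep in 1:5) {
    t1 <- data.frame(gene = sprintf("g%02d", 1:20),
                     degree = sample(1:50, 20, TRUE),
                     betweenness = runif(20), closeness = runif(20))
    med <- median_cutoffs(t1)
    strict <- select_hub_genes(t1, med, "strict")$hubs$gene
    incl <- select_hub_genes(t1, med, "inclusive")$hubs$gene
    expect_true(all(strict %in% incl))
  }

  sel <- select_hub_genes(data.frame(
    gene = c("Z", "A", "M"), degree = c(8, 8, 9),
    betweenness = c(0.3, 0.4, 0.1), closeness = c(0.9, 0.9, 0.9)),
    list(degree = 1, betweenness = 0.01, closeness = 0.1), "strict")
  expect_equal(sel$hubs$gene, c("M", "A", "Z"))
})

test_that("hub selections export with their medians", {
  net <- rand_ppi(15, 0.4, seed = 44)
  tab <- centrality_table(net)
  sel <- select_hub_genes(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hub_selection(sel, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(sel$hubs))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$strictness, "strict")
  expect_equal(meta$n_hubs, nrow(sel$hubs))
})
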