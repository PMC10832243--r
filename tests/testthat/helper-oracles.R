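# Brute-force oracles, deliberately independent of the package's (and
# igraph's) algorithms: distances by Floyd-Warshall, path counts by
# distance-layer dynamic programming, betweenness by the pair-dependency
# formula, hypergeometric tails by subset enumeration.

adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e)) {
    A[cbind(e$gene_a, e$gene_b)] <- 1L
    A[cbind(e$gene_b, e$gene_a)] <- 1L
  }
  A
}

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# sigma[s, t] = number of distinct shortest s-t paths
oracle_sigma <- function(A, d) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    ds <- d[s, ]
    maxL <- max(c(0, ds[is.finite(ds)]))
    for (L in seq_len(maxL)) {
      prev <- which(ds == L - 1)
      for (t in which(ds == L)) {
        sig[t] <- sum(sig[prev][A[prev, t] > 0])
      }
    }
    sigma[s, ] <- sig
  }
  sigma
}

oracle_betweenness <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  out <- stats::setNames(rep(0, n), net$nodes)
  if (n < 3) return(out)
  d <- oracle_distances(A)
  sigma <- oracle_sigma(A, d)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    out[v] <- acc / ((n - 1) * (n - 2) / 2)
  }
  out
}

oracle_closeness <- function(net) {
  A <- adj_matrix(net)
  d <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    if (!length(reach)) 0 else length(reach) / sum(reach)
  }, numeric(1)) |> stats::setNames(net$nodes)
}

oracle_degree <- function(net) {
  A <- adj_matrix(net)
  stats::setNames(as.integer(rowSums(A)), net$nodes)
}

# Erdos-Renyi test graph as a ppi_network (unit-interval dialect)
rand_ppi <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      score = rep(1, sum(keep)), stringsAsFactors = FALSE)
  ppi_network(edges, nodes = nodes, dialect = "unit_interval")
}

# P(X >= k) by enumerating every size-n draw from a 1..N urn with K
# marked elements; returns the full tail vector indexed by k = 0..min(n,K)
enum_hypergeom_tail <- function(n, K, N) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(cols) sum(cols <= K))
  vapply(0:min(n, K), function(k) mean(hits >= k), numeric(1))
}
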