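#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` where `X` is the number of query
#' genes falling in a term of size `K`, for a query of size `n` drawn
#' from a background of size `N` (`X ~ hypergeometric(N, K, n)`).
#' Evaluated through the hypergeometric tail in log space for
#' numerical stability; `k = 0` gives exactly 1.
#'
#' Non-increasing in `k` for fixed `(n, K, N)`.
#'
#' @param k number of query genes in the term (hits).
#' @param n query size.
#' @param K term size.
#' @param N background size.
#' @return the tail probability; vectorized over `k`.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (any(n > N) || any(K > N) || any(k < 0) || any(k > pmin(n, K))) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(n, K) <= N")
  }
  # upper tail P(X >= k) = 1 - P(X <= k - 1), stabilized via log
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, takes
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, and returns the
#' adjusted values in the input order.  Invariant to input order (up to
#' re-ordering) and never below the raw p-value.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term with at least one query hit with the
#' one-sided hypergeometric over-representation test, adjusts p-values
#' with Benjamini-Hochberg within each namespace, and keeps terms with
#' adjusted p strictly below `alpha`.  The background defaults to all
#' genes of the annotation database (`background_policy = "annotation"`);
#' an explicit background may be supplied instead.  Query genes outside
#' the background cannot be hits and are excluded from the query size.
#'
#' @param query `gene_set` or character vector of normalized symbols.
#' @param db an [annotation_db()].
#' @param background_policy `"annotation"` or `"custom"`.
#' @param background character vector, required for
#'   `background_policy = "custom"`; must contain all term genes.
#' @param alpha significance cutoff on the BH-adjusted p-value, strict;
#'   set `alpha = 1` to keep every tested term (e.g. for ranking).
#' @return `data.frame` of class `enrichment_result` with one row per
#'   retained term: `term_id`, `term_name`, `namespace`, `hit_count`,
#'   `term_size`, `query_size`, `background_size`, `p_raw`, `p_adj`,
#'   `pct_associated` (= 100 * hits / term size), sorted by `p_adj`
#'   ascending then `term_id`.
#' @export
enrich_gene_set <- function(query, db,
                            background_policy = c("annotation", "custom"),
                            background = NULL, alpha = 0.001) {
  background_policy <- match.arg(background_policy)
  stopifnot(inherits(db, "annotation_db"), alpha > 0, alpha <= 1)
  q <- if (inherits(query, "gene_set")) query$genes else
    sort(unique(toupper(query)))
  bg <- if (background_policy == "annotation") db$background else {
    if (is.null(background)) stop("custom background_policy needs a background")
    sort(unique(toupper(background)))
  }
  if (!all(unlist(db$terms$genes) %in% bg)) {
    stop("annotation term genes outside the background")
  }
  q <- intersect(q, bg)
  N <- length(bg)
  n <- length(q)
  hits <- vapply(db$terms$genes, function(g) length(intersect(g, q)),
                 integer(1))
  tested <- which(hits >= 1L)
  res <- data.frame(
    term_id = db$terms$term_id[tested],
    term_name = db$terms$term_name[tested],
    namespace = db$terms$namespace[tested],
    hit_count = hits[tested],
    term_size = lengths(db$terms$genes)[tested],
    query_size = rep(n, length(tested)),
    background_size = rep(N, length(tested)),
    stringsAsFactors = FALSE)
  if (nrow(res) == 0L) {
    res$p_raw <- res$p_adj <- res$pct_associated <- numeric(0)
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  res$p_raw <- hypergeom_pvalue(res$hit_count, n, res$term_size, N)
  res$p_adj <- NA_real_
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$p_adj[sel] <- bh_adjust(res$p_raw[sel])
  }
  res$pct_associated <- 100 * res$hit_count / res$term_size
  # alpha = 1 keeps every tested term (for ranking); otherwise strict <
  if (alpha < 1) res <- res[res$p_adj < alpha, , drop = FALSE]
  res <- res[order(res$p_adj, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Bubble-chart table of enrichment results
#'
#' The export behind the usual over-representation bubble plot:
#' `% associated genes` on the x-axis, term name on the y-axis, dot
#' size the hit count, color `-log10` of the adjusted p-value.  Row
#' order follows the (deterministic) result order.
#'
#' @param results an `enrichment_result` (non-empty).
#' @return `data.frame` with columns `term_name`, `pct_associated`,
#'   `hit_count`, `neg_log10_p_adj`.
#' @export
bubble_data <- function(results) {
  stopifnot(inherits(results, "enrichment_result"))
  if (nrow(results) == 0L) stop("no enrichment results to plot")
  data.frame(term_name = results$term_name,
             pct_associated = results$pct_associated,
             hit_count = results$hit_count,
             neg_log10_p_adj = -log10(results$p_adj),
             stringsAsFactors = FALSE)
}

#' Write enrichment results as TSV
#'
#' @param results an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
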