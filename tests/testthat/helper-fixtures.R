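# shared fixtures and independent oracles, built in code

toy_sheet <- function(n_per_group = 4) {
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("high", "low"), each = n_per_group))
}

toy_counts <- function(mat, ids = sprintf("g%d", seq_len(nrow(mat))),
                       samples = sprintf("S%02d", seq_len(ncol(mat)))) {
  colnames(mat) <- samples
  dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(mat))
}

# brute-force hypergeometric upper tail: enumerate every size-n draw from N
# items of which the first K are marked, count draws with overlap >= k
enum_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# naive average-rank Spearman, independent of base rank()
naive_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# hand-constructed cerna_network (for graph-contract tests on arbitrary
# topologies); degrees and hub flags computed from the edge list
make_net <- function(edges, classes = NULL, directions = NULL) {
  ids <- unique(c(edges$source, edges$target))
  deg <- table(factor(c(edges$source, edges$target), levels = ids))
  nodes <- tibble::tibble(
    id = ids,
    class = if (is.null(classes)) "mRNA" else unname(classes[ids]),
    direction = if (is.null(directions)) "up" else unname(directions[ids]),
    degree = as.integer(deg[ids]))
  nodes$is_hub <- nodes$degree > mean(nodes$degree)
  net <- list(nodes = nodes, edges = edges)
  class(net) <- "cerna_network"
  net
}

# minimal classified DE tibbles for correlation-stage fixtures
fake_de <- function(ids, directions = rep("up", length(ids))) {
  tibble::tibble(feature_id = ids, significant = TRUE, direction = directions)
}
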