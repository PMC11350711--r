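#' Export a ceRNA network for Cytoscape
#'
#' Writes the network in one of three dialects Cytoscape opens directly:
#'
#' * `edge_tsv` — a tab-separated edge table (`source`, `target`,
#'   `edge_type`, `scc`, `regulation`) at `path`, plus a node table
#'   (`id`, `class`, `direction`, `degree`, `is_hub`) next to it with a
#'   `_nodes.tsv` suffix;
#' * `sif` — simple interaction format, one `source edge_type target` line
#'   per edge (tab-separated tokens);
#' * `graphml` — GraphML with all node and edge attributes, via igraph.
#'
#' The network is validated before writing. Empty networks produce valid
#' files with headers (or an empty SIF).
#'
#' @param net A `cerna_network`.
#' @param path Output path.
#' @param dialect `"edge_tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("edge_tsv", "sif", "graphml")) {
  dialect <- match.arg(dialect)
  validate_cerna_network(net)
  switch(dialect,
    edge_tsv = {
      readr::write_tsv(net$edges, path, progress = FALSE)
      readr::write_tsv(net$nodes, nodes_path(path), progress = FALSE)
    },
    sif = {
      lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                       net$edges$target)
      writeLines(lines, path)
    },
    graphml = {
      g <- if (nrow(net$nodes) > 0) as_igraph(net) else
        igraph::make_empty_graph(0, directed = FALSE)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

nodes_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_nodes.tsv", path)
}

#' Read back an exported edge table
#'
#' Round-trip companion of `write_network(..., dialect = "edge_tsv")`.
#'
#' @param path Path written by [write_network()].
#' @return The edge tibble.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    source = readr::col_character(),
                    target = readr::col_character(),
                    edge_type = readr::col_character(),
                    scc = readr::col_double(),
                    regulation = readr::col_character()))
}
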