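#' Assemble the tripartite ceRNA network
#'
#' Builds the lncRNA-miRNA-mRNA graph implied by the final ceRNA pairs:
#' for each final pair, its lncRNA and mRNA nodes, every shared (witness)
#' miRNA with the two supporting miRNA edges, and (by default) the
#' lncRNA-mRNA edge itself. Node regulation direction comes from the DE
#' results; an id without a DE record is a hard error, since it indicates a
#' pipeline ordering bug. Each edge carries the Spearman correlation of its
#' endpoints and a `regulation` attribute: the DE direction of the
#' non-miRNA endpoint for miRNA edges, and of the mRNA for lncRNA-mRNA
#' edges.
#'
#' @param final_pairs `cerna_pairs` tibble; only rows with `final` are used.
#' @param mirna_pairs Result of [filter_mirna_pairs()] (for the witness
#'   edges' correlations).
#' @param de Named list of classified `de_results` (`mRNA`, `miRNA`,
#'   `lncRNA`).
#' @param include_lnc_mrna_edges Include the lncRNA-mRNA edges themselves?
#'   Default `TRUE`.
#' @return A `cerna_network` object: a list with tibbles `nodes`
#'   (`id`, `class`, `direction`, `degree`, `is_hub`) and `edges`
#'   (`source`, `target`, `edge_type`, `scc`, `regulation`).
#' @export
build_cerna_network <- function(final_pairs, mirna_pairs, de,
                                include_lnc_mrna_edges = TRUE) {
  finals <- filter(as_tibble(final_pairs), .data$final)
  dirs <- bind_rows(lapply(names(de), function(cl) {
    tibble(id = de[[cl]]$feature_id, class = cl,
           direction = de[[cl]]$direction)
  }))
  passing <- filter(mirna_pairs, .data$passes)
  pair_scc <- setNames(passing$scc,
                       paste(passing$mirna_id, passing$target_id))

  if (nrow(finals) == 0) {
    net <- list(nodes = tibble(id = character(), class = character(),
                               direction = character(), degree = integer(),
                               is_hub = logical()),
                edges = tibble(source = character(), target = character(),
                               edge_type = character(), scc = numeric(),
                               regulation = character()))
    class(net) <- "cerna_network"
    return(net)
  }

  dir_of <- setNames(dirs$direction, dirs$id)
  need <- unique(c(finals$lncrna_id, finals$mrna_id,
                   unlist(finals$shared_mirnas)))
  missing <- setdiff(need, dirs$id)
  if (length(missing) > 0) {
    abort(sprintf("no DE record for node(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }

  edges <- purrr::pmap_dfr(
    select(finals, "lncrna_id", "mrna_id", "shared_mirnas", "scc"),
    function(lncrna_id, mrna_id, shared_mirnas, scc) {
      mi <- shared_mirnas
      e <- bind_rows(
        tibble(source = lncrna_id, target = mi, edge_type = "lncRNA-miRNA",
               scc = unname(pair_scc[paste(mi, lncrna_id)]),
               regulation = unname(dir_of[lncrna_id])),
        tibble(source = mi, target = mrna_id, edge_type = "miRNA-mRNA",
               scc = unname(pair_scc[paste(mi, mrna_id)]),
               regulation = unname(dir_of[mrna_id])))
      if (include_lnc_mrna_edges) {
        e <- bind_rows(e, tibble(source = lncrna_id, target = mrna_id,
                                 edge_type = "lncRNA-mRNA", scc = scc,
                                 regulation = unname(dir_of[mrna_id])))
      }
      e
    })
  edges <- distinct(edges)

  class_of <- setNames(dirs$class, dirs$id)
  ids <- unique(c(edges$source, edges$target))
  deg <- table(factor(c(edges$source, edges$target), levels = ids))
  nodes <- tibble(id = ids,
                  class = unname(class_of[ids]),
                  direction = unname(dir_of[ids]),
                  degree = as.integer(deg[ids]))
  nodes <- arrange(nodes, .data$class, .data$id)

  net <- list(nodes = nodes, edges = edges)
  class(net) <- "cerna_network"
  net$nodes$is_hub <- net$nodes$id %in% hub_nodes(net)
  validate_cerna_network(net)
}

#' Highly connected (hub) nodes
#'
#' Nodes whose degree strictly exceeds the arithmetic mean degree of the
#' entire network (all classes pooled). On a regular graph — for example a
#' triangle, or a single edge — no node exceeds the mean, so the hub set is
#' empty.
#'
#' @param net A `cerna_network`.
#' @return Character vector of hub node ids.
#' @export
hub_nodes <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  if (nrow(net$nodes) == 0) return(character())
  net$nodes$id[net$nodes$degree > mean(net$nodes$degree)]
}

#' Validate network structural invariants
#'
#' Checks the degree-sum identity (`sum(degree) == 2 * n_edges`), that every
#' lncRNA-mRNA edge is witnessed by at least one miRNA with both supporting
#' edges present, and that the hub set obeys the strict mean-degree rule.
#' Called on every build and export.
#'
#' @param net A `cerna_network`.
#' @return `net`, invisibly validated.
#' @export
validate_cerna_network <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  if (sum(net$nodes$degree) != 2L * nrow(net$edges)) {
    abort("degree-sum identity violated")
  }
  lm <- filter(net$edges, .data$edge_type == "lncRNA-mRNA")
  if (nrow(lm) > 0) {
    lnc_mi <- filter(net$edges, .data$edge_type == "lncRNA-miRNA")
    mi_mr <- filter(net$edges, .data$edge_type == "miRNA-mRNA")
    ok <- purrr::map2_lgl(lm$source, lm$target, function(l, m) {
      wit <- intersect(lnc_mi$target[lnc_mi$source == l],
                       mi_mr$source[mi_mr$target == m])
      length(wit) >= 1
    })
    if (!all(ok)) abort("lncRNA-mRNA edge without a witnessing miRNA path")
  }
  if (!setequal(hub_nodes(net), net$nodes$id[net$nodes$is_hub])) {
    abort("hub flags inconsistent with the mean-degree rule")
  }
  invisible(net)
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("<cerna_network>\n")
  print(glance.cerna_network(x))
  invisible(x)
}

#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) as_tibble(x$edges)

#' One-row summary of a ceRNA network
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return A tibble with node counts per class, edge counts per type, and
#'   the number of hubs.
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  cls <- table(factor(x$nodes$class, levels = RNA_CLASSES))
  typ <- table(factor(x$edges$edge_type,
                      levels = c("lncRNA-miRNA", "miRNA-mRNA", "lncRNA-mRNA")))
  tibble(n_nodes = nrow(x$nodes),
         n_mrna = as.integer(cls["mRNA"]),
         n_mirna = as.integer(cls["miRNA"]),
         n_lncrna = as.integer(cls["lncRNA"]),
         n_edges = nrow(x$edges),
         n_lncrna_mirna_edges = as.integer(typ["lncRNA-miRNA"]),
         n_mirna_mrna_edges = as.integer(typ["miRNA-mRNA"]),
         n_lncrna_mrna_edges = as.integer(typ["lncRNA-mRNA"]),
         mean_degree = if (nrow(x$nodes)) mean(x$nodes$degree) else NA_real_,
         n_hubs = sum(x$nodes$is_hub))
}

#' Text report of a ceRNA network
#'
#' Node counts per class, edge counts per type, and the hub list, printed
#' to the console.
#'
#' @param net A `cerna_network`.
#' @return The [glance()] row, invisibly.
#' @export
network_report <- function(net) {
  g <- glance.cerna_network(net)
  cat(sprintf("ceRNA network: %d nodes (%d mRNA, %d miRNA, %d lncRNA), %d edges\n",
              g$n_nodes, g$n_mrna, g$n_mirna, g$n_lncrna, g$n_edges))
  cat(sprintf("  edges: %d lncRNA-miRNA, %d miRNA-mRNA, %d lncRNA-mRNA\n",
              g$n_lncrna_mirna_edges, g$n_mirna_mrna_edges,
              g$n_lncrna_mrna_edges))
  cat(sprintf("  mean degree %.2f; hubs (> mean): %s\n", g$mean_degree,
              if (g$n_hubs) paste(hub_nodes(net), collapse = ", ") else "none"))
  invisible(g)
}

#' Plot a ceRNA network
#'
#' Fruchterman-Reingold layout with the conventional colouring: red mRNAs,
#' blue miRNAs, green lncRNAs; hubs drawn larger.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nd <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    left_join(select(nd, "id", xs = "x", ys = "y"), by = c(source = "id")) |>
    left_join(select(nd, "id", xe = "x", ye = "y"), by = c(target = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xs, y = .data$ys,
                                       xend = .data$xe, yend = .data$ye,
                                       linetype = .data$edge_type),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$class,
                                     size = .data$is_hub)) +
    ggplot2::scale_colour_manual(values = c(mRNA = "#c0392b",
                                            miRNA = "#2980b9",
                                            lncRNA = "#27ae60")) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::theme_void()
}

#' Convert a ceRNA network to an igraph object
#'
#' @param net A `cerna_network`.
#' @return An undirected igraph graph with all node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}
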