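# Signed co-activity network assembly: threshold the correlation results,
# attach node attributes, count edge signs and modules, and export in
# Cytoscape-friendly formats.

#' Build a signed co-activity network
#'
#' Keeps the taxon pairs whose Spearman rho clears the magnitude threshold
#' and whose p-value clears the significance gate, then assembles an
#' undirected signed graph. Nodes are the taxa incident to at least one kept
#' edge, carrying mean relative activity and core / non-core membership when
#' supplied.
#'
#' The default gate uses the FDR-adjusted q-value (`q < alpha`); `gate =
#' "raw"` switches to unadjusted p-values, matching the looser reading of
#' the selection rule.
#'
#' @param results tibble from [spearman_matrix()] (taxon_i, taxon_j, rho, p,
#'   q) for one condition and gut section.
#' @param node_attrs optional tibble with `taxon_id` and any of
#'   `mean_relative_activity`, `membership` to attach to nodes.
#' @param rho_min magnitude threshold (default 0.4).
#' @param alpha significance level (default 0.05).
#' @param gate `"fdr"` (default) or `"raw"`.
#' @param condition,gut_section labels stored on the network.
#' @return an object of class `coactivity_network`: list with `nodes` and
#'   `edges` tibbles, the thresholds, and edge-sign tallies.
#' @export
build_network <- function(results, node_attrs = NULL,
                          rho_min = 0.4, alpha = 0.05,
                          gate = c("fdr", "raw"),
                          condition = NA_character_,
                          gut_section = NA_character_) {
  gate <- match.arg(gate)
  results <- as_tibble(results)
  stopifnot(rho_min >= 0, alpha > 0, alpha <= 1)
  if (nrow(results)) {
    pgate <- if (gate == "fdr") results$q else results$p
    keep <- !is.na(results$rho) & abs(results$rho) >= rho_min &
      !is.na(pgate) & pgate < alpha
    edges <- results[keep, c("taxon_i", "taxon_j", "rho", "p", "q")]
  } else {
    edges <- tibble(taxon_i = character(), taxon_j = character(),
                    rho = numeric(), p = numeric(), q = numeric())
  }
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  node_ids <- sort(unique(c(edges$taxon_i, edges$taxon_j)))
  nodes <- tibble(taxon_id = node_ids,
                  mean_relative_activity = NA_real_,
                  membership = "other")
  if (!is.null(node_attrs) && nrow(nodes)) {
    node_attrs <- as_tibble(node_attrs)
    idx <- match(nodes$taxon_id, node_attrs$taxon_id)
    if ("mean_relative_activity" %in% names(node_attrs)) {
      nodes$mean_relative_activity <- node_attrs$mean_relative_activity[idx]
    }
    if ("membership" %in% names(node_attrs)) {
      nodes$membership <- dplyr::coalesce(node_attrs$membership[idx],
                                          "other")
    }
  }
  structure(
    list(condition = condition, gut_section = gut_section,
         nodes = nodes, edges = edges,
         n_positive = sum(edges$sign == "+"),
         n_negative = sum(edges$sign == "-"),
         interacting_taxa = nrow(nodes),
         rho_min = rho_min, alpha = alpha, gate = gate),
    class = "coactivity_network")
}

#' @export
print.coactivity_network <- function(x, ...) {
  cat(sprintf(
    "<coactivity_network> %s / %s: %d interacting taxa, %d edges (%d+, %d-), %d modules\n",
    x$condition, x$gut_section, x$interacting_taxa, nrow(x$edges),
    x$n_positive, x$n_negative, count_modules(x)))
  invisible(x)
}

#' @rdname build_network
#' @param x a `coactivity_network`.
#' @param ... unused.
#' @export
tidy.coactivity_network <- function(x, ...) {
  x$edges
}

#' @rdname build_network
#' @export
glance.coactivity_network <- function(x, ...) {
  tibble(condition = x$condition, gut_section = x$gut_section,
         interacting_taxa = x$interacting_taxa,
         n_edges = nrow(x$edges),
         n_positive = x$n_positive, n_negative = x$n_negative,
         n_modules = count_modules(x))
}

as_igraph <- function(network) {
  stopifnot(inherits(network, "coactivity_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[c("taxon_i", "taxon_j", "rho", "p", "q", "sign")],
    directed = FALSE,
    vertices = network$nodes)
  g
}

#' Number of network modules
#'
#' Modules are the connected components among interacting nodes — the
#' reading under which pesticide-perturbed networks fragment and
#' supplementation re-connects them.
#'
#' @param network a `coactivity_network`.
#' @return integer component count (0 for an empty network).
#' @export
count_modules <- function(network) {
  if (nrow(network$nodes) == 0) return(0L)
  igraph::components(as_igraph(network))$no
}

#' Export a network for Cytoscape
#'
#' Writes the edge list as TSV, the graph as GraphML, or the Cytoscape SIF
#' format with a companion node-attribute TSV (activity, membership,
#' degree), so published-style figures can be rebuilt.
#'
#' @param network a `coactivity_network`.
#' @param path output file path (for SIF, the node-attribute table is
#'   written next to it with suffix `.nodes.tsv`).
#' @return `path`, invisibly.
#' @name network_export
#' @export
write_edge_tsv <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' @rdname network_export
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname network_export
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  rel <- ifelse(e$sign == "+", "pos", "neg")
  writeLines(sprintf("%s\t%s\t%s", e$taxon_i, rel, e$taxon_j), path)
  deg <- node_metrics(network)
  attrs <- dplyr::left_join(network$nodes,
                            deg[c("taxon_id", "degree")], by = "taxon_id")
  readr::write_tsv(attrs, paste0(path, ".nodes.tsv"))
  invisible(path)
}

#' Plot a co-activity network
#'
#' Fruchterman-Reingold layout; node size proportional to mean relative
#' activity, edge colour by correlation sign (green positive, red negative),
#' node shade by degree — the conventions of the published network figures.
#'
#' @param object a `coactivity_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coactivity_network <- function(object, seed = 1, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "empty network") +
             ggplot2::theme_void())
  }
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  met <- node_metrics(object)
  nodes$degree <- met$degree[match(nodes$taxon_id, met$taxon_id)]
  edges <- object$edges
  ei <- match(edges$taxon_i, nodes$taxon_id)
  ej <- match(edges$taxon_j, nodes$taxon_id)
  seg <- tibble(x = nodes$x[ei], y = nodes$y[ei],
                xend = nodes$x[ej], yend = nodes$y[ej],
                sign = edges$sign)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$sign),
      linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c("+" = "forestgreen",
                                            "-" = "firebrick")) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$mean_relative_activity,
                   fill = .data$degree),
      shape = 21) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$taxon_id),
      vjust = -1, size = 2.5) +
    ggplot2::scale_fill_gradient(low = "grey85", high = "grey20") +
    ggplot2::labs(title = sprintf("%s / %s", object$condition,
                                  object$gut_section),
                  colour = "sign") +
    ggplot2::theme_void()
}
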