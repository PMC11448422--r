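# Per-node topology metrics (degree, closeness centrality, neighborhood
# connectivity) under NetworkAnalyzer conventions, and rank-based comparison
# of their distributions across experimental conditions (Kruskal-Wallis
# omnibus + pairwise Dunn post hoc).

#' Per-node topology metrics
#'
#' For every interacting node of a co-activity network: degree DG (incident
#' edge count, signs ignored), closeness centrality CC (reciprocal of the
#' mean shortest-path distance to the other nodes of the node's connected
#' component, so CC is in (0, 1\] and computed component-wise on
#' disconnected graphs), and neighborhood connectivity NC (mean degree of
#' the node's neighbors). Membership labels are carried through.
#'
#' @param network a `coactivity_network`.
#' @return tibble (taxon_id, membership, degree, closeness_centrality,
#'   neighborhood_connectivity), one row per node.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "coactivity_network"))
  if (nrow(network$nodes) == 0) {
    return(tibble(taxon_id = character(), membership = character(),
                  degree = integer(), closeness_centrality = numeric(),
                  neighborhood_connectivity = numeric()))
  }
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  cc <- vapply(seq_len(nrow(d)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) return(0)
    1 / mean(dv)
  }, numeric(1))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  nc <- vapply(seq_len(nrow(adj)), function(v) {
    nb <- which(adj[v, ])
    if (length(nb) == 0) return(0)
    mean(deg[nb])
  }, numeric(1))
  ids <- igraph::V(g)$name
  tibble(taxon_id = ids,
         membership = network$nodes$membership[
           match(ids, network$nodes$taxon_id)],
         degree = as.integer(deg),
         closeness_centrality = cc,
         neighborhood_connectivity = nc)
}

#' Pairwise Dunn post hoc test
#'
#' Dunn's rank-based z test on all unordered group pairs, using the pooled
#' average ranks and the tie-corrected standard error
#' `sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_a + 1/n_b))` with
#' `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values, adjusted
#' across the pair family.
#'
#' @param values numeric vector of pooled observations.
#' @param groups group label per observation.
#' @param p_adjust `"bh"` (default), `"bonferroni"` or `"none"`.
#' @return tibble (group_a, group_b, z, p, p_adj).
#' @export
dunn_test <- function(values, groups, p_adjust = c("bh", "bonferroni",
                                                   "none")) {
  p_adjust <- match.arg(p_adjust)
  groups <- as.character(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  n <- length(values)
  r <- avg_rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  labels <- sort(unique(groups))
  stopifnot(length(labels) >= 2)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- combn(labels, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble(group_a = a, group_b = b, z = z, p = 2 * pnorm(-abs(z)))
  })
  out$p_adj <- switch(p_adjust,
                      bh = p.adjust(out$p, "BH"),
                      bonferroni = p.adjust(out$p, "bonferroni"),
                      none = out$p)
  out
}

#' Compare a topology metric across conditions
#'
#' Pools node-level metric values across conditions, runs a tie-corrected
#' Kruskal-Wallis omnibus test and the pairwise [dunn_test()]. Groups with
#' fewer than two values are excluded with a warning.
#'
#' @param profiles named list of [node_metrics()] tibbles, one per
#'   condition (names are the condition labels), or a single long tibble
#'   with a `condition` column.
#' @param metric one of `"degree"`, `"closeness_centrality"`,
#'   `"neighborhood_connectivity"` (aliases `"DG"`, `"CC"`, `"NC"`).
#' @param p_adjust pairwise adjustment passed to [dunn_test()].
#' @return object of class `topology_comparison`: list with `metric`,
#'   `omnibus` (tibble: statistic, df, p) and `pairwise` (Dunn tibble).
#' @export
compare_topology <- function(profiles, metric = "degree",
                             p_adjust = "bh") {
  metric <- switch(metric, DG = "degree", CC = "closeness_centrality",
                   NC = "neighborhood_connectivity", metric)
  long <- if (is.data.frame(profiles)) {
    as_tibble(profiles)
  } else {
    purrr::imap_dfr(profiles, ~ dplyr::mutate(.x, condition = .y))
  }
  stopifnot("condition" %in% names(long), metric %in% names(long))
  sizes <- table(long$condition)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 nodes: ",
            paste(small, collapse = ", "), call. = FALSE)
    long <- long[!long$condition %in% small, ]
  }
  if (length(unique(long$condition)) < 2) {
    stop("need >= 2 groups with >= 2 nodes each", call. = FALSE)
  }
  kw <- kruskal.test(long[[metric]], factor(long$condition))
  structure(
    list(metric = metric,
         omnibus = tibble(statistic = unname(kw$statistic),
                          df = unname(kw$parameter),
                          p = kw$p.value),
         pairwise = dunn_test(long[[metric]], long$condition,
                              p_adjust = p_adjust),
         data = long),
    class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf("<topology_comparison> %s: Kruskal-Wallis H = %.3f, p = %.3g\n",
              x$metric, x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_topology
#' @param x a `topology_comparison`.
#' @param ... unused.
#' @export
tidy.topology_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, metric = x$metric, .before = 1)
}

#' @rdname compare_topology
#' @export
glance.topology_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, metric = x$metric, .before = 1)
}

#' Slice a topology profile by membership class
#'
#' Groups node-level metric values by membership (core, non-core,
#' low-activity, other) with optional focal genera pulled out as their own
#' slices, as in the published violin panels contrasting core members with
#' the supplemented *Enterobacter* and *Pantoea* strains.
#'
#' @param profile a [node_metrics()] tibble.
#' @param focal_taxa genus names to slice out individually.
#' @return the profile with a `slice` column; unknown focal genera produce
#'   an empty slice with a warning.
#' @export
membership_slices <- function(profile, focal_taxa = character()) {
  profile <- as_tibble(profile)
  missing <- setdiff(focal_taxa, profile$taxon_id)
  if (length(missing)) {
    warning("focal taxa absent from profile: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(profile,
                slice = ifelse(.data$taxon_id %in% focal_taxa,
                               paste0("focal:", .data$taxon_id),
                               .data$membership))
}

#' Violin plot of a topology metric across conditions
#'
#' @param profiles as in [compare_topology()].
#' @param metric metric name or alias.
#' @return a ggplot object.
#' @export
plot_topology <- function(profiles, metric = "degree") {
  metric <- switch(metric, DG = "degree", CC = "closeness_centrality",
                   NC = "neighborhood_connectivity", metric)
  long <- if (is.data.frame(profiles)) {
    as_tibble(profiles)
  } else {
    purrr::imap_dfr(profiles, ~ dplyr::mutate(.x, condition = .y))
  }
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$condition, y = .data[[metric]],
                               fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
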