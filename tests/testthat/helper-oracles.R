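# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the package's own code paths.

# recursive permutation enumeration (independent of the package's
# iterative builder)
oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# brute-force two-sided permutation p for Spearman rho, one cor() call per
# permutation
oracle_spearman_p <- function(x, y) {
  obs <- abs(cor(x, y, method = "spearman"))
  perms <- oracle_permutations(seq_along(x))
  hits <- vapply(perms, function(idx) {
    abs(cor(x[idx], y, method = "spearman")) >= obs - 1e-12
  }, logical(1))
  mean(hits)
}

# direct Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  pmin(q_sorted, 1)[order(ord)]
}

# adjacency list from an edge tibble (taxon_i, taxon_j)
oracle_adjacency <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges$taxon_i[k]; j <- edges$taxon_j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, unique)
}

# all-pairs BFS distances, then degree / closeness (reciprocal mean
# distance within component) / neighborhood connectivity
oracle_metrics <- function(nodes, edges) {
  adj <- oracle_adjacency(nodes, edges)
  deg <- vapply(adj, length, integer(1))
  bfs_dist <- function(src) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d
  }
  cc <- vapply(nodes, function(v) {
    d <- bfs_dist(v)
    reach <- d[names(d) != v & is.finite(d)]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  }, numeric(1))
  nc <- vapply(nodes, function(v) {
    if (deg[v] == 0) 0 else mean(deg[adj[[v]]])
  }, numeric(1))
  data.frame(taxon_id = nodes, degree = as.integer(deg),
             closeness_centrality = unname(cc),
             neighborhood_connectivity = unname(nc))
}

# union-find connected-component count
oracle_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$taxon_i[k]); rj <- find(edges$taxon_j[k])
    if (ri != rj) parent[[ri]] <- rj
  }
  length(unique(vapply(nodes, find, character(1))))
}

# random undirected simple graph as a network object, by pushing a
# synthetic correlation table through build_network with passing stats
random_network <- function(n_nodes, p_edge, seed) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  withr::with_seed(seed, {
    keep <- runif(nrow(pairs)) < p_edge
    res <- tibble::tibble(taxon_i = pairs[keep, 1],
                          taxon_j = pairs[keep, 2],
                          rho = sample(c(-0.9, 0.9), sum(keep), TRUE),
                          p = 1e-6, q = 1e-4)
    build_network(res)
  })
}

# small activity table + metadata for one or two conditions
toy_counts <- function(mat, taxa = sprintf("t%02d", seq_len(nrow(mat))),
                       samples = sprintf("s%02d", seq_len(ncol(mat)))) {
  stopifnot(length(taxa) == nrow(mat), length(samples) == ncol(mat))
  out <- tibble::tibble(taxon_id = taxa)
  for (k in seq_along(samples)) out[[samples[k]]] <- as.integer(mat[, k])
  out
}

toy_metadata <- function(samples, conditions) {
  tibble::tibble(sample_id = samples, condition = conditions,
                 gut_section = "midgut",
                 cage = paste0("cage", rep_len(1:3, length(samples))),
                 replicate = seq_along(samples))
}

# hand product-limit table for a small cohort: returns S at each distinct
# time, computed independently of km_estimate
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (tt in times) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = times, surv = out)
}
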