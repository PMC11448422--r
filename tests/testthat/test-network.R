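res_row <- function(i, j, rho, p, q) {
  tibble::tibble(taxon_i = i, taxon_j = j, rho = rho, p = p, q = q)
}

test_that("edges are kept by the |rho| >= 0.4 and q < 0.05 rules", {
  res <- dplyr::bind_rows(
    res_row("a", "b", 0.40, 0.001, 0.049),   # boundary rho, q just under
    res_row("a", "c", 0.39, 0.0001, 0.001),  # below magnitude threshold
    res_row("b", "c", -0.80, 0.002, 0.051),  # q over alpha
    res_row("c", "d", -0.45, 0.001, 0.01))   # kept, negative
  net <- build_network(res)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(abs(net$edges$rho) >= 0.4))
  expect_equal(net$n_positive, 1)
  expect_equal(net$n_negative, 1)
  expect_equal(net$interacting_taxa, 4)  # a, b, c, d all touch a kept edge
  expect_equal(net$edges$sign, c("+", "-"))
  # raw gate admits the q = 0.051 edge
  raw <- build_network(res, gate = "raw")
  expect_equal(nrow(raw$edges), 3)
})

test_that("hand-enumerated toy network counts match", {
  # 10 taxa, 3 planted significant pairs; everything else null
  taxa <- letters[1:10]
  pairs <- t(combn(taxa, 2))
  res <- tibble::tibble(taxon_i = pairs[, 1], taxon_j = pairs[, 2],
                        rho = 0.1, p = 0.8, q = 0.9)
  planted <- c(3, 17, 40)
  res$rho[planted] <- c(0.9, -0.7, 0.5)
  res$p[planted] <- 1e-4
  res$q[planted] <- 1e-3
  net <- build_network(res)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$interacting_taxa,
               length(unique(c(res$taxon_i[planted],
                               res$taxon_j[planted]))))
  expect_equal(net$n_positive + net$n_negative, nrow(net$edges))
})

test_that("edge set grows monotonically with alpha", {
  withr::with_seed(51, {
    profs <- toy_counts(matrix(rnbinom(12 * 10, mu = 100, size = 1) + 1L,
                               nrow = 12))
  })
  res <- spearman_matrix(profs)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5, 1)
  sizes <- vapply(alphas, function(a) {
    nrow(build_network(res, alpha = a)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # and shrinks monotonically with rho_min
  sizes_r <- vapply(c(0.2, 0.4, 0.6, 0.8), function(r) {
    nrow(build_network(res, rho_min = r, alpha = 0.5)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes_r) <= 0))
})

test_that("module count equals connected components (union-find oracle)", {
  two <- build_network(dplyr::bind_rows(
    res_row("a", "b", 0.9, 1e-4, 1e-3),
    res_row("c", "d", 0.9, 1e-4, 1e-3)))
  expect_equal(count_modules(two), 2)
  empty <- build_network(res_row("a", "b", 0.1, 0.9, 0.9))
  expect_equal(count_modules(empty), 0)
  expect_equal(empty$interacting_taxa, 0)
  for (s in 1:10) {
    net <- random_network(n_nodes = 15, p_edge = 0.12, seed = s)
    if (nrow(net$edges) == 0) next
    expect_equal(count_modules(net),
                 oracle_components(net$nodes$taxon_id, net$edges))
  }
})

test_that("node attributes are carried onto network nodes", {
  attrs <- tibble::tibble(taxon_id = c("a", "b"),
                          mean_relative_activity = c(0.5, 0.2),
                          membership = c("core", "non-core"))
  net <- build_network(res_row("a", "b", 0.9, 1e-4, 1e-3),
                       node_attrs = attrs, condition = "ctl",
                       gut_section = "ileum")
  expect_equal(net$nodes$membership, c("core", "non-core"))
  expect_equal(net$nodes$mean_relative_activity, c(0.5, 0.2))
  g <- glance(net)
  expect_equal(g$condition, "ctl")
  expect_equal(g$n_edges, 1)
  expect_equal(tidy(net), net$edges)
})

test_that("exports round-trip through edge TSV, GraphML and SIF", {
  net <- random_network(10, 0.3, seed = 3)
  f_tsv <- tempfile(fileext = ".tsv")
  write_edge_tsv(net, f_tsv)
  back <- readr::read_tsv(f_tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$rho, net$edges$rho)

  f_gml <- tempfile(fileext = ".graphml")
  write_graphml(net, f_gml)
  g <- igraph::read_graph(f_gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))

  f_sif <- tempfile(fileext = ".sif")
  write_sif(net, f_sif)
  expect_equal(length(readLines(f_sif)), nrow(net$edges))
  nodes_back <- readr::read_tsv(paste0(f_sif, ".nodes.tsv"),
                                show_col_types = FALSE)
  expect_equal(nrow(nodes_back), nrow(net$nodes))
  expect_true("degree" %in% names(nodes_back))
})
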