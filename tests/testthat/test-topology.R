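path_net <- function(pairs) {
  res <- tibble::tibble(taxon_i = pairs[, 1], taxon_j = pairs[, 2],
                        rho = 0.9, p = 1e-5, q = 1e-4)
  build_network(res)
}

test_that("metrics on a path and a star match hand computation", {
  # path a - b - c: mean distance from b is 1, from a is 1.5
  pm <- node_metrics(path_net(rbind(c("a", "b"), c("b", "c"))))
  expect_equal(pm$closeness_centrality[pm$taxon_id == "b"], 1)
  expect_equal(pm$closeness_centrality[pm$taxon_id == "a"], 2 / 3)
  expect_equal(pm$degree[pm$taxon_id == "b"], 2L)

  # star: center degree 4, NC(center) = 1, NC(leaf) = 4
  star <- path_net(cbind("hub", c("l1", "l2", "l3", "l4")))
  sm <- node_metrics(star)
  expect_equal(sm$degree[sm$taxon_id == "hub"], 4L)
  expect_equal(sm$neighborhood_connectivity[sm$taxon_id == "hub"], 1)
  expect_equal(sm$neighborhood_connectivity[sm$taxon_id == "l1"], 4)
})

test_that("metrics equal the all-pairs BFS oracle on random graphs", {
  for (s in 1:10) {
    net <- random_network(n_nodes = 20, p_edge = 0.12, seed = 100 + s)
    if (nrow(net$edges) == 0) next
    got <- node_metrics(net)
    want <- oracle_metrics(net$nodes$taxon_id, net$edges)
    got <- got[order(got$taxon_id), ]
    want <- want[order(want$taxon_id), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$closeness_centrality, want$closeness_centrality,
                 tolerance = 1e-12)
    expect_equal(got$neighborhood_connectivity,
                 want$neighborhood_connectivity, tolerance = 1e-12)
  }
})

test_that("NC is constant k on a k-regular graph", {
  n <- 8
  ring <- path_net(cbind(sprintf("v%d", 1:n),
                         sprintf("v%d", c(2:n, 1))))
  rm <- node_metrics(ring)
  expect_true(all(rm$degree == 2L))
  expect_true(all(rm$neighborhood_connectivity == 2))
})

test_that("Kruskal-Wallis omnibus matches the hand rank formula", {
  profs <- list(
    g1 = tibble::tibble(taxon_id = letters[1:5], membership = "other",
                        degree = c(1, 2, 3, 4, 5)),
    g2 = tibble::tibble(taxon_id = letters[1:5], membership = "other",
                        degree = c(10, 20, 30, 40, 50)),
    g3 = tibble::tibble(taxon_id = letters[1:5], membership = "other",
                        degree = c(100, 200, 300, 400, 500)))
  cmp <- compare_topology(profs, metric = "degree")
  # ranks 1..15 with no ties: H = 12/(15*16) * 5 * ((3-8)^2 + 0 + (13-8)^2)
  expect_equal(cmp$omnibus$statistic, 12.5)
  expect_equal(nrow(cmp$pairwise), 3)
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p - 1e-12))
})

test_that("Dunn z is 0 with identical groups and KW ~ squared MW z on two", {
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6)
  d <- dunn_test(rep(vals, 2), rep(c("a", "b"), each = 8))
  expect_equal(d$z, 0)
  expect_equal(d$p, 1)

  withr::with_seed(61, {
    x <- rnorm(12); y <- rnorm(10) + 0.8
  })
  kw <- kruskal.test(list(x, y))
  dz <- dunn_test(c(x, y), rep(c("a", "b"), c(12, 10)))$z
  expect_equal(unname(kw$statistic), dz^2, tolerance = 1e-10)
})

test_that("Dunn p-values are uniform under permuted group labels", {
  withr::with_seed(71, {
    vals <- rnorm(36)
    labels <- rep(c("a", "b", "c"), each = 12)
    pvals <- vapply(1:1000, function(k) {
      dunn_test(vals, sample(labels), p_adjust = "none")$p[1]
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("small groups are excluded with a warning; <2 groups errors", {
  profs <- list(
    g1 = tibble::tibble(taxon_id = "a", membership = "other", degree = 3),
    g2 = tibble::tibble(taxon_id = letters[1:4], membership = "other",
                        degree = c(1, 2, 3, 4)),
    g3 = tibble::tibble(taxon_id = letters[1:4], membership = "other",
                        degree = c(5, 6, 7, 8)))
  expect_warning(cmp <- compare_topology(profs, "degree"), "g1")
  expect_setequal(unique(c(cmp$pairwise$group_a, cmp$pairwise$group_b)),
                  c("g2", "g3"))
  expect_error(
    suppressWarnings(compare_topology(profs[1:2], "degree")),
    ">= 2 groups")
})

test_that("membership slices partition nodes and flag unknown focal taxa", {
  prof <- tibble::tibble(
    taxon_id = c("Lactobacillus", "Frischella", "Enterobacter", "X"),
    membership = c("core", "non-core", "other", "other"),
    degree = 1:4, closeness_centrality = 0.5,
    neighborhood_connectivity = 2)
  sl <- membership_slices(prof, focal_taxa = "Enterobacter")
  expect_equal(sl$slice,
               c("core", "non-core", "focal:Enterobacter", "other"))
  expect_equal(nrow(sl), nrow(prof))
  expect_warning(membership_slices(prof, focal_taxa = "Pantoea"),
                 "Pantoea")
  # no core nodes -> empty core slice; all core -> slice equals profile
  expect_equal(sum(sl$slice == "low-activity"), 0)
  all_core <- dplyr::mutate(prof, membership = "core")
  expect_true(all(membership_slices(all_core)$slice == "core"))
})
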