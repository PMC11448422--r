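test_that("activity generator is a pure function of (design, condition)", {
  d <- community_design(8, n_replicates = 6, seed = 99,
                        conditions = c("a", "b"))
  t1 <- gen_activity_table(d, "a")
  t2 <- gen_activity_table(d, "a")
  expect_identical(t1, t2)
  expect_false(identical(t1, gen_activity_table(d, "b")))
  expect_true(all(as.matrix(t1[-1]) >= 0))
  expect_equal(dim(t1), c(8, 7))
  expect_error(gen_activity_table(d, "nope"), "unknown condition")
})

test_that("independent taxa show near-zero pairwise rank correlation", {
  d <- community_design(6, n_replicates = 200, seed = 3)
  tab <- gen_activity_table(d, "control")
  m <- t(as.matrix(tab[-1]))
  rho <- cor(m, method = "spearman")
  expect_lt(mean(abs(rho[upper.tri(rho)])), 0.15)
})

test_that("planted latent correlations surface as Spearman correlations", {
  # copula monotonicity: one pair at 0.95 must correlate strongly at n = 50
  plan <- tibble::tibble(taxon_i = "taxon_01", taxon_j = "taxon_02",
                         rho = 0.95)
  d <- community_design(4, edge_plan = plan, n_replicates = 50, seed = 7)
  tab <- gen_activity_table(d, "control")
  m <- as.matrix(tab[-1])
  expect_gt(cor(m[1, ], m[2, ], method = "spearman"), 0.7)
})

test_that("copula rank-correlation recovery holds across the rho range", {
  for (rho in c(-0.9, -0.5, 0.5, 0.9)) {
    plan <- tibble::tibble(taxon_i = "taxon_01", taxon_j = "taxon_02",
                           rho = rho)
    obs <- vapply(1:20, function(s) {
      d <- community_design(2, edge_plan = plan, n_replicates = 50,
                            seed = 100 + s)
      m <- as.matrix(gen_activity_table(d, "control")[-1])
      cor(m[1, ], m[2, ], method = "spearman")
    }, numeric(1))
    expect_lt(abs(mean(obs) - rho), 0.1)
  }
})

test_that("NB marginals keep their mean and variance", {
  d <- community_design(4, mean_abundances = c(20, 100, 500, 2000),
                        dispersions = 0.25, n_replicates = 1000, seed = 5)
  m <- as.matrix(gen_activity_table(d, "control")[-1])
  for (t in 1:4) {
    mu <- d$mean_abundances[t]
    v <- mu + 0.25 * mu^2
    se_mean <- sqrt(v / 1000)
    expect_lt(abs(mean(m[t, ]) - mu), 3 * se_mean)
    # SE of the sample variance via var(s^2) ~ (mu4 - v^2) / n, with the
    # fourth central moment summed from the NB pmf
    xs <- 0:qnbinom(1 - 1e-12, mu = mu, size = 4)
    w <- dnbinom(xs, mu = mu, size = 4)
    mu4 <- sum(w * (xs - mu)^4)
    se_var <- sqrt((mu4 - v^2) / 1000)
    expect_lt(abs(var(m[t, ]) - v), 3 * se_var)
  }
})

test_that("inconsistent edge plans are repaired or rejected by name", {
  # two strong edges sharing a node with an implied third of 0: not PSD,
  # and too far from PSD to repair silently
  plan <- tibble::tibble(taxon_i = c("taxon_01", "taxon_02"),
                         taxon_j = c("taxon_02", "taxon_03"),
                         rho = c(0.95, 0.95))
  d <- community_design(3, edge_plan = plan, n_replicates = 6, seed = 1)
  expect_error(suppressWarnings(gen_activity_table(d, "control")),
               "taxon_0")
  # mild inconsistency is repaired with a warning
  plan2 <- tibble::tibble(taxon_i = c("taxon_01", "taxon_02"),
                          taxon_j = c("taxon_02", "taxon_03"),
                          rho = c(0.75, 0.75))
  d2 <- community_design(3, edge_plan = plan2, n_replicates = 6, seed = 1)
  expect_warning(gen_activity_table(d2, "control"), "PSD")
})

test_that("survival generator honours hazards, frailty and determinism", {
  zero <- survival_design(
    tibble::tibble(label = "a", hazard = 0, multiplier = 1),
    n_cages_per_group = 2, bees_per_cage = 30, horizon_days = 28, seed = 2)
  cz <- gen_survival_cohort(zero)
  expect_true(all(cz$event == 0))
  expect_true(all(cz$time == 28))

  d <- survival_design(
    tibble::tibble(label = c("ctl", "exp"), hazard = c(0.03, 0.03),
                   multiplier = c(1, 3)),
    n_cages_per_group = 3, bees_per_cage = 200, cage_frailty_sd = 0,
    horizon_days = 28, seed = 4)
  cohort <- gen_survival_cohort(d)
  expect_identical(cohort, gen_survival_cohort(d))
  expect_equal(nrow(cohort), 1200)
  med <- function(g) {
    km <- km_estimate(cohort, group = g)
    km$time[km$surv <= 0.5][1]
  }
  expect_lt(med("exp"), med("ctl"))
})

test_that("hit-table generator plants resolvable queries", {
  paths <- c(make_lineage("Gilliamella", "apicola"),
             make_lineage("Lactobacillus", "apis"))
  expect_equal(nrow(gen_hit_table(paths, 0)), 0)
  hits <- gen_hit_table(paths, 30, p_above98 = 0.5, seed = 11)
  rec <- assign_taxonomy(hits)
  planted <- dplyr::distinct(hits, query_id, planted_type, planted_path)
  joined <- dplyr::left_join(rec, planted,
                             by = c(taxon_id = "query_id"))
  above <- joined[joined$planted_type == "above98", ]
  expect_true(all(above$lineage == above$planted_path))
  expect_true(all(above$assignment_rank == "species"))
  amb <- joined[joined$planted_type == "ambiguous", ]
  # species-level ambiguity resolves to the planted genus
  expect_true(all(amb$assignment_rank == "genus"))
  expect_equal(lineage_rank(amb$lineage, "genus"),
               lineage_rank(amb$planted_path, "genus"))
})
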