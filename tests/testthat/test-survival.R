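test_that("product-limit estimate matches hand-worked tables", {
  # 2 bees dying on days 1 and 2
  two <- tibble::tibble(time = c(1, 2), event = c(1, 1))
  km <- km_estimate(two)
  expect_equal(km$time, c(0, 1, 2))
  expect_equal(km$surv, c(1, 0.5, 0))

  # all censored
  cens <- tibble::tibble(time = rep(28, 5), event = 0)
  expect_true(all(km_estimate(cens)$surv == 1))

  # cohort of 6 with one censoring at day 2:
  # S(1) = 5/6; S(3) = 5/6 * 3/4 = 0.625; S(4) = 0.625 * 1/3
  six <- tibble::tibble(time = c(1, 2, 3, 4, 4, 5),
                        event = c(1, 0, 1, 1, 1, 0))
  km6 <- km_estimate(six)
  expect_equal(km6$surv[km6$time == 1], 5 / 6)
  expect_equal(km6$surv[km6$time == 3], 5 / 6 * 3 / 4)
  expect_equal(km6$surv[km6$time == 4], 5 / 6 * 3 / 4 * 1 / 3)
  expect_equal(km6$surv, c(1, oracle_km(six$time, six$event)$surv))
  # S is non-increasing and bounded
  expect_true(all(diff(km6$surv) <= 0))
  expect_true(all(km6$surv >= 0 & km6$surv <= 1))
  expect_error(km_estimate(six[0, ]), "empty")
})

test_that("with no censoring S(t) is one minus the empirical CDF", {
  withr::with_seed(81, {
    t_obs <- sample(1:15, 40, replace = TRUE)
  })
  km <- km_estimate(tibble::tibble(time = t_obs, event = 1))
  for (k in seq_len(nrow(km))) {
    expect_equal(km$surv[k], mean(t_obs > km$time[k]))
  }
})

test_that("KM curve and Greenwood SE match the survival package", {
  d <- survival_design(
    tibble::tibble(label = c("a", "b"), hazard = c(0.03, 0.06)),
    n_cages_per_group = 2, bees_per_cage = 40, cage_frailty_sd = 0.1,
    seed = 5)
  cohort <- gen_survival_cohort(d)
  km <- km_estimate(cohort, group = "a")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = cohort[cohort$group == "a", ])
  sm <- summary(fit, times = km$time[-1])
  expect_equal(km$surv[-1], sm$surv, tolerance = 1e-12)
  expect_equal(km$std_err[-1], sm$std.err, tolerance = 1e-8)
})

test_that("log-rank is null on identical groups and matches survdiff", {
  base <- tibble::tibble(time = c(2, 5, 7, 9, 12, 28),
                         event = c(1, 1, 0, 1, 1, 0))
  cohort <- dplyr::bind_rows(
    dplyr::mutate(base, group = "a", cage = "c1"),
    dplyr::mutate(base, group = "b", cage = "c2"))
  out <- compare_groups(cohort)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)

  d <- survival_design(
    tibble::tibble(label = c("a", "b"), hazard = c(0.02, 0.05)),
    n_cages_per_group = 3, bees_per_cage = 50, cage_frailty_sd = 0,
    seed = 6)
  coh <- gen_survival_cohort(d)
  got <- compare_groups(coh)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = coh)
  expect_equal(got$statistic, unname(sd_fit$chisq), tolerance = 1e-10)
  # symmetry under relabelling
  coh2 <- dplyr::mutate(coh, group = ifelse(group == "a", "b", "a"))
  expect_equal(compare_groups(coh2)$statistic, got$statistic,
               tolerance = 1e-12)
  # stratified variant matches survdiff with a stratum shared across
  # groups (cages are nested in groups, so a batch-like stratum is used)
  coh$batch <- rep_len(c("b1", "b2"), nrow(coh))
  got_s <- compare_groups(coh, strata = "batch")
  sd_s <- survival::survdiff(
    survival::Surv(time, event) ~ group + survival::strata(batch),
    data = coh)
  expect_equal(got_s$statistic, unname(sd_s$chisq), tolerance = 1e-10)
})

test_that("KM on merged identical groups equals KM on either group", {
  base <- tibble::tibble(time = c(3, 6, 6, 10, 28), event = c(1, 1, 0, 1, 0))
  cohort <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                             dplyr::mutate(base, group = "a2"))
  km_one <- km_estimate(base)
  km_merged <- km_estimate(cohort)
  expect_equal(km_merged$surv, km_one$surv)
  expect_equal(km_merged$time, km_one$time)
})

test_that("pairwise table covers all pairs with BH adjustment", {
  d <- survival_design(
    tibble::tibble(label = c("a", "b", "c"), hazard = c(0.01, 0.03, 0.08)),
    n_cages_per_group = 2, bees_per_cage = 40, cage_frailty_sd = 0,
    seed = 7)
  out <- compare_groups(gen_survival_cohort(d))
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adj >= out$p - 1e-12))
  # zero-event pair is flagged undefined rather than erroring
  frozen <- tibble::tibble(
    time = rep(28, 10), event = 0,
    group = rep(c("x", "y"), each = 5), cage = "c")
  nul <- compare_groups(frozen)
  expect_true(is.na(nul$statistic))
})
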