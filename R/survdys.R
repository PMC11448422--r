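# Kaplan-Meier survival estimation and log-rank group comparison for
# cage-cohort mortality records. The product-limit estimator and the
# log-rank statistic are computed directly from the risk-set tables (same-
# day deaths treated as simultaneous, censoring at the horizon reduces risk
# sets only); cage structure is handled by an optional stratified log-rank
# rather than a frailty model.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event days d <= t of (1 - deaths_d / at_risk_d)`, with
#' Greenwood's variance for the standard error and a log-scale confidence
#' band.
#'
#' @param cohort tibble with columns `time` (day >= 1), `event` (1 death,
#'   0 censored) and optionally `group`.
#' @param group if given, restrict to this group label.
#' @param conf_level confidence level for the Greenwood band (default
#'   0.95).
#' @return object of class `km_curve`: tibble (time, n_risk, n_event,
#'   n_censor, surv, std_err, lower, upper) with one row per distinct
#'   observed day, plus a `t = 0, S = 1` anchor row.
#' @export
km_estimate <- function(cohort, group = NULL, conf_level = 0.95) {
  cohort <- as_tibble(cohort)
  if (!is.null(group)) {
    stopifnot("group" %in% names(cohort))
    cohort <- cohort[cohort$group == group, ]
  }
  if (nrow(cohort) == 0) stop("empty cohort / group", call. = FALSE)
  stopifnot(all(cohort$event %in% c(0, 1)), all(cohort$time >= 0))
  times <- sort(unique(cohort$time))
  n <- nrow(cohort)
  tab <- purrr::map_dfr(times, function(tt) {
    tibble(time = tt,
           n_risk = sum(cohort$time >= tt),
           n_event = sum(cohort$time == tt & cohort$event == 1),
           n_censor = sum(cohort$time == tt & cohort$event == 0))
  })
  surv <- cumprod(1 - tab$n_event / tab$n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(ifelse(tab$n_risk > tab$n_event,
                      tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event)),
                      0))
  std_err <- surv * sqrt(gw)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  # log-scale band, clipped to [0, 1]
  se_log <- ifelse(surv > 0, sqrt(gw), NA_real_)
  lower <- pmin(pmax(exp(log(pmax(surv, .Machine$double.eps)) -
                           zq * se_log), 0), 1)
  upper <- pmin(exp(log(pmax(surv, .Machine$double.eps)) + zq * se_log), 1)
  lower[surv == 0] <- 0
  upper[surv == 0] <- 0
  out <- dplyr::bind_rows(
    tibble(time = 0, n_risk = n, n_event = 0L, n_censor = 0L,
           surv = 1, std_err = 0, lower = 1, upper = 1),
    dplyr::mutate(tab, surv = surv, std_err = std_err,
                  lower = lower, upper = upper))
  structure(out, class = c("km_curve", class(out)),
            group = group %||% NA_character_, n = n)
}

#' @rdname km_estimate
#' @param x a `km_curve`.
#' @param ... unused.
#' @export
glance.km_curve <- function(x, ...) {
  med <- x$time[x$surv <= 0.5][1]
  tibble(group = attr(x, "group"), n = attr(x, "n"),
         events = sum(x$n_event),
         median_survival = if (is.na(med)) NA_real_ else med,
         final_surv = x$surv[nrow(x)])
}

#' Kaplan-Meier survival by group
#'
#' Convenience wrapper fitting one [km_estimate()] per group and returning
#' the curves in one long tibble.
#'
#' @param cohort tibble with time, event, group.
#' @return tibble of KM rows with a `group` column, class `km_curves`.
#' @export
km_by_group <- function(cohort) {
  groups <- sort(unique(cohort$group))
  out <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(as_tibble(km_estimate(cohort, group = g)), group = g)
  })
  structure(out, class = c("km_curves", class(out)))
}

# Log-rank chi-square for exactly two groups within one stratum; returns
# observed and expected event counts plus the hypergeometric variance, so
# strata can be pooled before forming the statistic.
logrank_components <- function(time, event, is_b) {
  days <- sort(unique(time[event == 1]))
  o_b <- e_b <- v <- 0
  for (tt in days) {
    at_risk <- time >= tt
    n_tot <- sum(at_risk)
    n_b <- sum(at_risk & is_b)
    d_tot <- sum(time == tt & event == 1)
    d_b <- sum(time == tt & event == 1 & is_b)
    o_b <- o_b + d_b
    e_b <- e_b + d_tot * n_b / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n_b / n_tot) * (1 - n_b / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  c(observed = o_b, expected = e_b, variance = v)
}

#' Log-rank comparison of survival between groups
#'
#' Two-sided log-rank chi-square test with 1 degree of freedom per pair.
#' With more than two groups every unordered pair is tested and p-values are
#' BH-adjusted across the pair family. `strata` (typically the cage) pools
#' the observed-minus-expected contributions within strata before forming
#' the statistic, the stratified log-rank.
#'
#' @param cohort tibble with time, event, group (and the strata column when
#'   used).
#' @param groups labels to compare; default all groups in the cohort.
#' @param strata optional column name to stratify on (e.g. `"cage"`).
#' @return tibble (group_a, group_b, statistic, p, p_adj), one row per
#'   pair.
#' @export
compare_groups <- function(cohort, groups = NULL, strata = NULL) {
  cohort <- as_tibble(cohort)
  groups <- groups %||% sort(unique(cohort$group))
  stopifnot(length(groups) >= 2)
  pairs <- combn(groups, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sub <- cohort[cohort$group %in% c(a, b), ]
    if (!nrow(sub[sub$group == a, ]) || !nrow(sub[sub$group == b, ])) {
      stop("empty group in comparison: ", a, " vs ", b, call. = FALSE)
    }
    strat <- if (is.null(strata)) rep("all", nrow(sub)) else sub[[strata]]
    comp <- vapply(unique(strat), function(s) {
      sel <- strat == s
      logrank_components(sub$time[sel], sub$event[sel],
                         sub$group[sel] == b)
    }, numeric(3))
    o <- sum(comp["observed", ]); e <- sum(comp["expected", ])
    v <- sum(comp["variance", ])
    if (v == 0) {
      # no at-risk overlap or no events: statistic undefined
      return(tibble(group_a = a, group_b = b,
                    statistic = NA_real_, p = NA_real_))
    }
    stat <- (o - e)^2 / v
    tibble(group_a = a, group_b = b, statistic = stat,
           p = pchisq(stat, df = 1, lower.tail = FALSE))
  })
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Step plot of Kaplan-Meier curves
#'
#' @param object output of [km_by_group()] (or a single `km_curve`).
#' @param conf_band draw the Greenwood confidence band.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.km_curves <- function(object, conf_band = FALSE, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "day", y = "survival probability",
                  colour = "group") +
    ggplot2::theme_minimal()
  if (conf_band) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower),
                                linetype = 3, alpha = 0.6) +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper),
                         linetype = 3, alpha = 0.6)
  }
  p
}

#' @export
autoplot.km_curve <- function(object, ...) {
  obj <- dplyr::mutate(as_tibble(object),
                       group = attr(object, "group"))
  autoplot.km_curves(structure(obj, class = c("km_curves", class(obj))), ...)
}
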