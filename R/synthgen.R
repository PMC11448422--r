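# Synthetic inputs with the statistical structure the downstream analysis
# assumes: Gaussian-copula negative-binomial count tables with planted
# inter-taxon rank correlations, cage-structured survival cohorts, and
# BLAST-style hit tables for the taxonomy rules.

#' Describe a synthetic microbial community
#'
#' A community design fixes everything the count generator needs: taxon
#' names, which taxa are core / non-core members of the honeybee gut
#' microbiota, per-taxon negative-binomial marginals (mean and dispersion,
#' variance = mu + alpha * mu^2), a plan of latent inter-taxon correlations
#' to plant, the replicate structure, and a seed.
#'
#' Mean abundances default to a log-uniform draw between 10 and 20,000
#' transcripts, loosely emulating the strong dominance of a few core genera
#' in real gut communities; override `mean_abundances` for anything more
#' specific.
#'
#' @param n_taxa number of taxa (genera or ASVs).
#' @param taxa taxon names; defaults to `taxon_01 ...`.
#' @param core_taxa,noncore_taxa names designated core / non-core members.
#' @param mean_abundances per-taxon expected count (> 0), recycled.
#' @param dispersions per-taxon NB dispersion alpha (> 0), recycled.
#' @param edge_plan tibble/data.frame with columns `taxon_i`, `taxon_j`,
#'   `rho` — latent correlations in \[-1, 1\] to plant (others are 0).
#' @param n_replicates replicate samples per condition (study design: 6,
#'   five pooled workers per replicate).
#' @param conditions character vector of condition labels.
#' @param condition_edge_plans optional named list of per-condition
#'   `edge_plan` overrides.
#' @param dropout_prob per-taxon probability that a count is zeroed
#'   (optional zero inflation emulating occurrence gaps); default 0.
#' @param seed integer seed making the generator a pure function.
#' @return an object of class `community_design`.
#' @export
community_design <- function(n_taxa,
                             taxa = sprintf("taxon_%02d", seq_len(n_taxa)),
                             core_taxa = character(),
                             noncore_taxa = character(),
                             mean_abundances = NULL,
                             dispersions = 0.3,
                             edge_plan = NULL,
                             n_replicates = 6,
                             conditions = "control",
                             condition_edge_plans = NULL,
                             dropout_prob = 0,
                             seed = 1L) {
  stopifnot(n_taxa >= 1, length(taxa) == n_taxa, !anyDuplicated(taxa),
            n_replicates >= 1, length(conditions) >= 1)
  if (is.null(mean_abundances)) {
    mean_abundances <- with_seed(seed + 777L,
      round(exp(runif(n_taxa, log(10), log(2e4)))))
  }
  mean_abundances <- rep_len(mean_abundances, n_taxa)
  dispersions <- rep_len(dispersions, n_taxa)
  stopifnot(all(mean_abundances > 0), all(dispersions > 0),
            dropout_prob >= 0, dropout_prob < 1)
  edge_plan <- validate_edge_plan(edge_plan, taxa)
  if (!is.null(condition_edge_plans)) {
    stopifnot(all(names(condition_edge_plans) %in% conditions))
    condition_edge_plans <- lapply(condition_edge_plans, validate_edge_plan,
                                   taxa = taxa)
  }
  structure(
    list(n_taxa = n_taxa, taxa = taxa,
         core_taxa = core_taxa, noncore_taxa = noncore_taxa,
         mean_abundances = mean_abundances, dispersions = dispersions,
         edge_plan = edge_plan, n_replicates = n_replicates,
         conditions = conditions,
         condition_edge_plans = condition_edge_plans,
         dropout_prob = dropout_prob, seed = as.integer(seed)),
    class = "community_design")
}

validate_edge_plan <- function(edge_plan, taxa) {
  if (is.null(edge_plan) || nrow(as.data.frame(edge_plan)) == 0) {
    return(tibble(taxon_i = character(), taxon_j = character(),
                  rho = numeric()))
  }
  edge_plan <- as_tibble(edge_plan)
  stopifnot(all(c("taxon_i", "taxon_j", "rho") %in% names(edge_plan)))
  bad <- !(edge_plan$taxon_i %in% taxa) | !(edge_plan$taxon_j %in% taxa)
  if (any(bad)) {
    stop("edge plan names unknown taxa: ",
         paste(unique(c(edge_plan$taxon_i[bad], edge_plan$taxon_j[bad])),
               collapse = ", "), call. = FALSE)
  }
  if (any(edge_plan$taxon_i == edge_plan$taxon_j)) {
    stop("edge plan contains self-pairs", call. = FALSE)
  }
  stopifnot(all(abs(edge_plan$rho) <= 1))
  edge_plan
}

# Assemble the latent correlation matrix for one condition and repair it
# to PSD. Errors if the repair moves a planted entry by more than `max_shift`.
latent_correlation <- function(design, condition, max_shift = 0.1) {
  plan <- design$edge_plan
  if (!is.null(design$condition_edge_plans) &&
      condition %in% names(design$condition_edge_plans)) {
    plan <- design$condition_edge_plans[[condition]]
  }
  n <- design$n_taxa
  r <- diag(n)
  dimnames(r) <- list(design$taxa, design$taxa)
  if (nrow(plan)) {
    i <- match(plan$taxon_i, design$taxa)
    j <- match(plan$taxon_j, design$taxa)
    r[cbind(i, j)] <- plan$rho
    r[cbind(j, i)] <- plan$rho
  }
  rr <- nearest_psd(r)
  if (nrow(plan)) {
    i <- match(plan$taxon_i, design$taxa)
    j <- match(plan$taxon_j, design$taxa)
    shift <- abs(rr[cbind(i, j)] - plan$rho)
    if (any(shift > max_shift)) {
      k <- which.max(shift)
      stop(sprintf(
        "edge plan is too far from PSD: pair (%s, %s) moved by %.3f in repair",
        plan$taxon_i[k], plan$taxon_j[k], shift[k]), call. = FALSE)
    }
  }
  rr
}

#' Generate a synthetic taxon-by-sample activity table
#'
#' Counts are drawn through a Gaussian copula: a multivariate normal sample
#' with the condition's latent correlation matrix is mapped through the
#' standard normal CDF and inverted through each taxon's negative-binomial
#' quantile function, so planted latent correlations surface as Spearman
#' rank correlations between taxa while each taxon keeps its NB(mu, alpha)
#' marginal.
#'
#' @param design a [community_design()].
#' @param condition one of `design$conditions`.
#' @return a wide tibble: `taxon_id` plus one integer count column per
#'   replicate, named `<condition>_r<k>`.
#' @examples
#' d <- community_design(5, n_replicates = 6, seed = 42)
#' gen_activity_table(d, "control")
#' @export
gen_activity_table <- function(design, condition) {
  stopifnot(inherits(design, "community_design"))
  if (!condition %in% design$conditions) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  r <- latent_correlation(design, condition)
  n <- design$n_taxa
  m <- design$n_replicates
  eig <- eigen(r, symmetric = TRUE)
  a <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  seed <- design$seed + 1000L * match(condition, design$conditions)
  counts <- with_seed(seed, {
    z <- matrix(rnorm(m * n), nrow = m) %*% t(a)
    u <- pnorm(z)
    cnt <- vapply(seq_len(n), function(t) {
      qnbinom(u[, t], mu = design$mean_abundances[t],
              size = 1 / design$dispersions[t])
    }, numeric(m))
    if (design$dropout_prob > 0) {
      cnt[matrix(runif(m * n) < design$dropout_prob, nrow = m)] <- 0
    }
    cnt
  })
  out <- tibble(taxon_id = design$taxa)
  samples <- sprintf("%s_r%d", condition, seq_len(m))
  for (k in seq_len(m)) out[[samples[k]]] <- as.integer(counts[k, ])
  out
}

#' Simulate a full multi-condition experiment
#'
#' Runs [gen_activity_table()] for every condition in the design and binds
#' the per-condition tables into one activity table with a companion sample
#' metadata tibble (condition, gut section, cage, replicate). Replicates are
#' assigned to cages round-robin (the study pooled five workers per
#' replicate, two replicates per cage across three cages).
#'
#' @param design a [community_design()].
#' @param gut_section label stored in the metadata (one table per section).
#' @param n_cages cages per condition used for the round-robin assignment.
#' @return list with elements `counts` (wide tibble) and `metadata` (tibble
#'   with sample_id, condition, gut_section, cage, replicate).
#' @export
simulate_experiment <- function(design, gut_section = "midgut", n_cages = 3) {
  tabs <- lapply(design$conditions, function(cond) gen_activity_table(design, cond))
  counts <- Reduce(function(x, y) dplyr::left_join(x, y, by = "taxon_id"), tabs)
  metadata <- purrr::map_dfr(design$conditions, function(cond) {
    reps <- seq_len(design$n_replicates)
    tibble(sample_id = sprintf("%s_r%d", cond, reps),
           condition = cond, gut_section = gut_section,
           cage = sprintf("%s_cage%d", cond, ((reps - 1) %% n_cages) + 1),
           replicate = reps)
  })
  list(counts = counts, metadata = metadata)
}

#' Describe a synthetic caged-bee survival experiment
#'
#' @param groups tibble/data.frame with columns `label`, `hazard` (baseline
#'   daily hazard rate, >= 0) and `multiplier` (hazard ratio applied on top,
#'   default 1).
#' @param n_cages_per_group cages per group (study design: 3).
#' @param bees_per_cage bees per cage (study design: 200).
#' @param cage_frailty_sd SD of the lognormal cage effect on the hazard.
#' @param horizon_days end of follow-up; survivors are censored (study: 28).
#' @param seed integer seed.
#' @return an object of class `survival_design`.
#' @export
survival_design <- function(groups,
                            n_cages_per_group = 3,
                            bees_per_cage = 200,
                            cage_frailty_sd = 0.2,
                            horizon_days = 28,
                            seed = 1L) {
  groups <- as_tibble(groups)
  stopifnot(all(c("label", "hazard") %in% names(groups)))
  if (!"multiplier" %in% names(groups)) groups$multiplier <- 1
  stopifnot(all(groups$hazard >= 0), all(groups$multiplier >= 0),
            horizon_days >= 1, n_cages_per_group >= 1, bees_per_cage >= 1,
            cage_frailty_sd >= 0)
  structure(
    list(groups = groups, n_cages_per_group = n_cages_per_group,
         bees_per_cage = bees_per_cage, cage_frailty_sd = cage_frailty_sd,
         horizon_days = as.integer(horizon_days), seed = as.integer(seed)),
    class = "survival_design")
}

#' Generate a synthetic survival cohort
#'
#' One record per bee. Each cage draws a lognormal frailty multiplying its
#' group's daily hazard; day of death is geometric with daily death
#' probability `1 - exp(-hazard)`, so mortality is recorded in whole days as
#' in the cage experiment. Bees alive at the horizon are censored.
#'
#' @param design a [survival_design()].
#' @return tibble (bee_id, group, cage, time, event) with event 1 = death
#'   observed, 0 = censored at the horizon.
#' @export
gen_survival_cohort <- function(design) {
  stopifnot(inherits(design, "survival_design"))
  with_seed(design$seed, {
    purrr::pmap_dfr(design$groups, function(label, hazard, multiplier, ...) {
      purrr::map_dfr(seq_len(design$n_cages_per_group), function(cg) {
        frailty <- exp(rnorm(1, 0, design$cage_frailty_sd))
        h <- hazard * multiplier * frailty
        p <- 1 - exp(-h)
        n <- design$bees_per_cage
        day <- if (p <= 0) rep(Inf, n) else rgeom(n, p) + 1
        event <- as.integer(day <= design$horizon_days)
        tibble(
          bee_id = sprintf("%s_c%d_b%03d", label, cg, seq_len(n)),
          group = label,
          cage = sprintf("%s_cage%d", label, cg),
          time = as.integer(pmin(day, design$horizon_days)),
          event = event)
      })
    })
  })
}

#' Generate a BLAST-style hit table for the taxonomy rules
#'
#' Plants two kinds of queries against a list of true taxonomy paths:
#' "above-98" queries whose top hit exceeds 98% identity (resolved by the
#' top-hit rule) and "ambiguous" queries whose top-50 hits all sit at or
#' below 98% and span at least two sibling taxa (resolved by LCA). Sibling
#' paths differ at the species rank when `ambiguity = "species"` (LCA lands
#' on the genus) or at the genus rank when `ambiguity = "genus"` (LCA lands
#' on the family).
#'
#' @param truth_taxonomy character vector of 7-rank semicolon-delimited
#'   taxonomy paths (see [make_lineage()]).
#' @param n_queries number of queries.
#' @param p_above98 probability a query is of the "above-98" kind.
#' @param n_hits hits generated per query (<= 50 retained downstream).
#' @param ambiguity `"species"` or `"genus"`.
#' @param seed integer seed.
#' @return tibble (query_id, taxonomy_path, percent_identity, bitscore,
#'   planted_type, planted_path) sorted per query by bitscore descending.
#' @export
gen_hit_table <- function(truth_taxonomy, n_queries,
                          p_above98 = 0.5, n_hits = 20,
                          ambiguity = c("species", "genus"),
                          seed = 1L) {
  stopifnot(length(truth_taxonomy) >= 1, n_queries >= 0, n_hits >= 2)
  ambiguity <- match.arg(ambiguity)
  empty <- tibble(query_id = character(), taxonomy_path = character(),
                  percent_identity = numeric(), bitscore = numeric(),
                  planted_type = character(), planted_path = character())
  if (n_queries == 0) return(empty)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_queries), function(q) {
      truth <- sample(truth_taxonomy, 1)
      ranks <- strsplit(truth, ";", fixed = TRUE)[[1]]
      stopifnot(length(ranks) == 7)
      type <- if (runif(1) < p_above98) "above98" else "ambiguous"
      if (type == "above98") {
        ident <- c(runif(1, 98.1, 99.9),
                   sort(runif(n_hits - 1, 80, 98), decreasing = TRUE))
        paths <- c(truth, rep(sibling_path(ranks, "species"), n_hits - 1))
      } else {
        ident <- sort(runif(n_hits, 90, 98), decreasing = TRUE)
        sib <- sibling_path(ranks, ambiguity)
        paths <- ifelse(seq_len(n_hits) %% 2 == 1, truth, sib)
      }
      tibble(query_id = sprintf("query_%03d", q),
             taxonomy_path = paths,
             percent_identity = round(ident, 2),
             bitscore = round(seq(500, 300, length.out = n_hits) +
                                runif(n_hits, 0, 5), 1),
             planted_type = type,
             planted_path = truth) %>%
        dplyr::arrange(dplyr::desc(.data$bitscore))
    })
  })
}

# A path differing from `ranks` at the given rank (and below).
sibling_path <- function(ranks, at = c("species", "genus")) {
  at <- match.arg(at)
  out <- ranks
  if (at == "species") {
    out[7] <- paste0(ranks[7], "_sibling")
  } else {
    out[6] <- paste0(ranks[6], "_sibling")
    out[7] <- paste0(out[6], " sp.")
  }
  paste(out, collapse = ";")
}

#' Build a 7-rank taxonomy path
#'
#' @param genus genus name.
#' @param species species epithet (appended to the genus); default "sp.".
#' @param domain,phylum,class,order,family higher ranks; placeholders
#'   derived from the genus when omitted so prefix comparison stays
#'   rank-aligned.
#' @return a semicolon-delimited 7-rank path (domain...species).
#' @export
make_lineage <- function(genus, species = "sp.",
                         domain = "Bacteria",
                         phylum = paste0("phylum_of_", genus),
                         class = paste0("class_of_", genus),
                         order = paste0("order_of_", genus),
                         family = paste0("family_of_", genus)) {
  paste(domain, phylum, class, order, family, genus,
        paste(genus, species), sep = ";")
}
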