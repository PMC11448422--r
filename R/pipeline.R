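# End-to-end orchestration: simulate (or load) activity tables per gut
# section, apply the inclusion rules, infer per-condition co-activity
# networks, compare topology across conditions, test differential activity
# for the configured contrasts, and analyse survival — writing every
# artifact as TSV/GraphML/SIF under one output directory, stamped with the
# seed and a config hash so runs are reproducible.

#' Demo run configuration
#'
#' A small two-condition community (a sugar control and a pesticide
#' exposure) across the three gut sections, with the study's replicate
#' structure (6 replicates per condition, 3 cages) and a cohort of
#' 3 cages x 200 bees per group over 28 days. The control condition plants a
#' well-connected positive backbone among core members; the pesticide
#' condition loses most positive edges and gains negative ones — the
#' dysbiosis signature the analysis is meant to detect.
#'
#' @param seed integer master seed.
#' @param n_replicates replicates per condition per section.
#' @return a named list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, n_replicates = 6) {
  taxa <- c("Lactobacillus", "Bifidobacterium", "Gilliamella",
            "Snodgrassella", "Frischella", "Bartonella",
            "Parasaccharibacter", "Enterobacter", "Pantoea",
            "Klebsiella", "Serratia", "Staphylococcus",
            "unassigned:asv_01", "unassigned:asv_02", "Lysinibacillus")
  # correlations among the core clique follow a one-factor structure
  # (rho_ij = l_i * l_j) so the planted matrix is exactly PSD
  core4 <- c("Lactobacillus", "Bifidobacterium", "Gilliamella",
             "Snodgrassella")
  l_core <- c(0.95, 0.9, 0.95, 0.9)
  cp <- combn(4, 2)
  core_clique <- tibble(
    taxon_i = core4[cp[1, ]], taxon_j = core4[cp[2, ]],
    rho = round(l_core[cp[1, ]] * l_core[cp[2, ]], 3))
  nc3 <- c("Frischella", "Bartonella", "Parasaccharibacter")
  l_nc <- c(0.9, 0.9, 0.85)
  np <- combn(3, 2)
  noncore_clique <- tibble(
    taxon_i = nc3[np[1, ]], taxon_j = nc3[np[2, ]],
    rho = round(l_nc[np[1, ]] * l_nc[np[2, ]], 3))
  control_plan <- dplyr::bind_rows(core_clique, noncore_clique)
  pesticide_plan <- tibble(
    taxon_i = c("Lactobacillus", "Klebsiella", "Serratia"),
    taxon_j = c("Gilliamella", "Staphylococcus", "Lysinibacillus"),
    rho = c(0.8, 0.85, -0.8))
  list(
    conditions = c("sugar_control", "pesticide"),
    gut_sections = c("midgut", "ileum", "rectum"),
    taxa = taxa,
    core_taxa = core_members(),
    noncore_taxa = noncore_members(),
    edge_plans = list(sugar_control = control_plan,
                      pesticide = pesticide_plan),
    n_replicates = n_replicates,
    dispersion = 0.3,
    contrasts = list(c(reference = "pesticide",
                       treatment = "sugar_control")),
    rho_min = 0.4, alpha = 0.05, gate = "fdr",
    occurrence_min = 3, low_activity = 1e-4,
    survival_groups = tibble(
      label = c("sugar_control", "pesticide"),
      hazard = c(0.004, 0.004),
      multiplier = c(1, 3)),
    n_cages_per_group = 3, bees_per_cage = 200,
    cage_frailty_sd = 0.2, horizon_days = 28,
    seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' Same schema as [default_run_config()]; `edge_plans` entries and
#' `survival_groups` are coerced to tibbles.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1L)
  cfg <- utils::modifyList(base, cfg)
  cfg$edge_plans <- lapply(cfg$edge_plans, as_tibble)
  cfg$survival_groups <- as_tibble(cfg$survival_groups)
  cfg
}

config_design <- function(config, section_index) {
  community_design(
    n_taxa = length(config$taxa), taxa = config$taxa,
    core_taxa = config$core_taxa, noncore_taxa = config$noncore_taxa,
    dispersions = config$dispersion,
    edge_plan = NULL,
    n_replicates = config$n_replicates,
    conditions = config$conditions,
    condition_edge_plans = config$edge_plans,
    seed = config$seed + 101L * section_index)
}

membership_lookup <- function(config) {
  tibble(taxon_id = config$taxa,
         membership = dplyr::case_when(
           config$taxa %in% config$core_taxa ~ "core",
           config$taxa %in% config$noncore_taxa ~ "non-core",
           startsWith(config$taxa, "unassigned") ~ "unassigned",
           TRUE ~ "other"))
}

#' Run the full analysis pipeline
#'
#' Per (condition, gut section): generates the activity table, applies
#' [inclusion_filter()], correlates the relative activity of retained taxa,
#' builds the signed network and writes edge-list TSV, GraphML, SIF and
#' topology TSV. Per section it writes the cross-condition topology
#' comparisons (degree, closeness, neighborhood connectivity), then the
#' configured differential-activity contrasts and the survival analysis.
#' A summary table (one row per network: interacting taxa, positive /
#' negative edge counts, module count) mirrors the published per-network
#' accounting.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `summary`, `networks`, `topology`,
#'   `differential`, `survival` and the output paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("beenet_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  memb <- membership_lookup(config)
  networks <- list()
  summaries <- list()
  topo_profiles <- list()
  for (si in seq_along(config$gut_sections)) {
    section <- config$gut_sections[si]
    design <- config_design(config, si)
    sim <- simulate_experiment(design, gut_section = section,
                               n_cages = config$n_cages_per_group)
    write_activity_tsv(sim$counts,
                       file.path(out_dir, sprintf("counts_%s.tsv", section)))
    write_metadata_tsv(sim$metadata,
                       file.path(out_dir, sprintf("metadata_%s.tsv", section)))
    for (cond in config$conditions) {
      filt <- inclusion_filter(sim$counts, sim$metadata, cond,
                               occurrence_min = config$occurrence_min,
                               low_activity = config$low_activity)
      keep <- filt$taxon_id[filt$status %in% c("included", "borderline")]
      samples <- sim$metadata$sample_id[sim$metadata$condition == cond]
      rel <- relative_activity(sim$counts[c("taxon_id", samples)])
      profiles <- rel[rel$taxon_id %in% keep, ]
      res <- spearman_matrix(profiles)
      summ <- activity_summary(sim$counts, sim$metadata, cond)
      attrs <- dplyr::left_join(summ, memb, by = "taxon_id")
      net <- build_network(res, node_attrs = attrs,
                           rho_min = config$rho_min, alpha = config$alpha,
                           gate = config$gate,
                           condition = cond, gut_section = section)
      tag <- sprintf("%s_%s", section, cond)
      write_edge_tsv(net, file.path(out_dir, sprintf("edges_%s.tsv", tag)))
      write_graphml(net, file.path(out_dir, sprintf("network_%s.graphml", tag)))
      write_sif(net, file.path(out_dir, sprintf("network_%s.sif", tag)))
      metrics <- node_metrics(net)
      readr::write_tsv(metrics,
                       file.path(out_dir, sprintf("topology_%s.tsv", tag)))
      readr::write_tsv(filt,
                       file.path(out_dir, sprintf("inclusion_%s.tsv", tag)))
      networks[[tag]] <- net
      topo_profiles[[section]][[cond]] <- metrics
      summaries[[tag]] <- glance(net)
    }
  }
  # cross-condition topology comparisons per section
  topology <- list()
  for (section in config$gut_sections) {
    profs <- topo_profiles[[section]]
    usable <- vapply(profs, nrow, integer(1)) >= 2
    if (sum(usable) >= 2) {
      for (metric in c("degree", "closeness_centrality",
                       "neighborhood_connectivity")) {
        cmp <- compare_topology(profs[usable], metric = metric)
        topology[[paste(section, metric, sep = "_")]] <- cmp
        readr::write_tsv(
          tidy(cmp),
          file.path(out_dir, sprintf("topology_compare_%s_%s.tsv",
                                     section, metric)))
      }
    }
  }
  # differential activity per section and contrast
  differential <- list()
  for (si in seq_along(config$gut_sections)) {
    section <- config$gut_sections[si]
    counts <- read_activity_tsv(
      file.path(out_dir, sprintf("counts_%s.tsv", section)))
    metadata <- read_metadata_tsv(
      file.path(out_dir, sprintf("metadata_%s.tsv", section)))
    for (ct in config$contrasts) {
      res <- test_differential(counts, metadata,
                               reference = ct[["reference"]],
                               treatment = ct[["treatment"]])
      tag <- sprintf("%s_%s_vs_%s", section, ct[["treatment"]],
                     ct[["reference"]])
      readr::write_tsv(as_tibble(res),
                       file.path(out_dir, sprintf("diffact_%s.tsv", tag)))
      differential[[tag]] <- res
    }
  }
  # survival
  sdesign <- survival_design(config$survival_groups,
                             n_cages_per_group = config$n_cages_per_group,
                             bees_per_cage = config$bees_per_cage,
                             cage_frailty_sd = config$cage_frailty_sd,
                             horizon_days = config$horizon_days,
                             seed = config$seed + 9001L)
  cohort <- gen_survival_cohort(sdesign)
  readr::write_tsv(cohort, file.path(out_dir, "survival_cohort.tsv"))
  curves <- km_by_group(cohort)
  readr::write_tsv(as_tibble(curves), file.path(out_dir, "km_curves.tsv"))
  surv_cmp <- compare_groups(cohort)
  readr::write_tsv(surv_cmp, file.path(out_dir, "survival_compare.tsv"))
  summary <- dplyr::bind_rows(summaries)
  readr::write_tsv(summary, file.path(out_dir, "network_summary.tsv"))
  stamp <- list(seed = config$seed,
                config_hash = rlang::hash(config),
                n_networks = length(networks))
  yaml::write_yaml(stamp, file.path(out_dir, "run_info.yaml"))
  invisible(list(summary = summary, networks = networks,
                 topology = topology, differential = differential,
                 survival = list(cohort = cohort, curves = curves,
                                 comparisons = surv_cmp),
                 out_dir = out_dir))
}
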