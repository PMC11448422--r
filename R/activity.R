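# Activity-table handling: relative activity, genus aggregation, and the
# taxa-inclusion / low-activity rules applied before network inference.
#
# An activity table is a wide tibble: a `taxon_id` column followed by one
# integer count column per sample (16S rRNA transcript counts, a proxy for
# functional activity). Sample metadata travels in a companion tibble with
# columns (sample_id, condition, gut_section, cage, replicate).

count_matrix <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot("taxon_id" %in% names(counts),
            !anyDuplicated(counts$taxon_id))
  m <- as.matrix(counts[setdiff(names(counts), "taxon_id")])
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  rownames(m) <- counts$taxon_id
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(taxon_id = rownames(m)), as_tibble(m))
}

#' Per-sample relative activity
#'
#' Divides each sample column by its total so every column sums to one:
#' each taxon's share of the total 16S-transcript activity in that sample.
#'
#' @param counts activity table (wide tibble, `taxon_id` + sample columns).
#' @return tibble of the same shape with fractional values.
#' @examples
#' tab <- tibble::tibble(taxon_id = c("a", "b", "c"), s1 = c(10L, 30L, 60L))
#' relative_activity(tab)
#' @export
relative_activity <- function(counts) {
  m <- count_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  matrix_to_tibble(sweep(m, 2, totals, "/"))
}

#' Aggregate an activity table to genus level
#'
#' Sums counts within each assigned genus. ASVs whose assignment carries no
#' genus (LCA stopped above genus, or unassigned) are kept as their own
#' pseudo-genus rows named after the taxon, so they can still appear as
#' network nodes.
#'
#' @param counts activity table with ASV-level `taxon_id`s.
#' @param assignments tibble from [assign_taxonomy()] /
#'   [classify_membership()] with `taxon_id` and `lineage`; every taxon in
#'   `counts` must appear.
#' @return genus-level activity table; `taxon_id` holds genus names (or
#'   `"unassigned:<asv>"` pseudo-genera).
#' @export
aggregate_to_genus <- function(counts, assignments) {
  counts <- as_tibble(counts)
  assignments <- as_tibble(assignments)
  missing <- setdiff(counts$taxon_id, assignments$taxon_id)
  if (length(missing)) {
    stop("taxa without assignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genus <- lineage_rank(
    assignments$lineage[match(counts$taxon_id, assignments$taxon_id)],
    "genus")
  genus <- ifelse(is.na(genus), paste0("unassigned:", counts$taxon_id), genus)
  counts %>%
    dplyr::mutate(taxon_id = genus) %>%
    dplyr::group_by(.data$taxon_id) %>%
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop")
}

#' Taxon activity summary for one condition
#'
#' For each taxon: occurrence (replicates of the condition with count > 0)
#' and mean relative activity (its per-sample share of total activity,
#' averaged over the condition's replicates, zeros included).
#'
#' @param counts activity table.
#' @param metadata sample metadata tibble (needs sample_id, condition).
#' @param condition condition label to summarise.
#' @return tibble (taxon_id, occurrence, mean_relative_activity,
#'   n_replicates).
#' @export
activity_summary <- function(counts, metadata, condition) {
  samples <- metadata$sample_id[metadata$condition == condition]
  if (length(samples) == 0) {
    stop("no samples for condition: ", condition, call. = FALSE)
  }
  m <- count_matrix(counts)[, samples, drop = FALSE]
  rel <- as.matrix(
    count_matrix(relative_activity(matrix_to_tibble(m))))
  tibble(taxon_id = rownames(m),
         occurrence = as.integer(rowSums(m > 0)),
         mean_relative_activity = rowMeans(rel),
         n_replicates = length(samples))
}

#' Taxa-inclusion and low-activity rules
#'
#' Applies the study's inclusion rules per condition: taxa occurring in more
#' than `occurrence_min` replicates are included in network interpretation;
#' taxa with mean relative activity below `low_activity` (0.01% of the total
#' sample activity) that occur in fewer than `occurrence_min` replicates are
#' flagged low-activity. Taxa at exactly `occurrence_min` occurrences — a
#' case the verbatim rules (n > 3, n < 3 of 6) leave open — are retained for
#' correlation but labelled `"borderline"`; absent taxa are `"excluded"`,
#' and the remaining low-occurrence / high-activity taxa are `"excluded"` as
#' well since neither rule admits them.
#'
#' @param counts activity table.
#' @param metadata sample metadata tibble.
#' @param condition condition label.
#' @param occurrence_min occurrence pivot (default 3, of 6 replicates).
#' @param low_activity relative-activity threshold (default 1e-4).
#' @return tibble (taxon_id, occurrence, mean_relative_activity, status)
#'   where status partitions taxa into included / borderline / low-activity
#'   / excluded.
#' @export
inclusion_filter <- function(counts, metadata, condition,
                             occurrence_min = 3, low_activity = 1e-4) {
  s <- activity_summary(counts, metadata, condition)
  s %>%
    dplyr::mutate(status = dplyr::case_when(
      .data$occurrence == 0 ~ "excluded",
      .data$occurrence > occurrence_min ~ "included",
      .data$occurrence == occurrence_min ~ "borderline",
      .data$mean_relative_activity < low_activity ~ "low-activity",
      TRUE ~ "excluded")) %>%
    dplyr::select("taxon_id", "occurrence", "mean_relative_activity",
                  "status")
}

#' Read / write activity tables and metadata
#'
#' Plain-TSV round trip for the wide activity table (first column
#' `taxon_id`) and the companion metadata table.
#'
#' @param counts,metadata tibbles as used throughout the package.
#' @param path file path.
#' @return readers return tibbles; writers return `path` invisibly.
#' @name activity_io
#' @export
write_activity_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname activity_io
#' @export
read_activity_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(taxon_id = readr::col_character(),
                                          .default = readr::col_integer()))
}

#' @rdname activity_io
#' @export
write_metadata_tsv <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' @rdname activity_io
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(replicate = readr::col_integer(),
                                          .default = readr::col_character()))
}
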