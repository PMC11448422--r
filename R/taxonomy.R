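# Taxonomic assignment from BLAST-style hit tables: top-hit rule above 98%
# identity, otherwise lowest common ancestor over the top 50 hits; plus
# core / non-core membership classification of the assigned taxa.

RANK_LADDER <- c("domain", "phylum", "class", "order", "family",
                 "genus", "species")

#' Default core and non-core members of the honeybee gut microbiota
#'
#' The four core phylotypes (always found in *Apis mellifera* guts) and the
#' three non-core members, matched at genus level because networks are built
#' at genus level.
#'
#' @return character vector of genus names.
#' @export
core_members <- function() {
  c("Lactobacillus", "Bifidobacterium", "Gilliamella", "Snodgrassella")
}

#' @rdname core_members
#' @export
noncore_members <- function() {
  c("Frischella", "Bartonella", "Parasaccharibacter")
}

#' Sort and truncate a hit table per the assignment contract
#'
#' Hits are ordered per query by bitscore descending, ties broken by percent
#' identity descending then taxonomy path lexicographically; at most
#' `max_hits` hits are retained per query.
#'
#' @param hits tibble with columns query_id, taxonomy_path,
#'   percent_identity, bitscore.
#' @param max_hits hits retained per query (default 50).
#' @return the sorted, truncated tibble.
#' @export
rank_hits <- function(hits, max_hits = 50) {
  hits <- as_tibble(hits)
  stopifnot(all(c("query_id", "taxonomy_path", "percent_identity",
                  "bitscore") %in% names(hits)))
  hits %>%
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$percent_identity),
                   .data$taxonomy_path) %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::slice_head(n = max_hits) %>%
    dplyr::ungroup()
}

# Longest common prefix of rank-split paths; character(0) if none.
lca_path <- function(paths) {
  split <- strsplit(paths, ";", fixed = TRUE)
  depth <- min(lengths(split))
  if (depth == 0) return(character(0))
  out <- character(0)
  for (d in seq_len(depth)) {
    level <- vapply(split, `[[`, character(1), d)
    if (length(unique(level)) > 1) break
    out <- c(out, level[1])
  }
  out
}

#' Assign taxonomy from a hit table
#'
#' Per query: if the best hit exceeds `identity_threshold` percent identity,
#' the query takes that hit's full path (species-level assignment).
#' Otherwise the lineage is the lowest common ancestor — the longest common
#' rank prefix — of the top `max_hits` hits, assigned at the deepest shared
#' rank. Queries whose hits share no rank at all, and queries with no hits,
#' come back unassigned.
#'
#' An optional MEGAN-style top-percent filter can restrict the LCA to hits
#' whose bitscore is within `lca_top_percent` percent of the best hit; it is
#' off by default.
#'
#' @param hits tibble with columns query_id, taxonomy_path,
#'   percent_identity, bitscore (one row per hit).
#' @param queries query ids to report on; defaults to those present in
#'   `hits`. Queries listed here but absent from `hits` (no matches at all)
#'   come back unassigned rather than erroring.
#' @param identity_threshold strict lower bound for the top-hit rule
#'   (default 98: "above 98%" means `> 98`).
#' @param max_hits hits used per query (default 50).
#' @param lca_top_percent `NULL` (off) or a percentage: keep hits with
#'   bitscore >= (1 - pct/100) * best bitscore before the LCA.
#' @return tibble (taxon_id, lineage, assignment_rank, membership) with one
#'   row per query; membership is `"unassigned"` here and is refined by
#'   [classify_membership()].
#' @export
assign_taxonomy <- function(hits, queries = NULL, identity_threshold = 98,
                            max_hits = 50, lca_top_percent = NULL) {
  hits <- rank_hits(hits, max_hits = max_hits)
  queries <- queries %||% unique(hits$query_id)
  purrr::map_dfr(queries, function(q) {
    h <- hits[hits$query_id == q, ]
    if (nrow(h) == 0) {
      return(tibble(taxon_id = q, lineage = NA_character_,
                    assignment_rank = NA_character_,
                    membership = "unassigned"))
    }
    if (h$percent_identity[1] > identity_threshold) {
      return(tibble(taxon_id = q, lineage = h$taxonomy_path[1],
                    assignment_rank = "species", membership = "unassigned"))
    }
    if (!is.null(lca_top_percent)) {
      keep <- h$bitscore >= (1 - lca_top_percent / 100) * max(h$bitscore)
      h <- h[keep, ]
    }
    prefix <- lca_path(h$taxonomy_path)
    if (length(prefix) == 0) {
      return(tibble(taxon_id = q, lineage = NA_character_,
                    assignment_rank = NA_character_,
                    membership = "unassigned"))
    }
    tibble(taxon_id = q,
           lineage = paste(prefix, collapse = ";"),
           assignment_rank = RANK_LADDER[length(prefix)],
           membership = "unassigned")
  })
}

#' Extract the genus (or another rank) from a lineage
#'
#' @param lineage semicolon-delimited path (domain first).
#' @param rank one of the 7 ladder ranks.
#' @return the name at that rank, or `NA` if the lineage is truncated above
#'   it.
#' @export
lineage_rank <- function(lineage, rank = "genus") {
  idx <- match(rank, RANK_LADDER)
  stopifnot(!is.na(idx))
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    if (length(p) >= idx && !is.na(p[idx])) p[idx] else NA_character_
  }, character(1))
}

#' Classify taxa as core / non-core members
#'
#' Matches each record's genus (or species, when the lists are species
#' level) case-insensitively against the core list first, then the non-core
#' list; anything else is `"other"`, and records with no lineage at the
#' matching rank stay `"unassigned"`.
#'
#' @param records tibble from [assign_taxonomy()] (needs `lineage`).
#' @param core_list,noncore_list character vectors; must be disjoint.
#' @param rank matching rank, `"genus"` (default) or `"species"`.
#' @return `records` with the `membership` column filled in.
#' @export
classify_membership <- function(records,
                                core_list = core_members(),
                                noncore_list = noncore_members(),
                                rank = c("genus", "species")) {
  rank <- match.arg(rank)
  if (length(intersect(tolower(core_list), tolower(noncore_list)))) {
    stop("core and non-core lists overlap", call. = FALSE)
  }
  records <- as_tibble(records)
  name <- ifelse(is.na(records$lineage), NA_character_,
                 lineage_rank(records$lineage, rank))
  membership <- dplyr::case_when(
    is.na(name) ~ "unassigned",
    tolower(name) %in% tolower(core_list) ~ "core",
    tolower(name) %in% tolower(noncore_list) ~ "non-core",
    TRUE ~ "other")
  records$membership <- membership
  records
}
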