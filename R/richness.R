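#' Collapse a community table to a taxonomic rank
#'
#' Sums OTU counts into the distinct names found at the requested rank of
#' the taxonomy map. Taxa unassigned at that rank must carry the explicit
#' name `"unclassified"`, which becomes one taxon of the collapsed table
#' (drop it afterwards with `dplyr::select()` if a different convention is
#' wanted). The grand total of counts is conserved.
#'
#' @param table A community table at OTU resolution.
#' @param taxonomy A taxonomy map covering every taxon in `table`.
#' @param rank One of `taxonomy_ranks()`.
#' @return A community tibble whose taxon columns are rank-level names.
#' @export
collapse_to_rank <- function(table, taxonomy, rank) {
  table <- as_community_table(table, require_consecutive = FALSE)
  taxonomy <- as_taxonomy(taxonomy)
  rank <- match.arg(rank, taxonomy_ranks())
  taxa <- taxon_columns(table)
  missing <- setdiff(taxa, taxonomy$taxon)
  if (length(missing)) {
    abort(paste0("taxon '", missing[1], "' is absent from the taxonomy map"))
  }
  groups <- taxonomy[[rank]][match(taxa, taxonomy$taxon)]
  m <- count_matrix(table)
  collapsed <- t(rowsum(t(m), group = groups))
  rebuild_table(table, collapsed[, sort(colnames(collapsed)), drop = FALSE])
}

#' Per-sample richness and its summary at a rank
#'
#' Counts, for each sample, the taxa with non-zero reads at the requested
#' rank (or at OTU resolution with `rank = "otu"`) and summarizes the
#' per-sample values as mean, standard deviation, and range. A taxon is
#' "present" iff its count is at least 1; there is no relative-abundance
#' floor. The SD is the population form (divisor n), the convention under
#' which the published bioreactor richness summaries are exactly
#' reproducible from their per-sample values.
#'
#' @param table A community table.
#' @param taxonomy Taxonomy map; may be `NULL` when `rank = "otu"`.
#' @param rank `"otu"` or one of `taxonomy_ranks()`.
#' @param count_unclassified Count the pooled `"unclassified"` name as one
#'   taxon at the rank (default `TRUE`).
#' @return A one-row tibble with columns `rank`, `mean`, `sd`, `min`, `max`,
#'   `n_samples`, and a `per_sample` list-column of the per-sample richness
#'   values.
#' @export
summarize_richness <- function(table, taxonomy = NULL, rank = "otu",
                               count_unclassified = TRUE) {
  table <- as_community_table(table, require_consecutive = FALSE)
  rank <- match.arg(rank, c("otu", taxonomy_ranks()))
  if (rank != "otu") {
    if (is.null(taxonomy)) abort("a taxonomy map is needed for rank collapsing")
    table <- collapse_to_rank(table, taxonomy, rank)
    if (!count_unclassified && "unclassified" %in% names(table)) {
      table[["unclassified"]] <- NULL
    }
  }
  per_sample <- as.integer(rowSums(count_matrix(table) > 0))
  dplyr::bind_cols(tibble::tibble(rank = rank), richness_stats(per_sample))
}

#' Summary statistics of a richness vector
#'
#' Mean, population SD (divisor n), and range of per-sample richness
#' values. Exposed so published per-sample richness series can be
#' summarized directly without rebuilding a count table.
#'
#' @param per_sample Integer vector of per-sample richness values.
#' @return A one-row tibble with `mean`, `sd`, `min`, `max`, `n_samples`,
#'   and `per_sample` as a list-column.
#' @export
richness_stats <- function(per_sample) {
  stopifnot(is.numeric(per_sample), length(per_sample) >= 1)
  mu <- mean(per_sample)
  tibble::tibble(
    mean = mu,
    sd = sqrt(mean((per_sample - mu)^2)),
    min = min(per_sample),
    max = max(per_sample),
    n_samples = length(per_sample),
    per_sample = list(as.integer(per_sample))
  )
}

#' Richness summaries across all ranks
#'
#' Convenience wrapper running [summarize_richness()] at OTU resolution and
#' at each of the five named ranks, mirroring a per-rank richness summary
#' table for one reactor.
#'
#' @inheritParams summarize_richness
#' @return A tibble with one row per rank.
#' @export
richness_by_rank <- function(table, taxonomy, count_unclassified = TRUE) {
  purrr::map_dfr(
    c("otu", taxonomy_ranks()),
    function(rk) summarize_richness(table, taxonomy, rk,
                                    count_unclassified = count_unclassified)
  )
}
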