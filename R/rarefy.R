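#' Rarefy a community table to even depth
#'
#' Library-size normalization by random subsampling without replacement:
#' each sample's reads are drawn down to exactly `depth` reads (multivariate
#' hypergeometric per sample), so richness and similarity are comparable
#' across samples sequenced to different depths. In the bioreactor study
#' design this is 13422 reads per monthly sample, the smallest library among
#' the 24.
#'
#' Subsampling is delegated to [vegan::rrarefy()] under a fixed seed;
#' the same seed always yields a bit-identical table, and the global RNG
#' state is left untouched.
#'
#' @param table A community table.
#' @param depth Target reads per sample; every sample must have at least
#'   this many reads.
#' @param seed Integer seed controlling the subsample.
#' @return A community tibble whose rows each sum to exactly `depth`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample = c("m1", "m2"), month = 1:2,
#'   A = c(10L, 4L), B = c(5L, 8L)
#' )
#' rarefy(tbl, depth = 10, seed = 1)
#' @export
rarefy <- function(table, depth, seed) {
  table <- as_community_table(table)
  stopifnot(length(depth) == 1, depth >= 1, depth == round(depth))
  m <- count_matrix(table)
  totals <- rowSums(m)
  if (any(totals < depth)) {
    shallow <- rownames(m)[totals < depth][1]
    abort(paste0("sample '", shallow, "' has ", totals[shallow],
                 " reads, fewer than depth ", depth))
  }
  # counts are validated as non-negative integers above, so vegan's
  # smallest-count heuristic warning is spurious here
  out <- withr::with_seed(as.integer(seed),
                          suppressWarnings(vegan::rrarefy(m, depth)))
  rebuild_table(table, out)
}
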