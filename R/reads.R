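#' Read a FASTA file into a tibble
#'
#' Minimal sequence import for the quality-filter stage: one row per record,
#' sequences uppercased. Only the `{A, C, G, T, N}` alphabet is meaningful
#' downstream (ambiguous bases are counted as `N`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header text up to the first
#'   whitespace) and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(paste0("malformed FASTA: line 1 ('", substr(lines[1], 1, 30),
                 "') precedes any '>' header"))
  }
  rec <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate read id: '", ids[duplicated(ids)][1], "'"))
  }
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    function(x) paste(x, collapse = ""), character(1)
  )
  # headers with no body line (empty sequence) are kept as ""
  all_seqs <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  all_seqs[names(seqs)] <- seqs
  tibble::tibble(id = ids, sequence = toupper(unname(all_seqs)))
}

#' Quality-filter pyrosequencing reads
#'
#' Drops reads with more than `max_ambiguous` ambiguous bases (`N`) and reads
#' shorter than `min_length` bases, the standard denoising step applied to
#' 454 amplicon libraries before classification. Boundary cases are kept:
#' a read with exactly `max_ambiguous` Ns or exactly `min_length` bases
#' passes. Filtering is idempotent and preserves input order.
#'
#' @param reads A tibble with columns `id` and `sequence`
#'   (see [read_fasta()]).
#' @param max_ambiguous Maximum number of `N` bases tolerated (default 1).
#' @param min_length Minimum sequence length in bases (default 150).
#' @return The filtered read tibble.
#' @export
qc_filter <- function(reads, max_ambiguous = 1, min_length = 150) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (max_ambiguous < 0 || min_length < 0) {
    abort("max_ambiguous and min_length must be >= 0")
  }
  seqs <- toupper(reads$sequence)
  n_amb <- vapply(strsplit(seqs, ""), function(s) sum(s == "N"), integer(1))
  keep <- n_amb <= max_ambiguous & nchar(seqs) >= min_length
  tibble::as_tibble(reads[keep, , drop = FALSE])
}
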