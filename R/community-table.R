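#' Community count tables
#'
#' A community table is an ordinary tibble holding a samples-by-taxa count
#' matrix with time metadata: a `sample` column of unique labels, a `month`
#' column of strictly increasing consecutive integer month indices, and one
#' non-negative integer count column per taxon. Every analysis function in
#' the package takes this layout as its first argument, so results chain
#' with the pipe.
#'
#' `as_community_table()` validates a data frame against this contract and
#' returns it as a tibble; all other functions call it on entry, so malformed
#' input fails early with a message naming the offending column or sample.
#'
#' @param x A data frame with columns `sample`, `month`, and one numeric
#'   column per taxon.
#' @param require_consecutive Require month indices to be consecutive
#'   (`TRUE`, the default) or merely strictly increasing.
#'
#' @return A validated tibble in community-table layout.
#' @examples
#' tbl <- tibble::tibble(
#'   sample = c("m1", "m2"), month = 1:2,
#'   OTU_1 = c(5L, 3L), OTU_2 = c(0L, 2L)
#' )
#' as_community_table(tbl)
#' @export
as_community_table <- function(x, require_consecutive = TRUE) {
  if (!is.data.frame(x)) {
    abort("community table must be a data frame")
  }
  x <- tibble::as_tibble(x)
  if (!all(c("sample", "month") %in% names(x))) {
    abort("community table needs 'sample' and 'month' columns")
  }
  if (nrow(x) < 1) {
    abort("community table must have at least one sample")
  }
  if (anyDuplicated(x$sample)) {
    dup <- x$sample[duplicated(x$sample)][1]
    abort(paste0("duplicate sample id: '", dup, "'"))
  }
  mons <- x$month
  if (!is.numeric(mons) || any(is.na(mons)) || any(mons != round(mons))) {
    abort("'month' must be integer month indices")
  }
  if (nrow(x) > 1) {
    d <- diff(mons)
    if (any(d <= 0)) abort("month indices must be strictly increasing")
    if (require_consecutive && any(d != 1)) {
      abort("month indices must be consecutive")
    }
  }
  taxa <- taxon_columns(x)
  if (length(taxa) < 1) abort("community table has no taxon columns")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon id: '", taxa[duplicated(taxa)][1], "'"))
  }
  for (tx in taxa) {
    v <- x[[tx]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      abort(paste0("counts for taxon '", tx, "' must be non-negative integers"))
    }
  }
  x$month <- as.integer(x$month)
  x$sample <- as.character(x$sample)
  x
}

taxon_columns <- function(x) {
  setdiff(names(x), c("sample", "month"))
}

# samples-by-taxa integer matrix with sample ids as rownames
count_matrix <- function(x) {
  taxa <- taxon_columns(x)
  m <- as.matrix(x[, taxa, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample
  m
}

rebuild_table <- function(x, counts) {
  dplyr::bind_cols(
    x[, c("sample", "month")],
    tibble::as_tibble(as.data.frame(counts), .name_repair = "minimal")
  )
}

#' Read and write community tables
#'
#' Tab-separated layout: first row holds taxon ids, first column the sample
#' id, second column the integer month index, remaining cells integer counts.
#' `write_community_table()` followed by `read_community_table()` is the
#' identity on valid tables.
#'
#' @param path Path to a tab-separated community table.
#' @param table A community table (see [as_community_table()]).
#' @return `read_community_table()` returns a validated community tibble;
#'   `write_community_table()` returns `path` invisibly.
#' @export
read_community_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    month = readr::col_integer(),
    .default = readr::col_double()
  ))
  as_community_table(df)
}

#' @rdname read_community_table
#' @export
write_community_table <- function(table, path) {
  table <- as_community_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Taxonomy maps
#'
#' A taxonomy map is a tibble with columns `taxon`, `phylum`, `class`,
#' `order`, `family`, `genus`. Every rank must be filled for every taxon;
#' taxa with no assignment at a rank carry the explicit name
#' `"unclassified"`.
#'
#' @param x A data frame with the six taxonomy columns.
#' @return A validated taxonomy tibble.
#' @export
as_taxonomy <- function(x) {
  if (!is.data.frame(x)) abort("taxonomy must be a data frame")
  x <- tibble::as_tibble(x)
  needed <- c("taxon", taxonomy_ranks())
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("taxonomy is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, needed]
  if (anyDuplicated(x$taxon)) {
    abort(paste0("duplicate taxon in taxonomy: '",
                 x$taxon[duplicated(x$taxon)][1], "'"))
  }
  for (rk in needed) {
    v <- x[[rk]]
    if (!is.character(v)) v <- as.character(v)
    if (any(is.na(v)) || any(!nzchar(v))) {
      abort(paste0("taxonomy column '", rk, "' has empty or missing names"))
    }
    x[[rk]] <- v
  }
  x
}

#' Taxonomic ranks recognised by the package
#'
#' @return Character vector of rank names, coarsest first.
#' @export
taxonomy_ranks <- function() {
  c("phylum", "class", "order", "family", "genus")
}

#' @rdname as_taxonomy
#' @param path Path to a tab-separated taxonomy file with header
#'   `taxon phylum class order family genus`.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  as_taxonomy(df)
}

#' @rdname as_taxonomy
#' @param taxonomy A taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- as_taxonomy(taxonomy)
  readr::write_tsv(taxonomy, path)
  invisible(path)
}

#' Covariate tables
#'
#' Environmental and operational covariates in wide layout: a `sample`
#' column matching the community table's sample order, plus one numeric
#' column per variable. Group membership of variables (wastewater `W`,
#' operational `O`, scale `S`) is supplied separately where needed, as a
#' named character vector, e.g. `c(BOD = "W", temperature = "O",
#' scale = "S")`.
#'
#' @param x A data frame with a `sample` column and numeric variable columns.
#' @return A validated covariate tibble.
#' @export
as_covariate_table <- function(x) {
  if (!is.data.frame(x)) abort("covariates must be a data frame")
  x <- tibble::as_tibble(x)
  if (!"sample" %in% names(x)) abort("covariate table needs a 'sample' column")
  vars <- setdiff(names(x), "sample")
  if (!length(vars)) abort("covariate table has no variable columns")
  for (v in vars) {
    if (!is.numeric(x[[v]]) || any(is.na(x[[v]]))) {
      abort(paste0("covariate '", v, "' must be numeric with no missing values"))
    }
  }
  x$sample <- as.character(x$sample)
  x
}

covariate_matrix <- function(cov) {
  vars <- setdiff(names(cov), "sample")
  m <- as.matrix(cov[, vars, drop = FALSE])
  rownames(m) <- cov$sample
  m
}

#' Log2(x + 1) transform of covariates
#'
#' Standardizes skewed, non-negative environmental measurements before
#' constrained ordination. A binary scale indicator in `{0, 1}` maps to
#' itself, so indicator coding survives the transform.
#'
#' @param cov A covariate table (see [as_covariate_table()]).
#' @return The covariate tibble with every variable replaced by
#'   `log2(value + 1)`.
#' @export
transform_covariates <- function(cov) {
  cov <- as_covariate_table(cov)
  vars <- setdiff(names(cov), "sample")
  for (v in vars) {
    if (any(cov[[v]] < 0)) {
      abort(paste0("covariate '", v, "' has negative values; log2(x+1) needs x >= 0"))
    }
    cov[[v]] <- log2(cov[[v]] + 1)
  }
  cov
}
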