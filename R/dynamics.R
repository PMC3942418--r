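#' Pairwise sample similarity matrices
#'
#' `pearson_matrix()` computes the Pearson product-moment correlation
#' between every pair of samples' relative-abundance profiles over the
#' union of taxa — the fingerprint-style similarity used by moving-window
#' analysis. `sorenson_matrix()` computes the Sorenson (Sørensen–Dice)
#' similarity `2|A ∩ B| / (|A| + |B|)` on presence/absence, the binary
#' index underlying ordination of community membership.
#'
#' Both are exactly symmetric and invariant to taxon ordering. Pearson
#' requires at least 2 taxa and errors on a sample with zero total reads or
#' a flat (zero-variance) profile; Sorenson requires every sample to have
#' at least one taxon present.
#'
#' @param table A community table (month order is kept but not required to
#'   be consecutive).
#' @return An object of class `similarity_matrix`: a list with the
#'   symmetric `values` matrix (sample ids as dimnames), `metric`, and
#'   `sample_ids`. `tidy()` returns the lower triangle as a long tibble.
#' @export
pearson_matrix <- function(table) {
  table <- as_community_table(table, require_consecutive = FALSE)
  m <- count_matrix(table)
  if (ncol(m) < 2) abort("Pearson similarity needs at least 2 taxa")
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(paste0("sample '", rownames(m)[totals == 0][1], "' has zero total reads"))
  }
  rel <- m / totals
  flat <- apply(rel, 1, function(x) stats::var(x) == 0)
  if (any(flat)) {
    abort(paste0("sample '", rownames(m)[flat][1],
                 "' has a constant profile; Pearson correlation is undefined"))
  }
  vals <- stats::cor(t(rel), method = "pearson")
  vals <- (vals + t(vals)) / 2
  new_similarity_matrix(vals, "pearson", table$sample)
}

#' @rdname pearson_matrix
#' @export
sorenson_matrix <- function(table) {
  table <- as_community_table(table, require_consecutive = FALSE)
  pa <- count_matrix(table) > 0
  rich <- rowSums(pa)
  if (any(rich == 0)) {
    abort(paste0("sample '", rownames(pa)[rich == 0][1], "' has no taxa present"))
  }
  shared <- tcrossprod(pa * 1)
  vals <- 2 * shared / outer(rich, rich, `+`)
  new_similarity_matrix(vals, "sorenson", table$sample)
}

new_similarity_matrix <- function(values, metric, sample_ids) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, metric = metric, sample_ids = sample_ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("%s similarity matrix, %d samples\n",
              x$metric, length(x$sample_ids)))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  v <- x$values
  idx <- which(lower.tri(v), arr.ind = TRUE)
  tibble::tibble(
    sample_a = x$sample_ids[idx[, 2]],
    sample_b = x$sample_ids[idx[, 1]],
    similarity = v[idx],
    metric = x$metric
  )
}

#' Write a similarity matrix as square TSV
#'
#' @param x A `similarity_matrix`.
#' @param path Output path; the matrix is written with a header row and a
#'   leading `sample` column.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "similarity_matrix"))
  df <- tibble::as_tibble(as.data.frame(x$values))
  df <- dplyr::bind_cols(tibble::tibble(sample = x$sample_ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Moving-window community change
#'
#' The rate-of-change view of a monthly community series: for every pair of
#' consecutive months the percent change is `100 - 100 * r`, where r is the
#' Pearson correlation of the two months' relative-abundance profiles. The
#' series mean and population SD give the monthly rate Δt (percent per
#' month). A perfectly anticorrelated pair gives a change of 200; values
#' above 100 are reported as computed, not clamped.
#'
#' @param table A community table with at least 2 consecutive monthly
#'   samples.
#' @return An object of class `moving_window`. `tidy()` returns one row per
#'   consecutive month pair with the change value; `glance()` the mean and
#'   population SD of the change series (`delta_t_mean`, `delta_t_sd`,
#'   both percent).
#' @export
moving_window <- function(table) {
  table <- as_community_table(table)
  if (nrow(table) < 2) abort("moving-window analysis needs at least 2 samples")
  sim <- pearson_matrix(table)
  n <- nrow(table)
  r <- sim$values[cbind(2:n, 1:(n - 1))]
  change <- 100 - 100 * r
  structure(
    list(
      pairs = tibble::tibble(
        month = table$month[-1],
        previous_month = table$month[-n],
        sample = table$sample[-1],
        previous_sample = table$sample[-n],
        similarity = r,
        change = change
      ),
      delta_t_mean = mean(change),
      delta_t_sd = sqrt(mean((change - mean(change))^2)),
      sd_convention = "population"
    ),
    class = "moving_window"
  )
}

#' @export
print.moving_window <- function(x, ...) {
  cat(sprintf(
    "Moving-window community change: Δt = %.1f%% ± %.1f%% per month (%d pairs)\n",
    x$delta_t_mean, x$delta_t_sd, nrow(x$pairs)))
  invisible(x)
}

#' @export
tidy.moving_window <- function(x, ...) x$pairs

#' @export
glance.moving_window <- function(x, ...) {
  tibble::tibble(
    delta_t_mean = x$delta_t_mean,
    delta_t_sd = x$delta_t_sd,
    n_pairs = nrow(x$pairs),
    sd_convention = x$sd_convention
  )
}

#' @export
autoplot.moving_window <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$month, .data$change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$delta_t_mean, linetype = 2) +
    ggplot2::labs(
      x = "Month x (change vs month x - 1)", y = "Change (%)",
      title = sprintf("Δt = %.1f%% ± %.1f%% per month",
                      object$delta_t_mean, object$delta_t_sd)
    )
}
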