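#' Taxa accumulation over time windows
#'
#' Computes the taxa-time accumulation series S(T): the number of distinct
#' taxa observed at least once within an observation window of T consecutive
#' months, for T = 1 .. number of samples. Two windowing schemes are
#' offered:
#'
#' * `"sliding"` (default): S(T) is the mean over all `n - T + 1` contiguous
#'   windows of length T — the standard species-time construction in the
#'   macroecology literature, which uses every window of each span.
#' * `"nested"`: S(T) is the richness of the first T samples, i.e. a single
#'   accumulation from the start of the series.
#'
#' S(1) is the mean per-sample richness, S(n) the total distinct taxa
#' observed, and S is non-decreasing in T.
#'
#' @param table A community table with at least 2 consecutive monthly
#'   samples.
#' @param scheme `"sliding"` or `"nested"`.
#' @return A tibble of class `accum_curve` with columns `window_length`
#'   and `richness`, carrying the scheme as an attribute.
#' @export
accumulation_curve <- function(table, scheme = c("sliding", "nested")) {
  table <- as_community_table(table)
  scheme <- match.arg(scheme)
  pa <- count_matrix(table) > 0
  n <- nrow(pa)
  if (n < 2) abort("accumulation needs at least 2 samples")
  s <- vapply(seq_len(n), function(T) {
    if (scheme == "nested") {
      sum(colSums(pa[seq_len(T), , drop = FALSE]) > 0)
    } else {
      starts <- seq_len(n - T + 1)
      mean(vapply(starts, function(i) {
        sum(colSums(pa[i:(i + T - 1), , drop = FALSE]) > 0)
      }, double(1)))
    }
  }, double(1))
  out <- tibble::tibble(window_length = seq_len(n), richness = s)
  attr(out, "scheme") <- scheme
  class(out) <- c("accum_curve", class(out))
  out
}

#' Fit the taxa-time power law S = c * T^w
#'
#' Ordinary least squares of log10 S on log10 T. The slope is the
#' taxa-time exponent w, a dimensionless measure of temporal turnover
#' (w = 0: a closed, static community; w = 1: complete replacement each
#' step); the intercept gives the constant c = 10^intercept, and r-squared
#' is the usual coefficient of determination of the log-log regression.
#' A constant series (zero slope, zero residual variance) is reported as
#' w = 0, r-squared 0, with a warning.
#'
#' @param curve An [accumulation_curve()] result, or any data frame with
#'   columns `window_length` and `richness` (all richness values positive,
#'   at least 3 points).
#' @return An object of class `ttr_fit` with elements `w`, `c`,
#'   `r_squared`, and `curve`. `tidy()` returns the per-window data with
#'   fitted values; `glance()` the fit statistics; `autoplot()` the log-log
#'   scatter with the fitted line.
#' @examples
#' curve <- tibble::tibble(window_length = 1:12, richness = 2 * (1:12)^0.5)
#' fit_power_law(curve)
#' @export
fit_power_law <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("window_length", "richness") %in% names(curve)))
  T_ <- curve$window_length
  S <- curve$richness
  if (length(T_) < 3) abort("power-law fit needs at least 3 points")
  if (any(S <= 0)) abort("all richness values must be positive for a log-log fit")
  x <- log10(T_)
  y <- log10(S)
  fit <- stats::lm(y ~ x)
  w <- unname(stats::coef(fit)[2])
  c_ <- 10^unname(stats::coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < .Machine$double.eps * length(y)) {
    warn("constant accumulation series: reporting w = 0, r_squared = 0")
    w <- 0
    r2 <- 0
    c_ <- 10^mean(y)
  } else {
    r2 <- 1 - sum(stats::resid(fit)^2) / ss_tot
  }
  structure(
    list(w = w, c = c_, r_squared = r2,
         curve = tibble::as_tibble(curve[, c("window_length", "richness")]),
         scheme = attr(curve, "scheme") %||% NA_character_),
    class = "ttr_fit"
  )
}

#' @export
print.ttr_fit <- function(x, ...) {
  cat("Taxa-time power-law fit  S = c * T^w\n")
  cat(sprintf("  w = %.4f   c = %.3f   r^2 = %.4f   (%d windows, scheme: %s)\n",
              x$w, x$c, x$r_squared, nrow(x$curve),
              ifelse(is.na(x$scheme), "unknown", x$scheme)))
  invisible(x)
}

#' @export
tidy.ttr_fit <- function(x, ...) {
  dplyr::mutate(x$curve, fitted = x$c * .data$window_length^x$w)
}

#' @export
glance.ttr_fit <- function(x, ...) {
  tibble::tibble(w = x$w, c = x$c, r_squared = x$r_squared,
                 n_windows = nrow(x$curve), scheme = x$scheme)
}

#' @export
autoplot.ttr_fit <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$window_length, .data$richness)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Window length T (months)", y = "Taxa S(T)",
      title = sprintf("S = %.2f T^%.2f  (r² = %.3f)",
                      object$c, object$w, object$r_squared)
    )
}

#' Per-group taxa-time exponents and dominant/rare contrast
#'
#' Splits the OTU table by a taxonomic rank (typically phylum), fits the
#' taxa-time power law to each group's own OTUs, and contrasts the mean
#' exponent of the `k` most abundant groups against the `k` rarest, where
#' abundance ranking uses each group's mean relative abundance across all
#' samples. Groups absent from fewer than 2 samples, or with an all-zero
#' or constant accumulation series, are dropped from scoring.
#'
#' @param table A community table at OTU resolution.
#' @param taxonomy A taxonomy map covering every taxon.
#' @param rank Rank defining the groups (default `"phylum"`).
#' @param k Number of groups in each extreme of the dominant/rare contrast.
#' @param scheme Windowing scheme passed to [accumulation_curve()].
#' @param include_unclassified Score the pooled `"unclassified"` group
#'   (default `FALSE`, since it is not a biological lineage).
#' @return An object of class `group_ttr`. `tidy()` returns one row per
#'   group (mean relative abundance, w, c, r_squared); `glance()` the
#'   dominant and rare mean exponents.
#' @export
per_group_ttr <- function(table, taxonomy, rank = "phylum", k = 5,
                          scheme = c("sliding", "nested"),
                          include_unclassified = FALSE) {
  table <- as_community_table(table)
  taxonomy <- as_taxonomy(taxonomy)
  rank <- match.arg(rank, taxonomy_ranks())
  scheme <- match.arg(scheme)
  taxa <- taxon_columns(table)
  missing <- setdiff(taxa, taxonomy$taxon)
  if (length(missing)) {
    abort(paste0("taxon '", missing[1], "' is absent from the taxonomy map"))
  }
  groups <- taxonomy[[rank]][match(taxa, taxonomy$taxon)]
  if (!include_unclassified) {
    keep <- groups != "unclassified"
    taxa <- taxa[keep]
    groups <- groups[keep]
  }
  m <- count_matrix(table)[, taxa, drop = FALSE]
  rel <- m / rowSums(count_matrix(table))
  per_group <- purrr::map_dfr(sort(unique(groups)), function(g) {
    cols <- taxa[groups == g]
    sub <- m[, cols, drop = FALSE]
    n_samples_present <- sum(rowSums(sub) > 0)
    mra <- mean(rowSums(rel[, cols, drop = FALSE]))
    if (n_samples_present < 2) {
      return(tibble::tibble(group = g, relative_abundance = mra,
                            w = NA_real_, c = NA_real_,
                            r_squared = NA_real_, scored = FALSE))
    }
    sub_tbl <- rebuild_table(table, sub)
    curve <- accumulation_curve(sub_tbl, scheme = scheme)
    if (any(curve$richness <= 0)) {
      return(tibble::tibble(group = g, relative_abundance = mra,
                            w = NA_real_, c = NA_real_,
                            r_squared = NA_real_, scored = FALSE))
    }
    fit <- withCallingHandlers(
      fit_power_law(curve),
      warning = function(w_) invokeRestart("muffleWarning")
    )
    tibble::tibble(group = g, relative_abundance = mra, w = fit$w,
                   c = fit$c, r_squared = fit$r_squared, scored = TRUE)
  })
  scored <- dplyr::filter(per_group, .data$scored)
  if (nrow(scored) < 2) abort("fewer than 2 groups could be scored")
  if (k > nrow(scored)) {
    abort(paste0("k = ", k, " exceeds the ", nrow(scored), " scored groups"))
  }
  contrast <- dominant_rare_means(scored, k = k)
  structure(
    list(per_group = per_group, k = k,
         dominant_mean_w = contrast$dominant_mean_w,
         rare_mean_w = contrast$rare_mean_w,
         dominant_groups = contrast$dominant_groups,
         rare_groups = contrast$rare_groups,
         rank = rank, scheme = scheme),
    class = "group_ttr"
  )
}

#' Dominant and rare group mean exponents
#'
#' Given per-group exponents and mean relative abundances (either fitted by
#' [per_group_ttr()] or transcribed from a published per-phylum table),
#' averages the exponents of the `k` most abundant and the `k` least
#' abundant groups. Ties in abundance are broken by group name for
#' reproducibility.
#'
#' @param groups A data frame with columns `group`, `relative_abundance`,
#'   and `w`.
#' @param k Number of groups in each extreme.
#' @return A list with `dominant_mean_w`, `rare_mean_w`,
#'   `dominant_groups`, `rare_groups`.
#' @export
dominant_rare_means <- function(groups, k = 5) {
  stopifnot(is.data.frame(groups),
            all(c("group", "relative_abundance", "w") %in% names(groups)))
  groups <- dplyr::filter(groups, !is.na(.data$w))
  if (k < 1 || k > nrow(groups)) {
    abort("k must be between 1 and the number of scored groups")
  }
  ord <- order(-groups$relative_abundance, groups$group)
  dom <- groups$group[ord][seq_len(k)]
  rare <- groups$group[rev(ord)][seq_len(k)]
  list(
    dominant_mean_w = mean(groups$w[groups$group %in% dom]),
    rare_mean_w = mean(groups$w[groups$group %in% rare]),
    dominant_groups = dom,
    rare_groups = rare
  )
}

#' @export
print.group_ttr <- function(x, ...) {
  n_scored <- sum(x$per_group$scored)
  cat(sprintf("Per-%s taxa-time exponents (%d groups scored, scheme: %s)\n",
              x$rank, n_scored, x$scheme))
  cat(sprintf("  dominant mean w (top %d by abundance): %.3f\n",
              x$k, x$dominant_mean_w))
  cat(sprintf("  rare mean w (bottom %d):               %.3f\n",
              x$k, x$rare_mean_w))
  invisible(x)
}

#' @export
tidy.group_ttr <- function(x, ...) x$per_group

#' @export
glance.group_ttr <- function(x, ...) {
  tibble::tibble(
    dominant_mean_w = x$dominant_mean_w,
    rare_mean_w = x$rare_mean_w,
    k = x$k,
    n_groups_scored = sum(x$per_group$scored),
    rank = x$rank, scheme = x$scheme
  )
}

#' @export
autoplot.group_ttr <- function(object, ...) {
  dat <- dplyr::filter(object$per_group, .data$scored)
  ggplot2::ggplot(dat, ggplot2::aes(.data$relative_abundance, .data$w)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean relative abundance", y = "TTR exponent w",
                  title = paste0("Temporal turnover by ", object$rank))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
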