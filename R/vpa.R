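#' Variance partitioning of community inertia over three covariate groups
#'
#' Decomposes the inertia a constrained ordination explains into the unique
#' and shared contributions of three covariate groups — conventionally
#' wastewater characteristics (`W`), operational parameters (`O`), and
#' reactor scale (`S`). Seven constrained and partial CCAs are run (each
#' group alone and each pairwise/three-way union) and the seven Venn
#' regions are solved by inclusion-exclusion on explained fractions:
#' e.g. the pure `W` fraction is the fraction explained by all groups
#' together minus the fraction explained by `O` and `S` alone.
#'
#' Fractions are raw (unadjusted) inertia ratios. Shared (intersection)
#' fractions can come out slightly negative — a well-known property of
#' inclusion-exclusion partitions of explained variation — and are reported
#' as computed rather than truncated.
#'
#' @param table A community table.
#' @param cov A covariate table holding all grouped variables.
#' @param groups Named character vector mapping every variable in `cov`
#'   to `"W"`, `"O"`, or `"S"`; each group must be non-empty.
#' @return An object of class `vpa` with a `fractions` tibble over
#'   components `W`, `O`, `S`, `W:O`, `W:S`, `O:S`, `W:O:S`, and
#'   `unexplained` (fractions of total inertia summing to 1), plus the
#'   `explained_fraction` of the full model. `tidy()` returns the
#'   fractions; `autoplot()` a bar chart.
#' @export
variance_partition <- function(table, cov, groups) {
  table <- as_community_table(table, require_consecutive = FALSE)
  cov <- as_covariate_table(cov)
  vars <- setdiff(names(cov), "sample")
  if (is.null(names(groups)) || !all(vars %in% names(groups))) {
    abort("'groups' must be a named vector covering every covariate")
  }
  groups <- groups[vars]
  if (!all(groups %in% c("W", "O", "S"))) {
    abort("group labels must be 'W', 'O', or 'S'")
  }
  for (g in c("W", "O", "S")) {
    if (!any(groups == g)) abort(paste0("group '", g, "' has no variables"))
  }
  sub_cov <- function(labels) {
    cov[, c("sample", vars[groups %in% labels]), drop = FALSE]
  }
  frac <- function(labels) {
    cca_fit(table, sub_cov(labels))$explained_fraction
  }
  aW <- frac("W"); aO <- frac("O"); aS <- frac("S")
  aWO <- frac(c("W", "O")); aWS <- frac(c("W", "S")); aOS <- frac(c("O", "S"))
  aWOS <- frac(c("W", "O", "S"))

  # Venn regions by inclusion-exclusion on explained fractions
  triple <- aW + aO + aS - aWO - aWS - aOS + aWOS
  pure_W <- aWOS - aOS
  pure_O <- aWOS - aWS
  pure_S <- aWOS - aWO
  WO <- aW + aO - aWO - triple
  WS <- aW + aS - aWS - triple
  OS <- aO + aS - aOS - triple

  fractions <- tibble::tibble(
    component = c("W", "O", "S", "W:O", "W:S", "O:S", "W:O:S", "unexplained"),
    fraction = c(pure_W, pure_O, pure_S, WO, WS, OS, triple, 1 - aWOS)
  )
  structure(
    list(fractions = fractions, explained_fraction = aWOS,
         marginal = c(W = aW, O = aO, S = aS,
                      `W:O` = aWO, `W:S` = aWS, `O:S` = aOS, `W:O:S` = aWOS),
         group_sizes = table(factor(groups, levels = c("W", "O", "S")))),
    class = "vpa"
  )
}

#' @export
print.vpa <- function(x, ...) {
  cat("Variance partitioning of community inertia\n")
  cat(sprintf("  full model explains %.1f%% of total inertia\n",
              100 * x$explained_fraction))
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-12s %6.1f%%\n", f$component[i], 100 * f$fraction[i]))
  }
  invisible(x)
}

#' @export
tidy.vpa <- function(x, ...) x$fractions

#' @export
glance.vpa <- function(x, ...) {
  tibble::tibble(
    explained_fraction = x$explained_fraction,
    unexplained = 1 - x$explained_fraction,
    n_components = 7L
  )
}

#' @export
autoplot.vpa <- function(object, ...) {
  dat <- dplyr::mutate(object$fractions,
                       component = factor(.data$component,
                                          levels = .data$component))
  ggplot2::ggplot(dat, ggplot2::aes(.data$component, 100 * .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Explained inertia (%)",
                  title = "Variance partitioning")
}
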