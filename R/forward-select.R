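#' Monte Carlo forward selection of ordination covariates
#'
#' Builds a constrained-ordination model variable by variable: at each step
#' the candidate adding the most constrained inertia beyond the variables
#' already selected is tested with a permutation test, and selection stops
#' as soon as the best candidate fails the significance threshold. The
#' permutation scheme is residual permutation: the candidate is residualized
#' on the selected variables under row-mass weighting, the residuals are
#' shuffled across samples, and the added inertia is recomputed. The
#' p-value uses the `(b + 1) / (m + 1)` estimator (b permuted statistics at
#' least as large as observed, m permutations), so the smallest attainable
#' p at 499 permutations is 0.002.
#'
#' @param table A community table.
#' @param cov A covariate table of candidate variables.
#' @param n_permutations Number of Monte Carlo permutations per test
#'   (default 499).
#' @param threshold Significance level for admitting a variable
#'   (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `forward_selection`: `selected` and
#'   `rejected` tibbles (variable, added inertia, p-value, step), plus
#'   `n_permutations` and `threshold`. `tidy()` binds both with a
#'   `selected` flag.
#' @export
forward_select <- function(table, cov, n_permutations = 499,
                           threshold = 0.05, seed = 1) {
  table <- as_community_table(table, require_consecutive = FALSE)
  cov <- as_covariate_table(cov)
  check_cov_alignment(table, cov)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  candidates <- setdiff(names(cov), "sample")
  if (!length(candidates)) abort("no candidate variables")
  dec <- chi_square_decomposition(count_matrix(table))
  X <- covariate_matrix(cov)
  Xw <- weighted_design(X, dec$r)

  withr::with_seed(as.integer(seed), {
    selected <- tibble::tibble(variable = character(), added_inertia = double(),
                               p_value = double(), step = integer())
    remaining <- candidates
    Zw <- NULL
    step <- 0L
    repeat {
      if (!length(remaining)) break
      stats_now <- vapply(remaining, function(v) {
        added_inertia(dec$Q, Xw[, v, drop = FALSE], Zw)
      }, double(1))
      best <- remaining[which.max(stats_now)]
      p <- permutation_p(dec$Q, Xw[, best, drop = FALSE], Zw,
                         stats_now[best], n_permutations)
      if (p >= threshold) break
      step <- step + 1L
      selected <- dplyr::bind_rows(selected, tibble::tibble(
        variable = best, added_inertia = unname(stats_now[best]),
        p_value = p, step = step
      ))
      Zw <- cbind(Zw, Xw[, best, drop = FALSE])
      remaining <- setdiff(remaining, best)
    }
    # p-values for everything not admitted, conditioned on the final model
    rejected <- purrr::map_dfr(remaining, function(v) {
      stat <- added_inertia(dec$Q, Xw[, v, drop = FALSE], Zw)
      tibble::tibble(
        variable = v, added_inertia = stat,
        p_value = permutation_p(dec$Q, Xw[, v, drop = FALSE], Zw, stat,
                                n_permutations),
        step = NA_integer_
      )
    })
  })

  structure(
    list(selected = selected, rejected = rejected,
         n_permutations = as.integer(n_permutations), threshold = threshold),
    class = "forward_selection"
  )
}

# inertia a single (weighted) candidate column explains beyond Zw
added_inertia <- function(Q, xw, Zw) {
  if (!is.null(Zw)) xw <- residualize(xw, Zw)
  nrm2 <- sum(xw^2)
  if (nrm2 < .Machine$double.eps) return(0)
  sum(crossprod(xw, Q)^2) / nrm2
}

permutation_p <- function(Q, xw, Zw, observed, n_permutations) {
  if (!is.null(Zw)) xw <- residualize(xw, Zw)
  n <- nrow(Q)
  b <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- xw[sample.int(n), , drop = FALSE]
    if (!is.null(Zw)) perm <- residualize(perm, Zw)
    if (added_inertia(Q, perm, NULL) >= observed) b <- b + 1L
  }
  (b + 1) / (n_permutations + 1)
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection (%d permutations, threshold %.3f)\n",
              x$n_permutations, x$threshold))
  if (nrow(x$selected)) {
    cat("  selected:\n")
    for (i in seq_len(nrow(x$selected))) {
      cat(sprintf("    %d. %s  (added inertia %.4f, p = %.4f)\n",
                  x$selected$step[i], x$selected$variable[i],
                  x$selected$added_inertia[i], x$selected$p_value[i]))
    }
  } else {
    cat("  no variables selected\n")
  }
  if (nrow(x$rejected)) {
    cat(sprintf("  rejected: %s\n", paste(x$rejected$variable, collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.forward_selection <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$selected, selected = TRUE),
    dplyr::mutate(x$rejected, selected = FALSE)
  )
}

#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$selected),
    n_rejected = nrow(x$rejected),
    n_permutations = x$n_permutations,
    threshold = x$threshold
  )
}
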