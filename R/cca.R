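#' Canonical correspondence analysis from the chi-square eigen-formulation
#'
#' Constrained ordination of a community count table on environmental
#' covariates, implemented directly from the underlying matrix algebra:
#' the count table is converted to its chi-square-standardized residual
#' matrix `Q`, with `Q[i, j] = (p_ij - r_i c_j) / sqrt(r_i c_j)` where
#' `p_ij` are relative frequencies and `r`, `c` the row and column masses;
#' covariates are centred and scaled under row-mass weighting and `Q` is
#' projected onto their span; the singular value decomposition of the
#' projection yields the constrained axes (eigenvalues are squared singular
#' values). Total inertia is `sum(Q^2)`, identical to the classical
#' chi-square statistic of the table divided by its grand total, and the
#' explained fraction is constrained inertia over total inertia.
#'
#' Site scores are reported in site-focused scaling (weighted principal
#' coordinates of the linear-combination scores), species scores in the
#' corresponding standard coordinates, and biplot scores as correlations
#' of the weighted covariates with the constrained axes.
#'
#' @param table A community table with at least 3 samples and 2 taxa.
#' @param cov A covariate table whose `sample` column matches the community
#'   table's samples in order. No covariate may be constant, and there must
#'   be at most `n samples - 1` covariates.
#' @param condition Optional covariate table of conditioning variables
#'   (disjoint from `cov`): both `Q`-relevant covariates are residualized
#'   on them under row-mass weighting, so constrained inertia measures what
#'   `cov` explains beyond the condition.
#' @return An object of class `cca_fit` with `eigenvalues`,
#'   `total_inertia`, `constrained_inertia`, `explained_fraction`,
#'   `site_scores`, `species_scores`, and `biplot_scores`. `tidy()` returns
#'   the eigenvalues; `glance()` the inertia summary.
#' @examples
#' sim <- simulate_community(simulation_config(n_months = 6, depth = 500,
#'                                             n_phyla = 4, taxa_per_phylum = 10,
#'                                             seed = 1))
#' fit <- cca_fit(sim$community, sim$covariates[c("sample", "temperature")])
#' glance(fit)
#' @export
cca_fit <- function(table, cov, condition = NULL) {
  table <- as_community_table(table, require_consecutive = FALSE)
  cov <- as_covariate_table(cov)
  dec <- chi_square_decomposition(count_matrix(table))
  n <- nrow(dec$Q)
  if (n < 3) abort("CCA needs at least 3 samples")
  if (ncol(dec$Q) < 2) abort("CCA needs at least 2 taxa")
  check_cov_alignment(table, cov)
  X <- covariate_matrix(cov)
  if (ncol(X) > n - 1) {
    abort(paste0("more covariates (", ncol(X), ") than samples - 1 (", n - 1, ")"))
  }
  Xw <- weighted_design(X, dec$r)
  Zw <- NULL
  if (!is.null(condition) && length(setdiff(names(condition), "sample"))) {
    condition <- as_covariate_table(condition)
    check_cov_alignment(table, condition)
    overlap <- intersect(setdiff(names(cov), "sample"),
                         setdiff(names(condition), "sample"))
    if (length(overlap)) {
      abort(paste0("variable '", overlap[1],
                   "' appears in both cov and condition"))
    }
    Zw <- weighted_design(covariate_matrix(condition), dec$r)
    pre_norm <- sqrt(colSums(Xw^2))
    Xw <- residualize(Xw, Zw)
    # a covariate fully absorbed by the condition leaves a numerically
    # zero residual; zero it outright so qr() cannot rank it as noise
    absorbed <- sqrt(colSums(Xw^2)) < 1e-8 * pmax(pre_norm, 1e-300)
    Xw[, absorbed] <- 0
  }
  proj <- project_onto(dec$Q, Xw)
  sv <- svd(proj$fitted)
  keep <- which(sv$d^2 > 1e-12 * dec$total_inertia)
  n_axes <- min(length(keep), proj$rank, n - 1, ncol(dec$Q) - 1)
  keep <- head(keep, n_axes)
  eig <- sv$d[keep]^2
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  site_scores <- sweep(U %*% diag(sv$d[keep], length(keep)), 1,
                       sqrt(dec$r), "/")
  species_scores <- sweep(V, 1, sqrt(dec$c), "/")
  biplot_scores <- biplot_correlations(Xw, U)
  ax <- sprintf("CCA%d", seq_along(keep))
  dimnames(site_scores) <- list(table$sample, ax)
  dimnames(species_scores) <- list(colnames(dec$Q), ax)
  structure(
    list(
      eigenvalues = eig,
      total_inertia = dec$total_inertia,
      constrained_inertia = sum(proj$fitted^2),
      explained_fraction = sum(proj$fitted^2) / dec$total_inertia,
      site_scores = site_scores,
      species_scores = species_scores,
      biplot_scores = biplot_scores,
      n_axes = length(keep),
      conditioned = !is.null(Zw)
    ),
    class = "cca_fit"
  )
}

#' @rdname cca_fit
#' @export
partial_cca_fit <- function(table, cov, condition) {
  cca_fit(table, cov, condition = condition)
}

# chi-square residual decomposition of a count matrix
chi_square_decomposition <- function(m) {
  if (any(rowSums(m) == 0)) {
    abort(paste0("sample '", rownames(m)[rowSums(m) == 0][1],
                 "' has zero total reads"))
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  P <- m / sum(m)
  r <- rowSums(P)
  c_ <- colSums(P)
  E <- outer(r, c_)
  Q <- (P - E) / sqrt(E)
  list(Q = Q, r = r, c = c_, total_inertia = sum(Q^2))
}

# row-mass weighted, centred design matrix; errors on constant columns
weighted_design <- function(X, r) {
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    abort(paste0("covariate '", colnames(X)[const][1],
                 "' is constant across samples"))
  }
  Xc <- sweep(X, 2, colSums(X * r))
  Xc * sqrt(r)
}

residualize <- function(Xw, Zw) {
  Xw - qr.fitted(qr(Zw), Xw)
}

project_onto <- function(Q, Xw) {
  qrx <- qr(Xw)
  if (qrx$rank == 0) {
    return(list(fitted = Q * 0, rank = 0L))
  }
  list(fitted = qr.fitted(qrx, Q), rank = qrx$rank)
}

biplot_correlations <- function(Xw, U) {
  if (!ncol(U)) {
    return(matrix(0, ncol(Xw), 0, dimnames = list(colnames(Xw), NULL)))
  }
  norms <- sqrt(colSums(Xw^2))
  b <- crossprod(sweep(Xw, 2, pmax(norms, .Machine$double.eps), "/"), U)
  rownames(b) <- colnames(Xw)
  colnames(b) <- paste0("CCA", seq_len(ncol(U)))
  b
}

check_cov_alignment <- function(table, cov) {
  if (nrow(cov) != nrow(table) || !all(cov$sample == table$sample)) {
    abort("covariate samples must match the community table's samples in order")
  }
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("Canonical correspondence analysis\n")
  cat(sprintf("  total inertia:       %.4f\n", x$total_inertia))
  cat(sprintf("  constrained inertia: %.4f (%.1f%%%s)\n",
              x$constrained_inertia, 100 * x$explained_fraction,
              if (x$conditioned) ", after conditioning" else ""))
  cat(sprintf("  constrained axes:    %d\n", x$n_axes))
  invisible(x)
}

#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(
    axis = paste0("CCA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion = x$eigenvalues / x$total_inertia
  )
}

#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = x$constrained_inertia,
    explained_fraction = x$explained_fraction,
    n_axes = x$n_axes,
    conditioned = x$conditioned
  )
}

#' @export
autoplot.cca_fit <- function(object, ...) {
  if (object$n_axes < 2) {
    abort("biplot needs at least 2 constrained axes")
  }
  sites <- tibble::as_tibble(object$site_scores[, 1:2],
                             .name_repair = "minimal")
  names(sites) <- c("CCA1", "CCA2")
  sites$sample <- rownames(object$site_scores)
  bip <- tibble::as_tibble(object$biplot_scores[, 1:2],
                           .name_repair = "minimal")
  names(bip) <- c("CCA1", "CCA2")
  bip$variable <- rownames(object$biplot_scores)
  scale_arrow <- max(abs(sites$CCA1), abs(sites$CCA2))
  ggplot2::ggplot(sites, ggplot2::aes(.data$CCA1, .data$CCA2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -0.6, size = 3) +
    ggplot2::geom_segment(
      data = bip,
      ggplot2::aes(x = 0, y = 0,
                   xend = .data$CCA1 * scale_arrow,
                   yend = .data$CCA2 * scale_arrow),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = bip,
      ggplot2::aes(x = .data$CCA1 * scale_arrow * 1.08,
                   y = .data$CCA2 * scale_arrow * 1.08,
                   label = .data$variable), size = 3
    ) +
    ggplot2::labs(title = "CCA biplot (site-focused scaling)")
}
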