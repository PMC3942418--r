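# Small in-code fixtures shared across test files.

# community tibble from a counts matrix (rows = months 1..n)
make_table <- function(counts, samples = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  }
  dplyr::bind_cols(
    tibble::tibble(
      sample = samples %||% paste0("m", seq_len(n)),
      month = seq_len(n)
    ),
    tibble::as_tibble(as.data.frame(counts))
  )
}

# random community table with guaranteed non-empty samples
random_table <- function(n_samples, n_taxa, max_count = 20) {
  counts <- matrix(
    sample(0:max_count, n_samples * n_taxa, replace = TRUE),
    n_samples, n_taxa
  )
  empty <- rowSums(counts) == 0
  counts[empty, 1] <- 1L
  make_table(counts)
}

# 4-sample toy with taxon sets {A,B,C}, {A,B,D}, {A,C,E}, {A,B,F}
toy_sets_table <- function() {
  make_table(rbind(
    c(1, 1, 1, 0, 0, 0),
    c(1, 1, 0, 1, 0, 0),
    c(1, 0, 1, 0, 1, 0),
    c(1, 1, 0, 0, 0, 1)
  ) |> `colnames<-`(LETTERS[1:6]))
}

# tiny taxonomy over two phyla for collapse tests
toy_taxonomy <- function(taxa, phyla) {
  tibble::tibble(
    taxon = taxa, phylum = phyla,
    class = paste0(phyla, "_c"), order = paste0(phyla, "_o"),
    family = paste0(phyla, "_f"), genus = paste0(phyla, "_g")
  )
}

# closed-form Pearson correlation, independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# brute-force sliding-window accumulation: enumerate every window
sliding_oracle <- function(counts) {
  pa <- counts > 0
  n <- nrow(pa)
  vapply(seq_len(n), function(T) {
    vals <- vapply(seq_len(n - T + 1), function(i) {
      sum(apply(pa[i:(i + T - 1), , drop = FALSE], 2, any))
    }, double(1))
    mean(vals)
  }, double(1))
}

# direct double-loop chi-square statistic of a count table
chisq_oracle <- function(m) {
  total <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- rs[i] * cs[j] / total
      if (e > 0) acc <- acc + (m[i, j] - e)^2 / e
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
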