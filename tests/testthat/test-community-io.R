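test_that("FASTA reading parses records, uppercases, and flags headerless input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 sample=a", "ACGT", "acgt", ">r2", "ggcc"), f)
  reads <- read_fasta(f)
  expect_equal(reads$id, c("r1", "r2"))
  expect_equal(reads$sequence, c("ACGTACGT", "GGCC"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">r1", "ACGT"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("qc_filter applies the N-count and length boundaries and is idempotent", {
  reads <- tibble::tibble(
    id = c("two_n", "one_n_at_150", "short_clean", "clean"),
    sequence = c(
      paste0(strrep("A", 198), "NN"),          # 2 Ns, length 200 -> removed
      paste0(strrep("A", 149), "N"),           # 1 N, length 150 -> kept
      strrep("A", 149),                        # 0 Ns, length 149 -> removed
      strrep("ACGT", 50)
    )
  )
  kept <- qc_filter(reads)
  expect_equal(kept$id, c("one_n_at_150", "clean"))
  expect_identical(qc_filter(kept), kept)
  expect_error(qc_filter(reads, max_ambiguous = -1), ">= 0")
})

test_that("rarefaction hits the target depth exactly, deterministically, and without inflating counts", {
  tbl <- make_table(rbind(c(10, 5, 3), c(2, 1, 0), c(7, 7, 7)))
  out <- rarefy(tbl, depth = 3, seed = 11)
  m_in <- as.matrix(tbl[, -(1:2)])
  m_out <- as.matrix(out[, -(1:2)])
  expect_true(all(rowSums(m_out) == 3))
  expect_true(all(m_out <= m_in))
  expect_identical(out, rarefy(tbl, depth = 3, seed = 11))
  expect_false(identical(m_out, as.matrix(rarefy(tbl, depth = 3, seed = 12)[, -(1:2)])))

  # a sample already at depth is returned unchanged
  at_depth <- make_table(rbind(c(2, 1), c(1, 2)))
  expect_equal(rarefy(at_depth, depth = 3, seed = 1), as_community_table(at_depth))

  expect_error(rarefy(tbl, depth = 4, seed = 1), "m2")
})

test_that("rarefaction is unbiased: mean relative abundance converges to the input", {
  tbl <- make_table(matrix(c(40, 30, 20, 10), 1))
  rel_in <- c(40, 30, 20, 10) / 100
  draws <- vapply(1:1000, function(s) {
    as.numeric(rarefy(tbl, depth = 20, seed = s)[1, -(1:2)]) / 20
  }, double(4))
  mc_mean <- rowMeans(draws)
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(mc_mean - rel_in) <= 3 * mc_se + 1e-12))
})

test_that("rank collapsing sums within lineage names and conserves the grand total", {
  tbl <- make_table(rbind(c(3, 4, 1), c(0, 2, 5)))
  tax <- toy_taxonomy(c("t1", "t2", "t3"),
                      c("Proteobacteria", "Proteobacteria", "Bacteroidetes"))
  out <- collapse_to_rank(tbl, tax, "phylum")
  expect_equal(sort(setdiff(names(out), c("sample", "month"))),
               c("Bacteroidetes", "Proteobacteria"))
  expect_equal(out$Proteobacteria, c(7, 2))
  expect_equal(sum(as.matrix(out[, -(1:2)])), sum(as.matrix(tbl[, -(1:2)])))

  # all-distinct names: identity up to relabeling
  tax2 <- toy_taxonomy(c("t1", "t2", "t3"), c("P1", "P2", "P3"))
  out2 <- collapse_to_rank(tbl, tax2, "phylum")
  expect_equal(unname(as.matrix(out2[, c("P1", "P2", "P3")])),
               unname(as.matrix(tbl[, c("t1", "t2", "t3")])))

  expect_error(collapse_to_rank(tbl, tax[-1, ], "phylum"), "t1")

  # property: conservation on random tables
  for (i in 1:20) {
    rt <- random_table(4, 8)
    taxa <- setdiff(names(rt), c("sample", "month"))
    rtax <- toy_taxonomy(taxa, sample(c("A", "B", "C"), 8, replace = TRUE))
    expect_equal(sum(as.matrix(collapse_to_rank(rt, rtax, "phylum")[, -(1:2)])),
                 sum(as.matrix(rt[, -(1:2)])))
  }
})

test_that("richness summaries use presence >= 1 and the population SD", {
  tbl <- make_table(rbind(c(1, 0, 2), c(3, 1, 1)))
  tax <- toy_taxonomy(c("t1", "t2", "t3"), c("A", "A", "B"))
  otu <- summarize_richness(tbl)
  expect_equal(otu$per_sample[[1]], c(2L, 3L))
  phylum <- summarize_richness(tbl, tax, "phylum")
  expect_equal(phylum$per_sample[[1]], c(2L, 2L))
  expect_equal(phylum$sd, 0)

  stats <- richness_stats(c(2, 4, 6))
  expect_equal(stats$mean, 4)
  expect_equal(stats$sd, sqrt(8 / 3))  # divisor n, not n - 1
  expect_equal(c(stats$min, stats$max), c(2, 6))
})

test_that("table and taxonomy files round-trip and invalid input is rejected", {
  tbl <- as_community_table(random_table(3, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(tbl, f)
  expect_equal(read_community_table(f), tbl)

  tax <- as_taxonomy(toy_taxonomy(c("a", "b"), c("P1", "P2")))
  g <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, g)
  expect_equal(read_taxonomy(g), tax)

  expect_error(as_community_table(tibble::tibble(
    sample = c("a", "b"), month = 1:2, t1 = c(-1, 2))), "non-negative")
  expect_error(as_community_table(tibble::tibble(
    sample = c("a", "a"), month = 1:2, t1 = c(1, 2))), "duplicate sample")
  expect_error(as_community_table(tibble::tibble(
    sample = c("a", "b"), month = c(2, 1), t1 = c(1, 2))), "increasing")
  expect_error(as_taxonomy(tibble::tibble(taxon = "a", phylum = "P")),
               "missing column")
})

test_that("log2(x + 1) covariate transform fixes 0 and maps powers of two", {
  cov <- tibble::tibble(sample = c("a", "b", "c"), v = c(0, 1, 7))
  out <- transform_covariates(cov)
  expect_equal(out$v, c(0, 1, 3))
  expect_error(transform_covariates(tibble::tibble(sample = "a", v = -1)),
               "negative")
})
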