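test_that("total inertia equals the chi-square statistic over the grand total", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    p <- sample(2:8, 1)
    m <- matrix(sample(0:15, n * p, replace = TRUE), n, p)
    m[rowSums(m) == 0, 1] <- 1
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2) next
    tbl <- make_table(m)
    cov <- tibble::tibble(sample = tbl$sample, x = rnorm(nrow(tbl)))
    fit <- cca_fit(tbl, cov)
    expect_lt(abs(fit$total_inertia - chisq_oracle(m) / sum(m)), 1e-10)
  }
})

test_that("CCA agrees with vegan on eigenvalues and constrained inertia", {
  set.seed(42)
  m <- matrix(rpois(12 * 20, 8), 12)
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, x1 = rnorm(12),
                        x2 = runif(12), x3 = rnorm(12))
  fit <- cca_fit(tbl, cov)
  ref <- vegan::cca(m ~ x1 + x2 + x3, data = as.data.frame(cov[, -1]))
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, ref$CCA$tot.chi, tolerance = 1e-10)
  expect_equal(fit$eigenvalues, unname(ref$CCA$eig), tolerance = 1e-8)
})

test_that("a full-rank covariate set explains total inertia exactly", {
  set.seed(3)
  m <- matrix(rpois(5 * 8, 6) + 1, 5)
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, x1 = rnorm(5), x2 = rnorm(5),
                        x3 = rnorm(5), x4 = rnorm(5))
  fit <- cca_fit(tbl, cov)
  expect_lt(abs(fit$explained_fraction - 1), 1e-9)
})

test_that("a covariate orthogonal to compositional variation explains nothing", {
  # two duplicated-sample blocks with equal totals: all variation is
  # between blocks; a within-block contrast is row-mass-orthogonal to it
  block <- rbind(c(6, 3, 1), c(6, 3, 1), c(1, 4, 5), c(1, 4, 5))
  tbl <- make_table(block)
  within <- tibble::tibble(sample = tbl$sample, x = c(1, -1, 1, -1))
  expect_lt(cca_fit(tbl, within)$constrained_inertia, 1e-10)

  # the block indicator captures the between-block inertia, which here is
  # the whole of the table's inertia (computed by the chi-square oracle)
  between <- tibble::tibble(sample = tbl$sample, x = c(1, 1, 0, 0))
  fit <- cca_fit(tbl, between)
  expect_equal(fit$constrained_inertia, chisq_oracle(block) / sum(block),
               tolerance = 1e-10)
  expect_lte(length(fit$eigenvalues), 1)
})

test_that("eigenvalues are invariant to taxon order and covariate rescaling", {
  set.seed(9)
  m <- matrix(rpois(8 * 10, 5), 8)
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, x1 = rnorm(8), x2 = runif(8))
  e1 <- cca_fit(tbl, cov)$eigenvalues
  perm <- c("sample", "month", sample(setdiff(names(tbl), c("sample", "month"))))
  e2 <- cca_fit(tbl[, perm], cov)$eigenvalues
  cov_scaled <- dplyr::mutate(cov, x1 = 100 * x1 - 7, x2 = -0.01 * x2 + 3)
  e3 <- cca_fit(tbl, cov_scaled)$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-10)
  expect_equal(e1, e3, tolerance = 1e-10)
})

test_that("CCA rejects degenerate inputs with informative errors", {
  tbl <- make_table(matrix(rpois(4 * 5, 4) + 1, 4))
  expect_error(cca_fit(tbl, tibble::tibble(sample = tbl$sample,
                                           flat = rep(2, 4))), "flat")
  too_many <- tibble::tibble(sample = tbl$sample, a = rnorm(4), b = rnorm(4),
                             c = rnorm(4), d = rnorm(4))
  expect_error(cca_fit(tbl, too_many), "covariates")
})

test_that("partial CCA isolates inertia beyond the conditioning variables", {
  set.seed(12)
  m <- matrix(rpois(8 * 12, 6), 8)
  m[rowSums(m) == 0, 1] <- 1
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, x = rnorm(8))
  cond <- tibble::tibble(sample = tbl$sample, z = rnorm(8))

  # conditioning on the covariate itself leaves nothing to explain
  same <- tibble::tibble(sample = tbl$sample, z = cov$x)
  expect_lt(partial_cca_fit(tbl, cov, same)$constrained_inertia, 1e-10)

  # empty condition reduces to ordinary CCA
  empty <- tibble::tibble(sample = tbl$sample)
  expect_equal(partial_cca_fit(tbl, cov, empty)$constrained_inertia,
               cca_fit(tbl, cov)$constrained_inertia)

  # additivity: marginal = partial when the two designs are row-mass orthogonal
  eq <- make_table(rbind(c(5, 1, 2), c(2, 5, 1), c(1, 2, 5), c(3, 3, 2)))
  o1 <- tibble::tibble(sample = eq$sample, x = c(1, 1, -1, -1))
  o2 <- tibble::tibble(sample = eq$sample, z = c(1, -1, 1, -1))
  marginal <- cca_fit(eq, o1)$constrained_inertia
  partial <- partial_cca_fit(eq, o1, o2)$constrained_inertia
  expect_equal(partial, marginal, tolerance = 1e-10)

  expect_error(partial_cca_fit(tbl, cov, tibble::tibble(sample = tbl$sample,
                                                        x = rnorm(8))), "both")
})

test_that("forward selection admits a strong gradient at the minimal p-value", {
  # a banded compositional gradient (adjacent months share taxa) that the
  # covariate orders perfectly; shuffling it destroys the alignment
  m <- matrix(1, 12, 14)
  for (i in 1:12) m[i, i:(i + 2)] <- m[i, i:(i + 2)] + 25
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, gradient = 1:12,
                        noise = rnorm(12))
  fs <- forward_select(tbl, cov, n_permutations = 499, seed = 2)
  expect_true("gradient" %in% fs$selected$variable)
  expect_equal(fs$selected$p_value[fs$selected$variable == "gradient"],
               1 / 500)
})

test_that("forward selection stops cleanly when nothing passes", {
  set.seed(8)
  m <- matrix(rpois(10 * 15, 5), 10)
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, n1 = rnorm(10), n2 = rnorm(10))
  fs <- forward_select(tbl, cov, n_permutations = 99, threshold = 0.001,
                       seed = 5)
  expect_equal(nrow(fs$selected), 0)
  expect_setequal(fs$rejected$variable, c("n1", "n2"))
  expect_true(all(fs$rejected$p_value > 0 & fs$rejected$p_value <= 1))
  expect_error(forward_select(tbl, cov, n_permutations = 0), "permutations")
})

test_that("variance partitioning fractions sum to one and respect structure", {
  set.seed(21)
  m <- matrix(rpois(10 * 15, 6), 10)
  m[rowSums(m) == 0, 1] <- 1
  tbl <- make_table(m)
  cov <- tibble::tibble(sample = tbl$sample, w1 = rnorm(10), w2 = rnorm(10),
                        o1 = rnorm(10), s1 = rnorm(10))
  groups <- c(w1 = "W", w2 = "W", o1 = "O", s1 = "S")
  vp <- variance_partition(tbl, cov, groups)
  expect_lt(abs(sum(vp$fractions$fraction) - 1), 1e-9)
  expect_equal(vp$fractions$fraction[8], 1 - vp$explained_fraction)

  # symmetry: relabeling the groups permutes, never changes, the fractions
  relabeled <- c(w1 = "O", w2 = "O", o1 = "S", s1 = "W")
  vp2 <- variance_partition(tbl, cov, relabeled)
  expect_equal(vp2$fractions$fraction[vp2$fractions$component == "O"],
               vp$fractions$fraction[vp$fractions$component == "W"],
               tolerance = 1e-10)
  expect_equal(vp2$explained_fraction, vp$explained_fraction,
               tolerance = 1e-10)

  expect_error(variance_partition(tbl, cov, c(w1 = "W", w2 = "W", o1 = "O",
                                              s1 = "O")), "'S'")
})

test_that("orthogonal single-variable groups partition with zero intersections", {
  set.seed(33)
  counts <- t(rmultinom(8, 400, prob = runif(12) + 0.2))
  tbl <- make_table(counts)
  # equal row totals make the factorial contrasts row-mass orthogonal
  cov <- tibble::tibble(sample = tbl$sample,
                        w = rep(c(1, -1), each = 4),
                        o = rep(c(1, -1, 1, -1), each = 2),
                        s = rep(c(1, -1), 4))
  vp <- variance_partition(tbl, cov, c(w = "W", o = "O", s = "S"))
  f <- setNames(vp$fractions$fraction, vp$fractions$component)
  expect_lt(max(abs(f[c("W:O", "W:S", "O:S", "W:O:S")])), 1e-9)
  expect_equal(unname(f["W"]), cca_fit(tbl, cov[, c("sample", "w")])$explained_fraction,
               tolerance = 1e-9)
})

test_that("duplicated covariate groups share their signal instead of owning it", {
  set.seed(44)
  m <- matrix(rpois(9 * 12, 5) + 1, 9)
  tbl <- make_table(m)
  x <- rnorm(9)
  cov <- tibble::tibble(sample = tbl$sample, w = x, o = x, s = rnorm(9))
  vp <- variance_partition(tbl, cov, c(w = "W", o = "O", s = "S"))
  f <- setNames(vp$fractions$fraction, vp$fractions$component)
  expect_lt(abs(f["W"]), 1e-9)
  expect_lt(abs(f["O"]), 1e-9)
  expect_gt(f["W:O"], 0.01)
})
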