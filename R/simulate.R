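#' Configuration for the synthetic community generator
#'
#' Bundles and validates the parameters of [simulate_community()]. The
#' defaults emulate the sampling design of a year-long monthly 16S survey
#' of an activated-sludge bioreactor: 12 monthly samples of 13422 reads,
#' thousands of OTUs spread over 15 phyla with a strongly skewed abundance
#' distribution in which a few dominant phyla hold most of the reads,
#' high month-to-month persistence for dominant-phylum taxa, transient
#' rare taxa, and a seasonal temperature covariate partially coupled to
#' composition.
#'
#' @param n_months Number of monthly samples (default 12).
#' @param depth Reads per sample (default 13422).
#' @param n_phyla Number of phyla in the regional pool (default 15).
#' @param taxa_per_phylum OTUs per phylum (default 200).
#' @param pool_abundance_decay Geometric decay of phylum pool mass with
#'   abundance rank, in (0, 1) (default 0.75).
#' @param n_dominant_phyla Number of phyla in the dominant persistence
#'   class (default 4).
#' @param persistence_dominant,persistence_rare Probability that a taxon
#'   present one month is still present the next, by phylum class.
#' @param colonization_dominant,colonization_rare Probability that an
#'   absent taxon appears the next month, by phylum class.
#' @param abundance_sigma Lognormal spread (log scale SD) of taxon
#'   abundances within a phylum (default 1.5).
#' @param env_coupling Shift, per unit of the standardized seasonal
#'   covariate, applied to the log-abundance of responsive taxa
#'   (default 0.5; 0 decouples composition from the environment).
#' @param responsive_fraction Fraction of taxa responsive to the seasonal
#'   covariate (default 0.1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_months = 12, depth = 13422, n_phyla = 15,
                              taxa_per_phylum = 200,
                              pool_abundance_decay = 0.75,
                              n_dominant_phyla = 4,
                              persistence_dominant = 0.9,
                              persistence_rare = 0.6,
                              colonization_dominant = 0.3,
                              colonization_rare = 0.1,
                              abundance_sigma = 1.5,
                              env_coupling = 0.5,
                              responsive_fraction = 0.1,
                              seed = 1) {
  cfg <- list(
    n_months = as.integer(n_months), depth = as.integer(depth),
    n_phyla = as.integer(n_phyla),
    taxa_per_phylum = as.integer(taxa_per_phylum),
    pool_abundance_decay = pool_abundance_decay,
    n_dominant_phyla = as.integer(n_dominant_phyla),
    persistence_dominant = persistence_dominant,
    persistence_rare = persistence_rare,
    colonization_dominant = colonization_dominant,
    colonization_rare = colonization_rare,
    abundance_sigma = abundance_sigma,
    env_coupling = env_coupling,
    responsive_fraction = responsive_fraction,
    seed = as.integer(seed)
  )
  probs <- c(cfg$persistence_dominant, cfg$persistence_rare,
             cfg$colonization_dominant, cfg$colonization_rare,
             cfg$responsive_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    abort("all persistence/colonization/responsive probabilities must be in [0, 1]")
  }
  if (cfg$pool_abundance_decay <= 0 || cfg$pool_abundance_decay >= 1) {
    abort("pool_abundance_decay must be in (0, 1)")
  }
  if (cfg$n_months < 2) abort("n_months must be >= 2")
  if (cfg$depth < 1) abort("depth must be >= 1")
  if (cfg$n_dominant_phyla < 1 || cfg$n_dominant_phyla >= cfg$n_phyla) {
    abort("n_dominant_phyla must be >= 1 and < n_phyla")
  }
  if (cfg$abundance_sigma < 0 || cfg$env_coupling < 0) {
    abort("abundance_sigma and env_coupling must be >= 0")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a monthly community time series with covariates
#'
#' Generates one bioreactor's OTU table, taxonomy, and covariates under a
#' mechanistic null model of community turnover:
#'
#' * Each taxon's presence follows a two-state Markov chain (persist /
#'   colonize, with probabilities set by its phylum's dominance class) and
#'   starts at the chain's stationary distribution.
#' * Each taxon carries a fixed lognormal latent abundance (the skewed
#'   species-abundance distribution), with phylum pool masses geometric in
#'   abundance rank, so a few phyla dominate; month-to-month change comes
#'   from presence turnover, environmental forcing, and resampling noise.
#' * A seasonal sinusoid (temperature) multiplies the abundance of a
#'   responsive taxon subset by `exp(env_coupling * z)` where `z` is the
#'   standardized sinusoid.
#' * Observed counts are a multinomial draw of `depth` reads per month
#'   from that month's latent relative abundances.
#'
#' The remaining covariates (BOD, TN, TP, pH, DO, SRT, HRT, MLSS) are
#' realistic operating-range noise uncoupled from composition, and the
#' scale indicator is 0; group labels (`W`/`O`/`S`) are returned alongside.
#'
#' @param config A [simulation_config()].
#' @return A list with `community` (community tibble), `taxonomy`
#'   (taxonomy tibble), `covariates` (covariate tibble), `groups` (named
#'   vector mapping covariates to `W`/`O`/`S`), and `config`.
#' @examples
#' sim <- simulate_community(simulation_config(n_months = 6, depth = 1000,
#'                                             n_phyla = 5, taxa_per_phylum = 20,
#'                                             seed = 42))
#' dim(sim$community)
#' @export
simulate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  n_taxa <- cfg$n_phyla * cfg$taxa_per_phylum
  phyla <- sprintf("Phylum_%02d", seq_len(cfg$n_phyla))
  taxa <- sprintf("OTU_%04d", seq_len(n_taxa))
  phylum_of <- rep(phyla, each = cfg$taxa_per_phylum)
  dominant <- phylum_of %in% phyla[seq_len(cfg$n_dominant_phyla)]

  # phylum pool masses geometric in abundance rank; a fixed lognormal
  # abundance for each taxon (the skewed SAD), renormalized within phylum
  mass <- cfg$pool_abundance_decay^(seq_len(cfg$n_phyla) - 1)
  mass <- mass / sum(mass)
  base <- rlnorm(n_taxa, meanlog = 0, sdlog = cfg$abundance_sigma)
  for (k in seq_len(cfg$n_phyla)) {
    idx <- phylum_of == phyla[k]
    base[idx] <- base[idx] / sum(base[idx]) * mass[k]
  }

  pers <- ifelse(dominant, cfg$persistence_dominant, cfg$persistence_rare)
  col_ <- ifelse(dominant, cfg$colonization_dominant, cfg$colonization_rare)
  stationary <- ifelse(col_ + (1 - pers) > 0, col_ / (col_ + (1 - pers)), 1)

  responsive <- runif(n_taxa) < cfg$responsive_fraction
  z <- sin(2 * pi * (seq_len(cfg$n_months) - 1) / 12)

  present <- runif(n_taxa) < stationary
  counts <- matrix(0L, cfg$n_months, n_taxa,
                   dimnames = list(NULL, taxa))
  for (t in seq_len(cfg$n_months)) {
    if (t > 1) {
      u <- runif(n_taxa)
      present <- ifelse(present, u < pers, u < col_)
    }
    latent <- base * present *
      exp(cfg$env_coupling * z[t] * responsive)
    if (sum(latent) == 0) latent[which.max(base)] <- base[which.max(base)]
    counts[t, ] <- rmultinom(1, cfg$depth, latent)[, 1]
  }

  community <- dplyr::bind_cols(
    tibble::tibble(sample = sprintf("m%02d", seq_len(cfg$n_months)),
                   month = seq_len(cfg$n_months)),
    tibble::as_tibble(as.data.frame(counts))
  )

  taxonomy <- synthetic_taxonomy(taxa, phylum_of, cfg$taxa_per_phylum)
  covs <- synthetic_covariates(cfg$n_months, z)

  list(community = as_community_table(community),
       taxonomy = taxonomy,
       covariates = covs$covariates,
       groups = covs$groups,
       config = cfg)
}

# nested lineage labels below the phylum, deterministic in taxon index
synthetic_taxonomy <- function(taxa, phylum_of, taxa_per_phylum) {
  j <- (seq_along(taxa) - 1) %% taxa_per_phylum
  lineage <- function(prefix, n_units) {
    paste0(phylum_of, "_", prefix, sprintf("%02d", j %/% max(1, ceiling(taxa_per_phylum / n_units)) + 1))
  }
  as_taxonomy(tibble::tibble(
    taxon = taxa,
    phylum = phylum_of,
    class = lineage("c", 2),
    order = lineage("o", 4),
    family = lineage("f", 8),
    genus = lineage("g", 25)
  ))
}

# realistic activated-sludge operating ranges; only temperature is seasonal
synthetic_covariates <- function(n_months, z) {
  covariates <- as_covariate_table(tibble::tibble(
    sample = sprintf("m%02d", seq_len(n_months)),
    BOD = pmax(0, 219 + 35 * rnorm(n_months)),
    TN = pmax(0, 52.6 + 8 * rnorm(n_months)),
    TP = pmax(0, 5 + 1.5 * rnorm(n_months)),
    pH = pmax(0, 7.1 + 0.3 * rnorm(n_months)),
    temperature = 20.7 + 4.4 * z + 0.5 * rnorm(n_months),
    DO = pmax(0, 3.5 + 0.5 * rnorm(n_months)),
    SRT = pmax(0, 8.7 + 2.1 * rnorm(n_months)),
    HRT = pmax(0, 8.2 + 1.3 * rnorm(n_months)),
    MLSS = pmax(0, 3775 + 640 * rnorm(n_months)),
    scale = rep(0, n_months)
  ))
  groups <- c(BOD = "W", TN = "W", TP = "W", pH = "W",
              temperature = "O", DO = "O", SRT = "O", HRT = "O", MLSS = "O",
              scale = "S")
  list(covariates = covariates, groups = groups)
}

#' Simulate a paired full-scale / lab-scale reactor contrast
#'
#' Generates two reactors from one configuration: reactor `full` uses the
#' configured persistence probabilities; reactor `lab` lowers both
#' persistence probabilities by `turnover_delta`, producing a community
#' with faster temporal turnover (a larger taxa-time exponent). The two
#' reactors share the same influent wastewater covariates (`W` group) and
#' differ in the scale indicator (0 = full, 1 = lab).
#'
#' @param config A [simulation_config()] for the full-scale reactor.
#' @param turnover_delta Amount (>= 0) subtracted from both persistence
#'   probabilities for the lab reactor.
#' @return A list with elements `full` and `lab` (each holding `community`
#'   and `covariates`), plus the shared `taxonomy` and covariate `groups`.
#' @export
make_two_reactor_pair <- function(config = simulation_config(),
                                  turnover_delta = 0.15) {
  stopifnot(inherits(config, "simulation_config"))
  if (turnover_delta < 0) abort("turnover_delta must be >= 0")
  lab_cfg <- config
  lab_cfg$persistence_dominant <- config$persistence_dominant - turnover_delta
  lab_cfg$persistence_rare <- config$persistence_rare - turnover_delta
  if (lab_cfg$persistence_dominant < 0 || lab_cfg$persistence_rare < 0) {
    abort("turnover_delta pushes a persistence probability below 0")
  }
  lab_cfg$seed <- config$seed + 1L
  full <- simulate_community(config)
  lab <- simulate_community(lab_cfg)
  # shared influent: lab inherits the full-scale wastewater columns
  w_vars <- names(full$groups)[full$groups == "W"]
  lab$covariates[w_vars] <- full$covariates[w_vars]
  lab$covariates$scale <- 1
  lab$community$sample <- sub("^m", "L", lab$community$sample)
  full$community$sample <- sub("^m", "F", full$community$sample)
  lab$covariates$sample <- lab$community$sample
  full$covariates$sample <- full$community$sample
  list(
    full = list(community = full$community, covariates = full$covariates),
    lab = list(community = lab$community, covariates = lab$covariates),
    taxonomy = full$taxonomy,
    groups = full$groups
  )
}

#' Stack a two-reactor pair into one table for joint ordination
#'
#' Binds the two reactors' samples into a single community and covariate
#' table (months renumbered sequentially so the combined table remains a
#' valid time-ordered layout); the scale indicator then separates the
#' reactors in constrained ordination.
#'
#' @param pair Output of [make_two_reactor_pair()].
#' @return A list with stacked `community` and `covariates` tibbles and
#'   the covariate `groups`.
#' @export
stack_reactors <- function(pair) {
  stopifnot(all(c("full", "lab") %in% names(pair)))
  community <- dplyr::bind_rows(pair$full$community, pair$lab$community)
  community$month <- seq_len(nrow(community))
  covariates <- dplyr::bind_rows(pair$full$covariates, pair$lab$covariates)
  list(community = as_community_table(community),
       covariates = as_covariate_table(covariates),
       groups = pair$groups)
}
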