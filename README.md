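# taxatime

Temporal turnover and environmental drivers of microbial community time
series.

`taxatime` is for microbial ecologists with a **monthly (or otherwise
regularly sampled) OTU count table** — e.g. a year of 16S amplicon
surveys from an activated-sludge bioreactor — who want to quantify how
fast the community changes and what co-varies with that change. It
implements, on plain tibbles and with pipe-friendly functions:

* **Taxa–time relationship (TTR).** The accumulation of distinct taxa S
  over observation windows of T months follows a power law
  `S = c·T^w`; the exponent `w` (slope of the log–log regression) is a
  dimensionless measure of temporal turnover (0 = static community,
  1 = complete monthly replacement). Fitted globally, per phylum, and
  contrasted between the most abundant and rarest phyla.
* **Moving-window change.** Percent change `100 − 100·r` between
  consecutive months (Pearson `r` on relative-abundance profiles),
  summarized as Δt mean ± SD per month; plus Pearson and Sørensen
  similarity matrices.
* **Constrained ordination.** Canonical correspondence analysis written
  out from the chi-square eigen-decomposition (total inertia = χ²/N),
  partial CCA, Monte Carlo forward selection of covariates (residual
  permutation, `(b+1)/(m+1)` p-values), and three-way variance
  partitioning of explained inertia into wastewater / operational /
  scale components via inclusion–exclusion.
* **Preprocessing.** FASTA read QC (≤ 1 ambiguous base, ≥ 150 bp),
  seeded without-replacement rarefaction, taxonomic rank collapsing,
  and per-rank richness summaries (population-SD convention).
* **A calibrated synthetic generator** — Markov presence chains,
  lognormal abundances with geometric phylum masses, seasonal
  environmental forcing, multinomial read sampling — so the entire
  chain is testable without sequence data, including a paired
  full-scale / lab-scale reactor contrast.

Fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## A worked example

```r
library(taxatime)

# a paired two-reactor study design: 12 monthly samples x 13422 reads each
pair <- make_two_reactor_pair(simulation_config(seed = 1))
full <- rarefy(pair$full$community, depth = 13422, seed = 8)

fit_power_law(accumulation_curve(full))
#> Taxa-time power-law fit  S = c * T^w
#>   w = 0.3775   c = 751.902   r^2 = 0.9997   (12 windows, scheme: sliding)
```

A turnover exponent of 0.38 with r² > 0.99 says taxon accumulation in
this simulated reactor is an almost perfect power law, with turnover in
the range reported for activated sludge. Dominant phyla turn over more
slowly than rare ones:

```r
glance(per_group_ttr(full, pair$taxonomy, rank = "phylum", k = 5))
#> # A tibble: 1 × 6
#>   dominant_mean_w rare_mean_w     k n_groups_scored rank   scheme
#> 1           0.240       0.719     5              15 phylum sliding

moving_window(full)
#> Moving-window community change: Δt = 20.9% ± 13.5% per month (11 pairs)
```

Joint ordination of both reactors recovers the two covariates that
actually structure the simulation — the scale contrast between the
reactors and the seasonal temperature forcing:

```r
stacked <- stack_reactors(pair)
cov <- transform_covariates(stacked$covariates)

forward_select(stacked$community, cov, n_permutations = 499, seed = 12)
#> Forward selection (499 permutations, threshold 0.050)
#>   selected:
#>     1. scale  (added inertia 0.6203, p = 0.0020)
#>     2. temperature  (added inertia 0.1522, p = 0.0020)
#>   rejected: BOD, TN, TP, pH, DO, SRT, HRT, MLSS

variance_partition(stacked$community, cov, stacked$groups)
#> Variance partitioning of community inertia
#>   full model explains 60.8% of total inertia
#>   W              12.0%
#>   O              16.8%
#>   S              22.0%
#>   W:O             2.2%
#>   W:S             3.6%
#>   O:S             7.8%
#>   W:O:S          -3.6%
#>   unexplained    39.2%
```

The pure fractions are each group's unique explained inertia; shared
fractions (including the slightly negative three-way term, a normal
outcome of inclusion–exclusion partitions) account for covariation
among groups, and the eight components always sum to 1.

`run_pipeline(pipeline_config(...))` drives the same chain from TSV
inputs with per-stage logging and a deterministic JSON report. The
methods vignette (`vignettes/community-turnover.Rmd`) documents the
models, conventions, generator calibration, and known limitations.

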