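#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: input file paths, the
#' rarefaction depth and seed, taxa-time settings, permutation settings,
#' and the output directory. Accepts either explicit arguments or a YAML
#' file with the same field names via `read_pipeline_config()`.
#'
#' @param table_path Path to the tab-separated community table.
#' @param taxonomy_path Path to the taxonomy map.
#' @param covariates_path Path to the covariate table (wide layout).
#' @param groups Named character vector mapping covariates to
#'   `W`/`O`/`S` for variance partitioning.
#' @param depth Rarefaction depth (reads per sample).
#' @param seed Master seed; each randomized stage derives its own seed
#'   from it.
#' @param scheme Taxa-time windowing scheme.
#' @param k Group count for the dominant/rare contrast.
#' @param rank Rank for the per-group taxa-time analysis.
#' @param n_permutations Permutations for forward selection.
#' @param threshold Significance threshold for forward selection.
#' @param out_dir Output directory for the report and sub-tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path, taxonomy_path, covariates_path,
                            groups, depth, seed = 1,
                            scheme = c("sliding", "nested"), k = 5,
                            rank = "phylum",
                            n_permutations = 499, threshold = 0.05,
                            out_dir = ".") {
  for (p in c(table_path, taxonomy_path, covariates_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  if (depth < 1) abort("depth must be >= 1")
  structure(
    list(table_path = table_path, taxonomy_path = taxonomy_path,
         covariates_path = covariates_path, groups = groups,
         depth = as.integer(depth), seed = as.integer(seed),
         scheme = match.arg(scheme), k = as.integer(k), rank = rank,
         n_permutations = as.integer(n_permutations), threshold = threshold,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose fields mirror the
#'   `pipeline_config()` arguments (`groups` as a variable-to-label map).
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is needed to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  y$groups <- unlist(y$groups)
  do.call(pipeline_config, y)
}

#' Run the full community-dynamics pipeline
#'
#' Orchestrates every analysis stage on one community table: rarefaction,
#' per-rank richness summaries, the global and per-phylum taxa-time fits
#' with the dominant/rare contrast, moving-window change statistics,
#' similarity matrices, constrained ordination with forward selection,
#' and (when every `W`/`O`/`S` group retains a non-constant variable)
#' variance partitioning. Writes a versioned JSON report plus
#' tab-separated sub-tables into `out_dir`, logs each stage with its
#' parameters and derived seed, and reruns byte-identically under the same
#' configuration.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param log Connection or `""` for stderr logging; `NULL` silences.
#' @return The report as a named list, invisibly; the primary artifact is
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config, log = "") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  logger <- make_logger(log, log_con)
  # one master seed, split deterministically per randomized stage
  seeds <- list(rarefy = config$seed,
                forward = config$seed + 1000L)

  stage <- function(name, expr) {
    logger(paste0("stage ", name, " started"))
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    logger(paste0("stage ", name, " done"))
    res
  }

  inputs <- stage("load", {
    list(table = read_community_table(config$table_path),
         taxonomy = read_taxonomy(config$taxonomy_path),
         covariates = as_covariate_table(
           readr::read_tsv(config$covariates_path,
                           col_types = readr::cols(
                             sample = readr::col_character(),
                             .default = readr::col_double()))))
  })

  tbl <- stage("rarefy", {
    logger(paste0("  depth ", config$depth, ", seed ", seeds$rarefy))
    rarefy(inputs$table, depth = config$depth, seed = seeds$rarefy)
  })

  richness <- stage("richness", richness_by_rank(tbl, inputs$taxonomy))

  ttr_global <- stage("ttr_global", {
    fit_power_law(accumulation_curve(tbl, scheme = config$scheme))
  })
  ttr_groups <- stage("ttr_groups", {
    per_group_ttr(tbl, inputs$taxonomy, rank = config$rank, k = config$k,
                  scheme = config$scheme)
  })

  mw <- stage("moving_window", moving_window(tbl))
  stage("similarity", {
    write_similarity_matrix(sorenson_matrix(tbl),
                            file.path(config$out_dir, "sorenson.tsv"))
    write_similarity_matrix(pearson_matrix(tbl),
                            file.path(config$out_dir, "pearson.tsv"))
  })

  cov <- transform_covariates(inputs$covariates)
  keep_vars <- vapply(setdiff(names(cov), "sample"),
                      function(v) diff(range(cov[[v]])) > 0, logical(1))
  dropped <- names(keep_vars)[!keep_vars]
  if (length(dropped)) {
    logger(paste0("  dropping constant covariate(s): ",
                  paste(dropped, collapse = ", ")))
  }
  cov_use <- cov[, c("sample", names(keep_vars)[keep_vars]), drop = FALSE]

  selection <- stage("forward_select", {
    logger(paste0("  ", config$n_permutations, " permutations, seed ",
                  seeds$forward))
    forward_select(tbl, cov_use, n_permutations = config$n_permutations,
                   threshold = config$threshold, seed = seeds$forward)
  })
  cca_res <- stage("cca", {
    if (nrow(selection$selected)) {
      cca_fit(tbl, cov_use[, c("sample", selection$selected$variable)])
    } else {
      cca_fit(tbl, cov_use)
    }
  })

  groups_use <- config$groups[intersect(names(config$groups),
                                        setdiff(names(cov_use), "sample"))]
  vpa_res <- NULL
  if (all(c("W", "O", "S") %in% groups_use)) {
    vpa_res <- stage("vpa", {
      variance_partition(tbl, cov_use[, c("sample", names(groups_use))],
                         groups_use)
    })
  } else {
    logger("stage vpa skipped: a W/O/S group has no varying covariate")
  }

  report <- list(
    schema_version = "1.0",
    config = config[setdiff(names(config), "out_dir")],
    richness = as.data.frame(richness[, c("rank", "mean", "sd", "min", "max")]),
    ttr = list(global = as.data.frame(glance(ttr_global)),
               groups = as.data.frame(tidy(ttr_groups)),
               contrast = as.data.frame(glance(ttr_groups))),
    moving_window = list(pairs = as.data.frame(tidy(mw)),
                         summary = as.data.frame(glance(mw))),
    similarity_files = c("sorenson.tsv", "pearson.tsv"),
    ordination = list(selection = as.data.frame(tidy(selection)),
                      cca = as.data.frame(glance(cca_res))),
    vpa = if (!is.null(vpa_res)) as.data.frame(tidy(vpa_res)) else "skipped"
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  readr::write_tsv(richness[, c("rank", "mean", "sd", "min", "max")],
                   file.path(config$out_dir, "richness.tsv"))
  readr::write_tsv(tidy(ttr_groups),
                   file.path(config$out_dir, "ttr_groups.tsv"))
  logger(paste0("report written to ", report_path))
  invisible(report)
}

make_logger <- function(log, con) {
  force(log)
  function(msg) {
    line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", msg)
    writeLines(line, con)
    flush(con)
    if (!is.null(log)) message(line)
  }
}
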