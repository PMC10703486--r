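#' Default run configuration
#'
#' Nested list of every pipeline parameter with the package defaults:
#' the synthetic study conditions (`sim`, see [sim_config()]), GSEA
#' parameters (`gsea`: weight 1, 1000 gene permutations, ranking
#' metric `"stat"`), clustering (`cluster`: k = 10 for the 200-drug
#' synthetic library, k-means++ with 10 restarts, max-min selection
#' rule), target extraction (`targets`: top 35 recurring genes from
#' the first context's leading edges) and validation (`validate`: 5
#' donors, the 2 strongest candidates from the selected cluster plus
#' the most reversal-neutral drug as negative control).
#'
#' @return A nested configuration list.
#' @export
default_run_config <- function() {
  list(
    sim = list(n_genes = 2000, n_module_genes = 137, module_effect = 3,
               n_contexts = 2, n_drugs = 200, frac_reversers = 0.1,
               frac_mimickers = 0.1, set_size = 50, coherence = 0.8,
               noise_sd = 1, seed = 1L),
    gsea = list(weight = 1, n_perm = 1000, metric = "stat", seed = 1L),
    cluster = list(k = 10, n_init = 10, seed = 1L, method = "kmeans",
                   rule = "min"),
    targets = list(top_n = 35, context = NULL),
    validate = list(donor_count = 5, n_candidates = 2,
                    include_neutral_control = TRUE, expr_noise_sd = 0.5,
                    enrichment_weight = 0.25)
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it (recursively) over
#' [default_run_config()]; keys absent from the file keep their
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional nested list merged last (e.g. from CLI
#'   flags).
#' @return A configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("Config file not found: ", path),
            class = "sigrev_io_error")
    }
    config <- utils::modifyList(config, yaml::read_yaml(path))
  }
  utils::modifyList(config, overrides)
}

#' Derive all stage seeds from one master seed
#'
#' Overwrites the `sim`, `gsea` and `cluster` seeds with streams
#' derived deterministically from `seed`, so one integer reproduces a
#' whole run.
#'
#' @param config A configuration list.
#' @param seed Master integer seed.
#' @return The updated configuration.
#' @export
apply_master_seed <- function(config, seed) {
  config$sim$seed <- derive_seed(seed, "sim")
  config$gsea$seed <- derive_seed(seed, "gsea")
  config$cluster$seed <- derive_seed(seed, "cluster")
  config
}

require_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("Expected file %s is missing; run `%s` first.",
                  path, produced_by),
          class = "sigrev_missing_upstream_error")
  }
  invisible(path)
}

write_manifest <- function(out_dir, stage, config, outputs) {
  counts <- lapply(outputs, function(p) {
    if (grepl("\\.(tsv|gmt)$", p) && file.exists(p)) {
      length(readLines(p, warn = FALSE))
    } else NA
  })
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("sigrev")),
    config = config,
    config_hash = hash31(paste(deparse(config), collapse = "")),
    outputs = setNames(counts, basename(unlist(outputs))))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

sim_config_from <- function(config) {
  do.call(sim_config, config$sim)
}

de_path <- function(out_dir, ctx) file.path(out_dir, paste0("de_", ctx, ".tsv"))
lib_prefix <- function(out_dir) file.path(out_dir, "drug_library")

#' Pipeline stage commands
#'
#' Each `cmd_*()` function is one stage of the reversal pipeline,
#' reading its inputs from `out_dir` (as written by the upstream
#' stage), writing its tab-delimited outputs plus a JSON run manifest
#' there, and returning the written paths invisibly. `cmd_all()` runs
#' simulate, score, cluster, targets and validate in order.
#'
#' Outputs per stage: `simulate` writes `de_<context>.tsv` DE tables,
#' the `drug_library.*` GMT pair + manifest and the test-only
#' `truth.json`; `score` writes `drug_scores.tsv` (per drug and
#' context: ES/NES/p for both sets, `delta_nes`, comma-joined down
#' leading edge); `cluster` writes `delta_nes_matrix.tsv` (drugs x
#' contexts + cluster assignment) and `cluster_summary.tsv`; `targets`
#' writes `recurring_targets.tsv`; `validate` writes
#' `validation_expr.tsv`, `validation_samples.tsv` and
#' `validation_report.tsv`.
#'
#' @param out_dir Output directory (created if missing).
#' @param config Configuration list from [default_run_config()] /
#'   [load_run_config()].
#' @return Character vector of written paths, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(out_dir, config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- sim_config_from(config)
  disease <- generate_disease_contexts(scfg)
  lib <- generate_drug_library(scfg, disease$truth)
  paths <- character()
  for (ctx in names(disease$tables)) {
    p <- de_path(out_dir, ctx)
    write_de_table(disease$tables[[ctx]], p)
    paths <- c(paths, p)
  }
  write_drug_library(lib$library, lib_prefix(out_dir))
  paths <- c(paths, paste0(lib_prefix(out_dir),
                           c(".up.gmt", ".down.gmt", ".manifest.tsv")))
  truth_path <- file.path(out_dir, "truth.json")
  write_truth(lib$truth, truth_path)
  paths <- c(paths, truth_path)
  write_manifest(out_dir, "simulate", config, as.list(paths))
  invisible(paths)
}

read_context_tables <- function(out_dir, config) {
  labels <- context_labels(config$sim$n_contexts)
  tables <- lapply(labels, function(ctx) {
    p <- de_path(out_dir, ctx)
    require_file(p, "simulate")
    read_de_table(p, context = ctx)
  })
  names(tables) <- labels
  tables
}

#' @rdname pipeline
#' @export
cmd_score <- function(out_dir, config = default_run_config()) {
  tables <- read_context_tables(out_dir, config)
  require_file(paste0(lib_prefix(out_dir), ".manifest.tsv"), "simulate")
  library <- read_drug_library(lib_prefix(out_dir))
  rankings <- lapply(tables, build_ranking, metric = config$gsea$metric)
  scores <- score_library(rankings, library,
                          weight = config$gsea$weight,
                          n_perm = config$gsea$n_perm,
                          seed = config$gsea$seed)
  flat <- scores |>
    mutate(leading_edge_down = vapply(.data$leading_edge_down,
                                      paste, character(1),
                                      collapse = ","))
  p <- file.path(out_dir, "drug_scores.tsv")
  readr::write_tsv(flat, p)
  write_manifest(out_dir, "score", config, list(p))
  invisible(p)
}

read_scores <- function(out_dir) {
  p <- file.path(out_dir, "drug_scores.tsv")
  require_file(p, "score")
  readr::read_tsv(p, col_types = readr::cols(
    signature_id = readr::col_character(),
    context = readr::col_character(),
    leading_edge_down = readr::col_character(),
    .default = readr::col_double())) |>
    mutate(leading_edge_down = strsplit(
      dplyr::coalesce(.data$leading_edge_down, ""), ",", fixed = TRUE))
}

#' @rdname pipeline
#' @export
cmd_cluster <- function(out_dir, config = default_run_config()) {
  scores <- read_scores(out_dir)
  m <- assemble_matrix(scores)
  m <- cluster_matrix(m, k = config$cluster$k, seed = config$cluster$seed,
                      n_init = config$cluster$n_init,
                      method = config$cluster$method)
  wide <- as_tibble(m$mat, rownames = "signature_id") |>
    mutate(cluster = unname(m$cluster[.data$signature_id]))
  p1 <- file.path(out_dir, "delta_nes_matrix.tsv")
  p2 <- file.path(out_dir, "cluster_summary.tsv")
  readr::write_tsv(wide, p1)
  readr::write_tsv(m$cluster_summary, p2)
  write_manifest(out_dir, "cluster", config, list(p1, p2))
  invisible(c(p1, p2))
}

read_clustered_matrix <- function(out_dir, config) {
  scores <- read_scores(out_dir)
  p <- file.path(out_dir, "delta_nes_matrix.tsv")
  require_file(p, "cluster")
  wide <- readr::read_tsv(p, col_types = readr::cols(
    signature_id = readr::col_character(),
    cluster = readr::col_integer(),
    .default = readr::col_double()))
  m <- assemble_matrix(scores)
  assignment <- setNames(wide$cluster, wide$signature_id)
  m$cluster <- assignment[rownames(m$mat)]
  m$k <- length(unique(assignment))
  m$cluster_summary <- cluster_summarize(m$mat, m$cluster)
  m
}

#' @rdname pipeline
#' @export
cmd_targets <- function(out_dir, config = default_run_config()) {
  m <- read_clustered_matrix(out_dir, config)
  selected <- select_top_cluster(m, rule = config$cluster$rule)
  targets <- recurring_targets(m, selected,
                               context = config$targets$context,
                               top_n = config$targets$top_n)
  p <- file.path(out_dir, "recurring_targets.tsv")
  readr::write_tsv(targets, p)
  write_manifest(out_dir, "targets",
                 c(config, list(selected_cluster = selected)), list(p))
  invisible(p)
}

#' @rdname pipeline
#' @export
cmd_validate <- function(out_dir, config = default_run_config()) {
  m <- read_clustered_matrix(out_dir, config)
  tp <- file.path(out_dir, "recurring_targets.tsv")
  require_file(tp, "targets")
  targets <- readr::read_tsv(tp, col_types = "ci")
  require_file(file.path(out_dir, "truth.json"), "simulate")
  truth <- read_truth(file.path(out_dir, "truth.json"))

  selected <- select_top_cluster(m, rule = config$cluster$rule)
  members <- names(m$cluster)[m$cluster == selected]
  row_means <- rowMeans(m$mat)
  candidates <- members[order(-row_means[members])]
  candidates <- head(candidates, config$validate$n_candidates)
  treatments <- candidates
  if (isTRUE(config$validate$include_neutral_control)) {
    non_members <- setdiff(rownames(m$mat), members)
    neutral_like <- non_members[which.min(abs(row_means[non_members]))]
    treatments <- c(treatments, neutral_like)
  }

  scfg <- sim_config_from(config)
  vx <- generate_validation_experiment(
    scfg, truth, treatments,
    donor_count = config$validate$donor_count,
    expr_noise_sd = config$validate$expr_noise_sd)
  signatures <- list(recurring_targets = targets$gene)
  enr <- sample_enrichment(vx$expr, signatures, meta = vx$meta,
                           weight = config$validate$enrichment_weight)
  report <- reversal_report(enr, treatments = treatments)

  p1 <- file.path(out_dir, "validation_expr.tsv")
  p2 <- file.path(out_dir, "validation_samples.tsv")
  p3 <- file.path(out_dir, "validation_report.tsv")
  readr::write_tsv(vx$expr, p1)
  readr::write_tsv(vx$meta, p2)
  readr::write_tsv(report, p3)
  write_manifest(out_dir, "validate",
                 c(config, list(treatments = treatments)),
                 list(p1, p2, p3))
  invisible(c(p1, p2, p3))
}

#' @rdname pipeline
#' @export
cmd_all <- function(out_dir, config = default_run_config()) {
  cmd_simulate(out_dir, config)
  cmd_score(out_dir, config)
  cmd_cluster(out_dir, config)
  cmd_targets(out_dir, config)
  cmd_validate(out_dir, config)
  invisible(list.files(out_dir, full.names = TRUE))
}
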