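#' Simulation configuration for the synthetic study
#'
#' Bundles and validates every knob of the synthetic-data generators:
#' the gene universe, the planted disease up-module (an interferon-like
#' block of genes shifted upward in every disease context), the drug
#' library composition, and the noise model. The defaults describe the
#' reference study conditions used throughout the package's tests: a
#' 2000-gene universe with a 137-gene module shifted by 3 score units
#' against unit noise, two biological contexts (CD14 monocytes and
#' PBMCs), and a 200-drug library with 10% planted reversers and 10%
#' mimickers carrying 50-gene up/down sets at coherence 0.8.
#'
#' @param n_genes Size of the gene universe.
#' @param n_module_genes Number of genes in the planted disease up-module.
#' @param module_effect Mean upward shift of module genes' DE score, in
#'   score (standard-deviation) units.
#' @param n_contexts Number of biological contexts; the first two are
#'   labelled `"CD14"` and `"PBMC"`.
#' @param n_drugs Number of drug signatures in the library.
#' @param frac_reversers,frac_mimickers Fractions of the library planted
#'   as reversers (down-set drawn from the module) and mimickers
#'   (up-set drawn from the module); their sum must be at most 1.
#' @param set_size Genes per drug up/down set (at most 300, mirroring
#'   the top-300 truncation applied to real perturbation signatures).
#' @param coherence Fraction of a planted drug's module-facing set that
#'   is drawn from the planted module (0 = indistinguishable from a
#'   neutral drug, 1 = the whole set is module genes).
#' @param noise_sd Standard deviation of the per-gene DE score noise.
#' @param seed Integer seed; all generators derive their RNG streams
#'   from it deterministically.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, n_module_genes = 40, n_drugs = 30)
#' cfg$n_genes
sim_config <- function(n_genes = 2000, n_module_genes = 137,
                       module_effect = 3, n_contexts = 2, n_drugs = 200,
                       frac_reversers = 0.1, frac_mimickers = 0.1,
                       set_size = 50, coherence = 0.8, noise_sd = 1,
                       seed = 1L) {
  stopifnot_scalar_num(n_genes, "n_genes", 1, Inf, TRUE)
  stopifnot_scalar_num(n_module_genes, "n_module_genes", 1, Inf, TRUE)
  stopifnot_scalar_num(module_effect, "module_effect", 0)
  stopifnot_scalar_num(n_contexts, "n_contexts", 1, Inf, TRUE)
  stopifnot_scalar_num(n_drugs, "n_drugs", 1, Inf, TRUE)
  stopifnot_scalar_num(frac_reversers, "frac_reversers", 0, 1)
  stopifnot_scalar_num(frac_mimickers, "frac_mimickers", 0, 1)
  stopifnot_scalar_num(set_size, "set_size", 1, 300, TRUE)
  stopifnot_scalar_num(coherence, "coherence", 0, 1)
  stopifnot_scalar_num(noise_sd, "noise_sd", 1e-12)
  stopifnot_scalar_num(seed, "seed", integerish = TRUE)
  if (frac_reversers + frac_mimickers > 1) {
    abort("`frac_reversers` + `frac_mimickers` must be at most 1.",
          class = "sigrev_config_error")
  }
  if (n_module_genes > n_genes) {
    abort("`n_module_genes` cannot exceed `n_genes`.",
          class = "sigrev_config_error")
  }
  if (2 * set_size > n_genes) {
    abort("`2 * set_size` cannot exceed `n_genes`.",
          class = "sigrev_config_error")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_module_genes = as.integer(n_module_genes),
         module_effect = module_effect,
         n_contexts = as.integer(n_contexts),
         n_drugs = as.integer(n_drugs),
         frac_reversers = frac_reversers,
         frac_mimickers = frac_mimickers,
         set_size = as.integer(set_size),
         coherence = coherence,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_universe <- function(config) {
  sprintf("G%05d", seq_len(config$n_genes))
}

context_labels <- function(n) {
  base <- c("CD14", "PBMC")
  if (n <= 2L) base[seq_len(n)] else c(base, sprintf("context%d", 3:n))
}

#' Generate disease differential-expression tables with a planted module
#'
#' Draws one DE table per biological context under a normal
#' location-shift model: genes in the planted module receive a score
#' distributed `Normal(module_effect, noise_sd)`, all other genes
#' `Normal(0, noise_sd)`. The score is reported as `log2fc`; `stat` is
#' the score in noise-sd units and `padj` is the Benjamini-Hochberg
#' adjustment of the two-sided normal tail of `stat`, so adjusted
#' p-values decrease monotonically in `|stat|` and "top-N DEG"
#' selection is well defined.
#'
#' @param config A [sim_config()].
#' @return A list with `tables` (named list of tibbles
#'   `gene, log2fc, stat, padj`, one per context) and `truth`
#'   (a `sigrev_truth` list with `module_genes`; `drug_class` is filled
#'   in by [generate_drug_library()]).
#' @export
#' @examples
#' sim <- generate_disease_contexts(sim_config(n_genes = 300,
#'   n_module_genes = 25, n_drugs = 10, set_size = 20))
#' names(sim$tables)
generate_disease_contexts <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().",
          class = "sigrev_config_error")
  }
  universe <- sim_universe(config)
  module_genes <- withr::with_seed(
    derive_seed(config$seed, "module"),
    sort(sample(universe, config$n_module_genes))
  )
  labels <- context_labels(config$n_contexts)
  is_module <- universe %in% module_genes
  tables <- withr::with_seed(derive_seed(config$seed, "contexts"), {
    lapply(labels, function(lab) {
      score <- rnorm(config$n_genes,
                     mean = ifelse(is_module, config$module_effect, 0),
                     sd = config$noise_sd)
      stat <- score / config$noise_sd
      tibble(gene = universe,
             log2fc = score,
             stat = stat,
             padj = p.adjust(2 * pnorm(-abs(stat)), method = "BH"))
    })
  })
  names(tables) <- labels
  truth <- structure(list(module_genes = module_genes, drug_class = NULL),
                     class = "sigrev_truth")
  list(tables = tables, truth = truth)
}

#' Generate a drug-signature library with planted reversers and mimickers
#'
#' Builds `n_drugs` perturbation signatures, each an up-set and a
#' disjoint down-set of `set_size` genes, identified as
#' `"name_database_id"`. Class counts round down: reversers first
#' (`floor(frac_reversers * n_drugs)`), then mimickers, the remainder
#' neutral. A reverser's down-set contains `ceiling(coherence *
#' set_size)` planted module genes (the drug "pushes down" what the
#' disease pushes up) with the remainder drawn uniformly from the rest
#' of the universe; mimickers are symmetric with module genes in the
#' up-set; neutral drugs draw both sets uniformly.
#'
#' @param config A [sim_config()].
#' @param truth Truth object from [generate_disease_contexts()]
#'   (supplies the planted module genes).
#' @return A list with `library` (tibble `signature_id, drug_name,
#'   database, database_id, up, down`, the last two list-columns of
#'   gene-id character vectors) and `truth` with `drug_class` filled in
#'   (named character vector, one of `"reverser"`, `"mimicker"`,
#'   `"neutral"` per signature).
#' @export
generate_drug_library <- function(config, truth) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().",
          class = "sigrev_config_error")
  }
  if (!length(truth$module_genes)) {
    abort("`truth$module_genes` is empty; run generate_disease_contexts() first.",
          class = "sigrev_config_error")
  }
  n_forced <- ceiling(config$coherence * config$set_size)
  if (n_forced > config$n_module_genes) {
    abort(sprintf(
      "coherence * set_size (%d) exceeds the number of module genes (%d).",
      n_forced, config$n_module_genes), class = "sigrev_config_error")
  }
  universe <- sim_universe(config)
  module <- truth$module_genes

  n_rev <- floor(config$frac_reversers * config$n_drugs)
  n_mim <- floor(config$frac_mimickers * config$n_drugs)
  classes <- c(rep("reverser", n_rev), rep("mimicker", n_mim),
               rep("neutral", config$n_drugs - n_rev - n_mim))

  draw_planted_set <- function() {
    forced <- sample(module, n_forced)
    free <- sample(setdiff(universe, forced), config$set_size - n_forced)
    c(forced, free)
  }

  lib <- withr::with_seed(derive_seed(config$seed, "library"), {
    purrr::map(seq_len(config$n_drugs), function(i) {
      cls <- classes[[i]]
      if (cls == "reverser") {
        down <- draw_planted_set()
        up <- sample(setdiff(universe, down), config$set_size)
      } else if (cls == "mimicker") {
        up <- draw_planted_set()
        down <- sample(setdiff(universe, up), config$set_size)
      } else {
        both <- sample(universe, 2L * config$set_size)
        up <- both[seq_len(config$set_size)]
        down <- both[config$set_size + seq_len(config$set_size)]
      }
      tibble(drug_name = sprintf("drug%04d", i),
             database = "SYNLIB",
             database_id = sprintf("SL%05d", i),
             up = list(sort(up)), down = list(sort(down)))
    }) |> bind_rows()
  })
  lib <- lib |>
    mutate(signature_id = paste(.data$drug_name, .data$database,
                                .data$database_id, sep = "_")) |>
    select(all_of(c("signature_id", "drug_name", "database",
                    "database_id", "up", "down")))
  truth$drug_class <- setNames(classes, lib$signature_id)
  list(library = lib, truth = truth)
}

#' Generate a treated-vs-control validation expression matrix
#'
#' Emulates an in-vitro verification experiment: for each donor, one
#' sample per treatment plus a vehicle (`"DMSO"`) control. Baseline
#' log2 expression is `baseline_log2` everywhere and elevated by
#' `module_elevation` on the planted module genes (the disease state).
#' A planted reverser shifts module genes down by `coherence *
#' module_elevation` on the log2 scale; a mimicker shifts them up by
#' the same amount; neutral drugs and DMSO leave the mean untouched.
#' Multiplicative log-normal noise of sd `expr_noise_sd` (log2 scale)
#' is added per gene per sample.
#'
#' @param config A [sim_config()].
#' @param truth Truth object with `module_genes` and `drug_class`
#'   (i.e. after [generate_drug_library()]).
#' @param treatments Character vector of signature ids to treat with
#'   (may be empty for a control-only experiment).
#' @param donor_count Number of donors (>= 2).
#' @param module_elevation Log2 elevation of module genes at baseline;
#'   defaults to `config$module_effect`.
#' @param baseline_log2 Baseline log2 expression of every gene.
#' @param expr_noise_sd Log2-scale noise sd; set 0 for the noise-free
#'   mean parameterization.
#' @return A list with `expr` (tibble: `gene` column plus one column
#'   per sample of non-negative expression values) and `meta` (tibble
#'   `sample, donor, treatment`).
#' @export
generate_validation_experiment <- function(config, truth, treatments,
                                           donor_count = 5,
                                           module_elevation = config$module_effect,
                                           baseline_log2 = 5,
                                           expr_noise_sd = 0.5) {
  stopifnot_scalar_num(donor_count, "donor_count", 2, Inf, TRUE)
  if (length(treatments)) {
    unknown <- setdiff(treatments, names(truth$drug_class))
    if (length(unknown)) {
      abort(paste0("Unknown treatment id(s): ",
                   paste(unknown, collapse = ", ")),
            class = "sigrev_lookup_error")
    }
  }
  universe <- sim_universe(config)
  is_module <- universe %in% truth$module_genes
  arms <- c(treatments, "DMSO")
  donors <- sprintf("D%02d", seq_len(donor_count))

  meta <- tidyr::expand_grid(donor = donors, treatment = arms) |>
    mutate(sample = paste(.data$donor, .data$treatment, sep = "_")) |>
    select(all_of(c("sample", "donor", "treatment")))

  shift_for <- function(trt) {
    if (trt == "DMSO") return(0)
    cls <- truth$drug_class[[trt]]
    switch(cls,
           reverser = -config$coherence * module_elevation,
           mimicker = config$coherence * module_elevation,
           neutral = 0)
  }
  expr <- withr::with_seed(derive_seed(config$seed, "validation"), {
    cols <- lapply(seq_len(nrow(meta)), function(i) {
      mu <- baseline_log2 + ifelse(is_module, module_elevation, 0) +
        ifelse(is_module, shift_for(meta$treatment[[i]]), 0)
      2^(mu + rnorm(length(universe), sd = expr_noise_sd))
    })
    names(cols) <- meta$sample
    tibble(gene = universe) |> bind_cols_list(cols)
  })
  list(expr = expr, meta = meta)
}

bind_cols_list <- function(tbl, cols) {
  for (nm in names(cols)) tbl[[nm]] <- cols[[nm]]
  tbl
}
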