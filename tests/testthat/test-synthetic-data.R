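test_that("config invariants are enforced", {
  expect_error(sim_config(frac_reversers = 0.7, frac_mimickers = 0.5),
               class = "sigrev_config_error")
  expect_error(sim_config(n_genes = 100, n_module_genes = 200),
               class = "sigrev_config_error")
  expect_error(sim_config(n_genes = 100, set_size = 60),
               class = "sigrev_config_error")
  expect_error(sim_config(set_size = 400), class = "sigrev_config_error")
  expect_error(sim_config(coherence = 1.2), class = "sigrev_config_error")
})

test_that("disease tables have the right dimensions and are deterministic", {
  cfg <- sim_config(n_genes = 1000, n_module_genes = 137,
                    module_effect = 3, noise_sd = 1, n_drugs = 50,
                    seed = 1L)
  a <- generate_disease_contexts(cfg)
  b <- generate_disease_contexts(cfg)
  expect_named(a$tables, c("CD14", "PBMC"))
  expect_true(all(vapply(a$tables, nrow, integer(1)) == 1000L))
  expect_length(a$truth$module_genes, 137L)
  expect_identical(a, b)
  # adjusted p-values are monotone decreasing in |stat|
  de <- a$tables$CD14
  ord <- order(-abs(de$stat))
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
})

test_that("zero module effect leaves module and background scores indistinguishable", {
  cfg <- sim_config(n_genes = 4000, n_module_genes = 400,
                    module_effect = 0, noise_sd = 1, n_drugs = 10,
                    set_size = 30, seed = 7L)
  sim <- generate_disease_contexts(cfg)
  de <- sim$tables$CD14
  mod <- de$log2fc[de$gene %in% sim$truth$module_genes]
  bg <- de$log2fc[!de$gene %in% sim$truth$module_genes]
  expect_lt(abs(mean(mod) - mean(bg)), 3 / sqrt(length(mod)))
})

test_that("library class counts follow the floor-and-remainder rounding rule", {
  cfg <- sim_config(n_drugs = 200, frac_reversers = 0.1,
                    frac_mimickers = 0.07)
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  cls <- table(lib$truth$drug_class)
  expect_identical(as.integer(cls[["reverser"]]), 20L)
  expect_identical(as.integer(cls[["mimicker"]]), 14L)
  expect_identical(as.integer(cls[["neutral"]]), 166L)
  expect_identical(length(lib$truth$drug_class), nrow(lib$library))
})

test_that("drug sets are disjoint, sized, and identifiers follow name_database_id", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)$library
  expect_true(all(vapply(seq_len(nrow(lib)), function(i) {
    length(intersect(lib$up[[i]], lib$down[[i]])) == 0
  }, logical(1))))
  expect_true(all(lengths(lib$up) == cfg$set_size))
  expect_true(all(lengths(lib$down) == cfg$set_size))
  expect_true(all(grepl("^[^_]+_[^_]+_[^_]+$", lib$signature_id)))
  expect_identical(lib$signature_id,
                   paste(lib$drug_name, lib$database, lib$database_id,
                         sep = "_"))
})

test_that("coherence = 1 forces reverser down-sets inside the module", {
  cfg <- sim_config(n_genes = 1000, n_module_genes = 137, n_drugs = 40,
                    frac_reversers = 0.25, set_size = 35, coherence = 1,
                    seed = 3L)
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  rev_ids <- names(lib$truth$drug_class)[lib$truth$drug_class == "reverser"]
  for (id in rev_ids) {
    down <- lib$library$down[[match(id, lib$library$signature_id)]]
    expect_true(all(down %in% sim$truth$module_genes))
  }
})

test_that("coherence = 0 reversers match the hypergeometric overlap of neutrals", {
  # expected module overlap of a uniform draw: set_size * m / N
  cfg <- sim_config(n_genes = 500, n_module_genes = 100, n_drugs = 400,
                    frac_reversers = 1, frac_mimickers = 0,
                    set_size = 40, coherence = 0, seed = 9L)
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)$library
  overlap <- vapply(lib$down, function(d) {
    sum(d %in% sim$truth$module_genes)
  }, numeric(1))
  expected <- 40 * 100 / 500  # hypergeometric mean, computed directly
  se <- sqrt(40 * (100 / 500) * (400 / 500) * (460 / 499)) / sqrt(400)
  expect_lt(abs(mean(overlap) - expected), 4 * se)
})

test_that("excessive coherence for the module size is a configuration error", {
  cfg <- sim_config(n_genes = 1000, n_module_genes = 20, set_size = 50,
                    coherence = 0.9)
  sim <- generate_disease_contexts(cfg)
  expect_error(generate_drug_library(cfg, sim$truth),
               class = "sigrev_config_error")
})

test_that("validation experiment builds per-donor arms with a DMSO control", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  rev_id <- names(lib$truth$drug_class)[lib$truth$drug_class == "reverser"][1]

  # control-only design
  ctrl <- generate_validation_experiment(cfg, lib$truth, character(),
                                         donor_count = 5)
  expect_identical(nrow(ctrl$meta), 5L)
  expect_true(all(ctrl$meta$treatment == "DMSO"))
  expect_identical(ncol(ctrl$expr), 6L)  # gene + 5 samples

  # every donor has a DMSO sample; unknown drug is a lookup error
  vx <- generate_validation_experiment(cfg, lib$truth, rev_id,
                                       donor_count = 3)
  dmso_donors <- vx$meta$donor[vx$meta$treatment == "DMSO"]
  expect_setequal(dmso_donors, unique(vx$meta$donor))
  expect_error(
    generate_validation_experiment(cfg, lib$truth, "no_such_drug"),
    class = "sigrev_lookup_error")
  expect_true(all(as.matrix(vx$expr[-1]) >= 0))
})

test_that("noise-free means put reverser-treated module genes strictly below DMSO", {
  cfg <- sim_config(n_genes = 300, n_module_genes = 30, n_drugs = 20,
                    frac_reversers = 0.5, set_size = 20, coherence = 1,
                    seed = 5L)
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  classes <- lib$truth$drug_class
  rev_id <- names(classes)[classes == "reverser"][1]
  neu_id <- names(classes)[classes == "neutral"][1]
  vx <- generate_validation_experiment(cfg, lib$truth, c(rev_id, neu_id),
                                       donor_count = 2, expr_noise_sd = 0)
  expr <- vx$expr
  mod_rows <- expr$gene %in% sim$truth$module_genes
  mean_by_arm <- function(trt) {
    smp <- vx$meta$sample[vx$meta$treatment == trt]
    mean(as.matrix(expr[mod_rows, smp]))
  }
  expect_lt(mean_by_arm(rev_id), mean_by_arm("DMSO"))
  expect_equal(mean_by_arm(neu_id), mean_by_arm("DMSO"))
})

test_that("the on-disk library and DE files never leak the planted labels", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  out <- withr::local_tempdir()
  write_drug_library(lib$library, file.path(out, "lib"))
  write_de_table(sim$tables$CD14, file.path(out, "de.tsv"))
  manifest <- readr::read_tsv(file.path(out, "lib.manifest.tsv"),
                              show_col_types = FALSE)
  expect_named(manifest, c("signature_id", "drug_name", "database",
                           "database_id"))
  de_header <- readLines(file.path(out, "de.tsv"), n = 1)
  expect_identical(de_header, "gene\tlog2fc\tstat\tpadj")
  all_text <- c(readLines(file.path(out, "lib.manifest.tsv")),
                readLines(file.path(out, "lib.up.gmt")),
                readLines(file.path(out, "lib.down.gmt")))
  expect_false(any(grepl("reverser|mimicker|neutral", all_text)))
})
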