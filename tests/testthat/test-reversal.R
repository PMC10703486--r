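make_sig <- function(id, up, down) {
  tibble::tibble(signature_id = id, drug_name = sub("_.*", "", id),
                 database = "DB", database_id = "X",
                 up = list(up), down = list(down))
}

test_that("delta_nes is exactly nes_down minus nes_up and swap-antisymmetric", {
  rk <- make_ranking(120, seed = 1)
  for (seed in 1:8) {
    genes <- withr::with_seed(seed, sample(rk$gene, 16))
    sig <- make_sig("d_DB_1", genes[1:8], genes[9:16])
    sc <- score_drug(rk, sig, n_perm = 150, seed = seed)
    expect_identical(sc$delta_nes, sc$nes_down - sc$nes_up)
    swapped <- make_sig("d_DB_1", genes[9:16], genes[1:8])
    sc2 <- score_drug(rk, swapped, n_perm = 150, seed = seed)
    expect_equal(sc2$delta_nes, -sc$delta_nes, tolerance = 1e-12)
  }
})

test_that("worked arithmetic: nes_down 1.8 and nes_up -1.2 give delta 3.0", {
  # the identity itself, on stored components
  sc <- tibble::tibble(nes_down = 1.8, nes_up = -1.2)
  expect_identical(sc$nes_down - sc$nes_up, 3)
})

test_that("pipeline scoring equals independent per-set GSEA recomposition", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  rk <- build_ranking(sim$tables$CD14)
  rev_id <- names(lib$truth$drug_class)[lib$truth$drug_class == "reverser"][1]
  sig <- lib$library[lib$library$signature_id == rev_id, ]

  scores <- score_library(list(CD14 = rk), lib$library,
                          n_perm = 300, seed = 5)
  got <- scores[scores$signature_id == rev_id, ]

  null <- gsea_null(rk, cfg$set_size, weight = 1, n_perm = 300,
                    seed = sigrev:::derive_seed(5, "CD14"))
  res_up <- gsea_preranked(rk, sig$up[[1]], null = null)
  res_down <- gsea_preranked(rk, sig$down[[1]], null = null)
  expect_equal(got$nes_up, res_up$nes, tolerance = 1e-12)
  expect_equal(got$nes_down, res_down$nes, tolerance = 1e-12)
  expect_equal(got$delta_nes, res_down$nes - res_up$nes,
               tolerance = 1e-12)
  expect_gt(got$delta_nes, 0)  # planted reverser opposes the disease
})

test_that("assemble_matrix builds a complete lexicographic matrix", {
  scores <- tibble::tibble(
    signature_id = rep(c("b_DB_1", "a_DB_1", "c_DB_1"), each = 2),
    context = rep(c("PBMC", "CD14"), 3),
    delta_nes = c(1, 2, 3, 4, 5, 6),
    leading_edge_down = replicate(6, character(), simplify = FALSE))
  m <- assemble_matrix(scores)
  expect_identical(rownames(m$mat), c("a_DB_1", "b_DB_1", "c_DB_1"))
  expect_identical(colnames(m$mat), c("CD14", "PBMC"))
  expect_identical(dim(m$mat), c(3L, 2L))
  expect_identical(m$mat["a_DB_1", "PBMC"], 3)

  shuffled <- assemble_matrix(scores[sample(6), ])
  expect_identical(shuffled$mat, m$mat)

  # incomplete drug dropped with a warning naming it
  expect_warning(m2 <- assemble_matrix(scores[-1, ]),
                 regexp = "b_DB_1", class = "sigrev_incomplete_warning")
  expect_identical(dim(m2$mat), c(2L, 2L))
  expect_error(
    suppressWarnings(assemble_matrix(scores[c(1, 4), ])),
    class = "sigrev_empty_matrix_error")
})

test_that("clustering handles singleton, identical-row and two-blob cases", {
  scores <- tidyr::expand_grid(
    signature_id = sprintf("d%02d_DB_1", 1:6),
    context = c("CD14", "PBMC")) |>
    dplyr::mutate(delta_nes = rep(c(3, 3, 3, 0, 0, 0), each = 2) +
                    rep(c(0.05, -0.05), 6) + 0.01 * seq_len(12),
                  leading_edge_down = replicate(12, character(),
                                                simplify = FALSE))
  m <- assemble_matrix(scores)

  # k = rows: singleton clusters with zero within-cluster variance
  mk <- cluster_matrix(m, k = 6, seed = 1)
  expect_identical(as.integer(table(mk$cluster)), rep(1L, 6))
  expect_equal(mk$tot_withinss, 0, tolerance = 1e-12)

  # two well-separated blobs recover the planted split; cross-check
  # against an independent hierarchical partition
  m2 <- cluster_matrix(m, k = 2, seed = 1)
  planted <- rep(1:2, each = 3)
  expect_identical(unname(table(m2$cluster[planted == 1])),
                   unname(table(m2$cluster[planted == 2])))
  agreement <- m2$cluster[1] == m2$cluster[2] &&
    m2$cluster[2] == m2$cluster[3] && m2$cluster[4] == m2$cluster[5] &&
    m2$cluster[5] == m2$cluster[6] && m2$cluster[1] != m2$cluster[4]
  expect_true(agreement)
  indep <- stats::cutree(stats::hclust(stats::dist(m$mat)), k = 2)
  expect_identical(unname(indep == indep[1]),
                   unname(m2$cluster == m2$cluster[1]))

  # identical rows, k = 1
  same <- m
  same$mat[] <- 1
  m3 <- cluster_matrix(same, k = 1, seed = 1)
  expect_identical(unname(m3$cluster), rep(1L, 6))

  expect_error(cluster_matrix(m, k = 7), class = "sigrev_argument_error")
})

test_that("cluster selection follows the max-min rule with documented tie-breaks", {
  fake <- structure(list(
    mat = matrix(0, 6, 2, dimnames = list(sprintf("d%d", 1:6),
                                          c("CD14", "PBMC"))),
    cluster = setNames(rep(1:3, each = 2), sprintf("d%d", 1:6)),
    cluster_summary = tibble::tibble(
      cluster = 1:3, size = c(2L, 2L, 2L),
      CD14 = c(3, 4, 1), PBMC = c(3, 0, 1),
      min_context_mean = c(3, 0, 1), overall_mean = c(3, 2, 1))),
    class = "delta_nes_matrix")
  expect_identical(select_top_cluster(fake), 1L)
  expect_identical(select_top_cluster(fake, rule = "mean"), 1L)

  # single cluster is selected trivially
  one <- fake
  one$cluster_summary <- fake$cluster_summary[1, ]
  expect_identical(select_top_cluster(one), 1L)

  # tie on min: larger overall mean wins, then larger cluster
  tied <- fake
  tied$cluster_summary$min_context_mean <- c(3, 3, 1)
  tied$cluster_summary$overall_mean <- c(3, 5, 1)
  expect_identical(select_top_cluster(tied), 2L)
})

test_that("recurring targets count leading-edge membership with tie-break", {
  scores <- tibble::tibble(
    signature_id = rep(c("a_DB_1", "b_DB_1", "c_DB_1"), each = 1),
    context = "CD14",
    delta_nes = c(3, 3, 3),
    leading_edge_down = list(c("G1", "G2"), c("G1", "G3"), c("G1", "G2")))
  m <- structure(list(
    mat = matrix(3, 3, 1, dimnames = list(c("a_DB_1", "b_DB_1", "c_DB_1"),
                                          "CD14")),
    scores = scores,
    cluster = setNames(c(1L, 1L, 1L), c("a_DB_1", "b_DB_1", "c_DB_1")),
    cluster_summary = tibble::tibble(cluster = 1L, size = 3L, CD14 = 3,
                                     min_context_mean = 3,
                                     overall_mean = 3)),
    class = "delta_nes_matrix")
  tab <- recurring_targets(m, 1L)
  expect_identical(tab$gene, c("G1", "G2", "G3"))
  expect_identical(tab$frequency, c(3L, 2L, 1L))
  expect_false("G9" %in% tab$gene)
  expect_identical(nrow(recurring_targets(m, 1L, top_n = 2)), 2L)
})

test_that("clustering and selection are invariant to row permutation", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  rankings <- lapply(sim$tables, build_ranking)
  scores <- score_library(rankings, lib$library, n_perm = 200, seed = 2)
  m1 <- cluster_matrix(assemble_matrix(scores), k = 4, seed = 9)
  perm <- withr::with_seed(1, sample(nrow(scores)))
  m2 <- cluster_matrix(assemble_matrix(scores[perm, ]), k = 4, seed = 9)
  expect_identical(m1$mat, m2$mat)
  expect_identical(m1$cluster, m2$cluster)
  expect_identical(select_top_cluster(m1), select_top_cluster(m2))
})

test_that("tidy/glance/autoplot work on the reversal matrix", {
  cfg <- tiny_sim_config()
  sim <- generate_disease_contexts(cfg)
  lib <- generate_drug_library(cfg, sim$truth)
  rankings <- lapply(sim$tables, build_ranking)
  scores <- score_library(rankings, lib$library, n_perm = 150, seed = 3)
  m <- cluster_matrix(assemble_matrix(scores), k = 3, seed = 1)
  long <- tidy(m)
  expect_identical(nrow(long), nrow(m$mat) * 2L)
  expect_true(all(c("signature_id", "context", "delta_nes", "cluster")
                  %in% names(long)))
  g <- glance(m)
  expect_identical(g$k, 3L)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
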