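#' Score one drug signature against one disease ranking
#'
#' Runs pre-ranked GSEA on the drug's up-set and down-set against the
#' same disease ranking and forms the reversal statistic
#' `delta_nes = nes_down - nes_up`. A drug whose transcriptional
#' response opposes the disease signature has its down-set enriched at
#' the top of the disease ranking (large positive `nes_down`) and its
#' up-set at the bottom (negative `nes_up`), so larger `delta_nes`
#' means a more complete predicted reversal. The same permutation seed
#' is applied to both sets, so swapping up and down negates `delta_nes`
#' exactly.
#'
#' @param ranking A tibble `gene, score` (descending), e.g. from
#'   [build_ranking()].
#' @param signature A one-row library tibble (see
#'   [generate_drug_library()] / [read_drug_library()]) or a list with
#'   `signature_id`, `up`, `down`.
#' @param context Context label recorded in the result; defaults to the
#'   ranking's `"context"` attribute.
#' @param weight,n_perm,seed Passed to [gsea_preranked()].
#' @param null_up,null_down Optional precomputed permutation nulls for
#'   the up/down set sizes (see [gsea_null()]).
#' @return A one-row tibble `signature_id, context, es_up, nes_up,
#'   p_up, es_down, nes_down, p_down, delta_nes, leading_edge_down`
#'   (list-column).
#' @export
score_drug <- function(ranking, signature, context = NULL, weight = 1,
                       n_perm = 1000, seed = 1L,
                       null_up = NULL, null_down = NULL) {
  up <- if (is.list(signature$up)) signature$up[[1]] else signature$up
  down <- if (is.list(signature$down)) signature$down[[1]] else signature$down
  context <- context %||% attr(ranking, "context") %||% "context1"
  res_up <- gsea_preranked(ranking, up, weight, n_perm, seed,
                           null = null_up, quiet = TRUE)
  res_down <- gsea_preranked(ranking, down, weight, n_perm, seed,
                             null = null_down, quiet = TRUE)
  tibble(signature_id = signature$signature_id[[1]],
         context = context,
         es_up = res_up$es, nes_up = res_up$nes, p_up = res_up$pvalue,
         es_down = res_down$es, nes_down = res_down$nes,
         p_down = res_down$pvalue,
         delta_nes = res_down$nes - res_up$nes,
         leading_edge_down = list(res_down$leading_edge))
}

#' Score a whole drug library across disease contexts
#'
#' Applies [score_drug()] to every (drug, context) pair. The
#' permutation null depends only on the ranking, the set size and the
#' weight, so one null is computed per (context, set size) and shared
#' across drugs — results are deterministic and independent of drug
#' order. Drugs with an unusable set in a context (no overlap with the
#' ranking, or a degenerate set) are excluded with a warning naming
#' the drug and the reason.
#'
#' @param rankings Named list of ranked tibbles, one per context.
#' @param library Drug-library tibble (`signature_id, up, down`, ...).
#' @param weight,n_perm,seed GSEA parameters; the per-(context, size)
#'   null seed is derived deterministically from `seed`.
#' @return A tibble of per-(drug, context) scores, as in
#'   [score_drug()].
#' @export
score_library <- function(rankings, library, weight = 1, n_perm = 1000,
                          seed = 1L) {
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    abort("`rankings` must be a named list (one ranking per context).",
          class = "sigrev_validation_error")
  }
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(ctx, ranking, size) {
    key <- paste(ctx, size, sep = "\r")
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- gsea_null(ranking, size, weight, n_perm,
                                     derive_seed(seed, ctx))
    }
    null_cache[[key]]
  }
  out <- vector("list", length(rankings) * nrow(library))
  pos <- 0L
  for (ctx in names(rankings)) {
    ranking <- rankings[[ctx]]
    in_universe <- function(genes) genes[genes %in% ranking$gene]
    for (i in seq_len(nrow(library))) {
      sig <- library[i, ]
      pos <- pos + 1L
      up <- in_universe(sig$up[[1]])
      down <- in_universe(sig$down[[1]])
      row <- tryCatch(
        score_drug(ranking, sig, context = ctx, weight = weight,
                   n_perm = n_perm, seed = seed,
                   null_up = if (length(up)) get_null(ctx, ranking, length(up)),
                   null_down = if (length(down)) get_null(ctx, ranking, length(down))),
        error = function(e) {
          warn(sprintf("Excluding %s in context %s: %s",
                       sig$signature_id[[1]], ctx, conditionMessage(e)),
               class = "sigrev_exclusion_warning")
          NULL
        })
      out[[pos]] <- row
    }
  }
  bind_rows(out)
}

#' Assemble the drugs-by-contexts reversal matrix
#'
#' Pivots per-(drug, context) scores into a complete `delta_nes`
#' matrix. Drugs missing a score in any context are dropped with a
#' warning listing their ids. Rows (signature ids) and columns
#' (context labels) are ordered lexicographically, so the result does
#' not depend on input order.
#'
#' @param scores Tibble from [score_library()].
#' @return A `delta_nes_matrix` object: list with `mat` (numeric
#'   matrix), `scores` (the complete long tibble, retaining
#'   leading-edge gene sets), and `cluster`/`k`/`cluster_summary`
#'   slots filled by [cluster_matrix()].
#' @export
assemble_matrix <- function(scores) {
  contexts <- sort(unique(scores$context))
  counts <- scores |>
    group_by(.data$signature_id) |>
    summarise(n_ctx = dplyr::n_distinct(.data$context), .groups = "drop")
  incomplete <- counts$signature_id[counts$n_ctx < length(contexts)]
  if (length(incomplete)) {
    warn(paste0("Dropping drug(s) not scored in every context: ",
                paste(sort(incomplete), collapse = ", ")),
         class = "sigrev_incomplete_warning")
    scores <- filter(scores, !.data$signature_id %in% incomplete)
  }
  if (!nrow(scores)) {
    abort("No drug was scored in every context; matrix is empty.",
          class = "sigrev_empty_matrix_error")
  }
  wide <- scores |>
    select(all_of(c("signature_id", "context", "delta_nes"))) |>
    tidyr::pivot_wider(names_from = "context", values_from = "delta_nes") |>
    arrange(.data$signature_id)
  mat <- as.matrix(wide[, contexts, drop = FALSE])
  rownames(mat) <- wide$signature_id
  structure(list(mat = mat, scores = arrange(scores, .data$signature_id,
                                             .data$context),
                 cluster = NULL, k = NULL, cluster_summary = NULL),
            class = "delta_nes_matrix")
}

# k-means++ seeding: first center uniform, then proportional to the
# squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      pick <- if (all(d2 == 0)) sample.int(n, 1L)
              else sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Cluster the reversal matrix
#'
#' k-means (k-means++ seeding, `n_init` restarts keeping the lowest
#' total within-cluster sum of squares) on the raw `delta_nes` rows.
#' Rows are not standardized: NES values from the same permutation
#' scheme already share a scale. An agglomerative alternative
#' (`method = "ward"`, Ward.D2 on Euclidean distances) is provided for
#' comparison. A per-cluster summary (size, per-context mean
#' `delta_nes`, the across-context minimum and overall mean) is
#' attached.
#'
#' @param m A `delta_nes_matrix` from [assemble_matrix()].
#' @param k Number of clusters (must not exceed the number of drugs).
#' @param seed Integer seed for the k-means initialization.
#' @param n_init Number of k-means restarts.
#' @param method `"kmeans"` (default) or `"ward"`.
#' @return The `delta_nes_matrix` with `cluster` (named integer
#'   vector), `k` and `cluster_summary` filled in.
#' @export
cluster_matrix <- function(m, k = 50, seed = 1L, n_init = 10,
                           method = c("kmeans", "ward")) {
  method <- rlang::arg_match(method)
  stopifnot_scalar_num(k, "k", 1, Inf, TRUE)
  x <- m$mat
  if (k > nrow(x)) {
    abort(sprintf("k (%d) exceeds the number of drugs (%d).",
                  k, nrow(x)), class = "sigrev_argument_error")
  }
  if (method == "kmeans") {
    fit <- withr::with_seed(derive_seed(seed, "kmeans"), {
      best <- NULL
      for (i in seq_len(n_init)) {
        centers <- kmeanspp_centers(x, k)
        centers <- centers[!duplicated(centers), , drop = FALSE]
        cand <- suppressWarnings(
          kmeans(x, centers = centers, iter.max = 100L,
                 algorithm = "Lloyd"))
        if (is.null(best) || cand$tot.withinss < best$tot.withinss) {
          best <- cand
        }
      }
      best
    })
    assignment <- fit$cluster
    tot_withinss <- fit$tot.withinss
  } else {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    assignment <- stats::cutree(hc, k = k)
    tot_withinss <- NA_real_
  }
  names(assignment) <- rownames(x)
  m$cluster <- assignment
  m$k <- as.integer(k)
  m$tot_withinss <- tot_withinss
  m$cluster_summary <- cluster_summarize(x, assignment)
  m
}

# Per-cluster size, per-context mean delta_nes, across-context minimum
# and overall mean of the per-context means.
cluster_summarize <- function(x, assignment) {
  per_ctx <- stats::aggregate(x, by = list(cluster = assignment), mean)
  sizes <- as.integer(table(assignment)[as.character(per_ctx$cluster)])
  ctx_cols <- colnames(x)
  as_tibble(per_ctx) |>
    mutate(size = sizes,
           min_context_mean = do.call(pmin, as.list(per_ctx[ctx_cols])),
           overall_mean = rowMeans(per_ctx[ctx_cols])) |>
    select(all_of(c("cluster", "size", ctx_cols,
                    "min_context_mean", "overall_mean"))) |>
    arrange(desc(.data$min_context_mean))
}

#' Select the strongest-reversal cluster
#'
#' Picks the cluster whose per-context mean `delta_nes` is highest "in
#' every context": the argmax of the across-context minimum of the
#' per-context means (`rule = "min"`, robust to one context
#' dominating), or of the overall mean (`rule = "mean"`). Ties are
#' broken by larger overall mean, then larger cluster size, then lower
#' cluster index.
#'
#' @param m A clustered `delta_nes_matrix`.
#' @param rule `"min"` (default) or `"mean"`.
#' @return The selected cluster index (integer).
#' @export
select_top_cluster <- function(m, rule = c("min", "mean")) {
  rule <- rlang::arg_match(rule)
  if (is.null(m$cluster)) {
    abort("Matrix is not clustered yet; run cluster_matrix() first.",
          class = "sigrev_argument_error")
  }
  s <- m$cluster_summary
  key <- if (rule == "min") s$min_context_mean else s$overall_mean
  ord <- order(-key, -s$overall_mean, -s$size, s$cluster)
  as.integer(s$cluster[[ord[[1]]]])
}

#' Recurring target genes of a drug cluster
#'
#' Counts, over the members of one cluster, how many drugs carry each
#' gene in the leading edge of their down-regulation signature — the
#' genes the cluster's drugs recurrently push down, i.e. the putative
#' targets of the predicted reversal. Frequencies are sorted
#' descending, ties broken lexicographically, and cut to `top_n` rows.
#'
#' @param m A clustered `delta_nes_matrix`.
#' @param cluster_index Cluster to summarise; defaults to
#'   [select_top_cluster()].
#' @param context Context whose leading edges are counted; defaults to
#'   the first (lexicographic) context.
#' @param top_n Number of rows to keep (default 35); `Inf` keeps all.
#' @return A tibble `gene, frequency` (integer counts,
#'   `1 <= frequency <= cluster size`).
#' @export
recurring_targets <- function(m, cluster_index = NULL, context = NULL,
                              top_n = 35) {
  if (is.null(m$cluster)) {
    abort("Matrix is not clustered yet; run cluster_matrix() first.",
          class = "sigrev_argument_error")
  }
  cluster_index <- cluster_index %||% select_top_cluster(m)
  context <- context %||% colnames(m$mat)[[1]]
  members <- names(m$cluster)[m$cluster == cluster_index]
  if (!length(members)) {
    abort(sprintf("Cluster %s is empty.", cluster_index),
          class = "sigrev_argument_error")
  }
  les <- m$scores |>
    filter(.data$signature_id %in% members, .data$context == !!context)
  counts <- table(unlist(les$leading_edge_down))
  if (!length(counts)) {
    return(tibble(gene = character(), frequency = integer()))
  }
  out <- tibble(gene = names(counts),
                frequency = as.integer(counts)) |>
    arrange(desc(.data$frequency), .data$gene)
  head(out, top_n)
}
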