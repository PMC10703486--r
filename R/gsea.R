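#' Weighted running-sum enrichment score
#'
#' Computes the pre-ranked GSEA enrichment statistic of a gene set
#' along a ranked list: walking down the ranking, the running sum
#' increases by `|score|^weight / sum(|score in set|^weight)` at set
#' members ("hits") and decreases by `1 / (N - set size)` at
#' non-members. The enrichment score is the signed deviation of
#' maximum magnitude. Set genes absent from the ranking are dropped
#' (their count is reported via a message), not treated as misses.
#'
#' @param ranking A tibble `gene, score` sorted descending by score
#'   (see [build_ranking()]).
#' @param gene_set Character vector of gene ids.
#' @param weight Non-negative exponent on `|score|` for hit increments;
#'   `weight = 0` gives the classical unweighted Kolmogorov-Smirnov
#'   statistic, `weight = 1` (default) the standard GSEA statistic.
#' @param quiet Suppress the dropped-genes message.
#' @return A list with `es` (in `[-1, 1]`), `running_sum` (length =
#'   ranking size), `extremum_index`, `hits` (logical vector) and
#'   `n_dropped`.
#' @export
#' @examples
#' rk <- tibble::tibble(gene = paste0("g", 1:6),
#'                      score = c(3, 2, 1, -1, -2, -3))
#' enrichment_score(rk, c("g1", "g2"))$es
enrichment_score <- function(ranking, gene_set, weight = 1, quiet = FALSE) {
  stopifnot_scalar_num(weight, "weight", 0)
  n <- nrow(ranking)
  hits <- ranking$gene %in% gene_set
  k <- sum(hits)
  n_dropped <- length(unique(gene_set)) - k
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("%d of %d set genes absent from the ranking were dropped.",
                   n_dropped, length(unique(gene_set))))
  }
  if (k == 0L) {
    abort("Gene set has no overlap with the ranked universe.",
          class = "sigrev_empty_overlap_error")
  }
  if (k == n) {
    abort("Gene set covers the whole universe; miss step is undefined.",
          class = "sigrev_degenerate_error")
  }
  w <- abs(ranking$score)^weight
  nr <- sum(w[hits])
  if (nr == 0) {
    abort("All set members have zero |score|^weight; hit step is undefined.",
          class = "sigrev_degenerate_error")
  }
  # hit and miss contributions accumulated separately: the miss ramp is
  # an exact integer-count ratio, so extremal sets reach exactly +/-1,
  # and the accumulation order matches es_from_positions() bit for bit
  # so permutation ties are counted consistently
  hit_cum <- cumsum(ifelse(hits, w, 0)) / nr
  miss_cum <- cumsum(!hits)
  running <- hit_cum - miss_cum / (n - k)
  idx <- es_extremum_index(running)
  list(es = running[[idx]], running_sum = running, extremum_index = idx,
       hits = hits, n_dropped = n_dropped)
}

# Signed extremum of a running sum. Deviations whose magnitudes are
# within ES_TOL of the maximum count as tied, and the earliest rank
# wins -- without the tolerance, a running sum that touches +m and -m
# exactly (possible on small discrete rankings) would resolve the tie
# by accumulation noise.
ES_TOL <- 1e-10

es_extremum_index <- function(values) {
  which(abs(values) >= max(abs(values)) - ES_TOL)[[1]]
}

# O(set size) enrichment score from hit positions in a pre-sorted
# ranking; used for the permutation null. `w` is |score|^weight for the
# full ranking. Uses the same accumulation order and tie rule as
# enrichment_score(), so the two agree bit for bit (tested).
es_from_positions <- function(w, n, positions) {
  k <- length(positions)
  wi <- w[positions]
  cum <- cumsum(wi)
  nr <- cum[[k]]
  drop_miss <- (positions - seq_len(k)) / (n - k)
  h <- cum / nr - drop_miss          # running sum at each hit
  b <- c(0, cum[-k]) / nr - drop_miss # running sum just before each hit
  cand <- as.vector(rbind(b, h))      # position order: b1,h1,b2,h2,...
  cand[[es_extremum_index(cand)]]
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `n_perm` uniform random gene sets of the given size from the
#' ranked universe (gene-set permutation, the only null available for a
#' pre-ranked list) and returns their enrichment scores.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets.
#' @param n_perm Number of permutations.
#' @param seed Integer seed; the null is deterministic given
#'   `(ranking, set_size, weight, n_perm, seed)`.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
gsea_null <- function(ranking, set_size, weight = 1, n_perm = 1000,
                      seed = 1L) {
  n <- nrow(ranking)
  if (set_size >= n) {
    abort("`set_size` must be smaller than the universe.",
          class = "sigrev_degenerate_error")
  }
  w <- abs(ranking$score)^weight
  withr::with_seed(derive_seed(seed, set_size), {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(w, n, sort(sample.int(n, set_size)))
    }, numeric(1))
  })
}

#' Pre-ranked GSEA with permutation NES and p-value
#'
#' Computes the enrichment score of `gene_set` against `ranking`,
#' normalizes it against a gene-permutation null of same-size random
#' sets, and extracts the leading edge. Normalization is
#' sign-stratified: `nes = es / |mean(null scores of the same sign)|`,
#' so the sign of NES equals the sign of ES. The permutation p-value is
#' `(1 + #same-sign nulls at least as extreme) / (1 + #same-sign
#' nulls)`.
#'
#' @inheritParams enrichment_score
#' @inheritParams gsea_null
#' @param null Optional precomputed null score vector (from
#'   [gsea_null()] with matching `set_size`); when supplied, `n_perm`
#'   and `seed` are ignored and no random numbers are drawn.
#' @return A `gsea_result` object: list with `es`, `nes`, `pvalue`,
#'   `leading_edge` (character vector in rank order), `running_sum`,
#'   `extremum_index`, `n_perm_used`, `set_size_used`, `n_dropped`,
#'   `weight`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' rk <- tibble::tibble(gene = paste0("g", 1:20), score = 10:-9)
#' res <- gsea_preranked(rk, paste0("g", 1:4), n_perm = 200, seed = 7)
#' tidy(res)
gsea_preranked <- function(ranking, gene_set, weight = 1, n_perm = 1000,
                           seed = 1L, null = NULL, quiet = FALSE) {
  es_out <- enrichment_score(ranking, gene_set, weight, quiet = quiet)
  es <- es_out$es
  k <- sum(es_out$hits)
  if (is.null(null)) {
    if (n_perm < 100) {
      warn("Fewer than 100 permutations; reported p-values are unreliable.",
           class = "sigrev_nperm_warning")
    }
    null <- gsea_null(ranking, k, weight, n_perm, seed)
  }
  le <- leading_edge(es_out$running_sum, es_out$extremum_index,
                     gene_set, ranking)
  if (es == 0) {
    nes <- 0
    pvalue <- 1
  } else {
    same <- if (es > 0) null > 0 else null < 0
    if (!any(same)) {
      abort("No null scores share the sign of the observed ES; NES is undefined.",
            class = "sigrev_nes_undefined_error")
    }
    nes <- es / abs(mean(null[same]))
    pvalue <- (1 + sum(abs(null[same]) >= abs(es))) / (1 + sum(same))
  }
  structure(list(es = es, nes = nes, pvalue = pvalue, leading_edge = le,
                 running_sum = es_out$running_sum,
                 extremum_index = es_out$extremum_index,
                 hits = es_out$hits,
                 n_perm_used = length(null), set_size_used = k,
                 n_dropped = es_out$n_dropped, weight = weight),
            class = "gsea_result")
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive enrichment score, the set members at ranks up to and
#' including the running-sum extremum; for a negative score, the
#' members at or after the extremum; empty for a zero score.
#'
#' @param running_sum Numeric running sum from [enrichment_score()].
#' @param extremum_index Index of the signed extremum.
#' @param gene_set The query gene set.
#' @param ranking The ranked list the running sum was computed on.
#' @return Character vector of leading-edge genes in rank order.
#' @export
leading_edge <- function(running_sum, extremum_index, gene_set, ranking) {
  es <- running_sum[[extremum_index]]
  if (es == 0) return(character())
  idx <- if (es > 0) seq_len(extremum_index)
         else seq(extremum_index, length(running_sum))
  genes <- ranking$gene[idx]
  genes[genes %in% gene_set]
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "<gsea_result> ES = %.4f, NES = %.4f, p = %.4g (%d permutations)\n",
    x$es, x$nes, x$pvalue, x$n_perm_used))
  cat(sprintf("  set size used: %d (%d dropped); leading edge: %d genes\n",
              x$set_size_used, x$n_dropped, length(x$leading_edge)))
  invisible(x)
}
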