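#' Single-sample signature enrichment (ssGSEA-style)
#'
#' Scores each signature in each sample from within-sample expression
#' ranks alone: genes are ordered by decreasing expression (ties broken
#' by gene id), rank weights `(N - position + 1)^weight` drive the hit
#' increments of a running sum (misses decrement by `1/(N - set
#' size)`), and the score is the mean of the running sum — a
#' normalized area statistic in `[-1, 1]`. Higher scores mean the
#' signature's genes sit higher in that sample's expression profile.
#' Because only ranks enter, the score is invariant to any monotone
#' transform of a sample's expression vector.
#'
#' @param expr Expression tibble with a `gene` column and one numeric
#'   column per sample (non-negative values), or a numeric matrix with
#'   gene rownames.
#' @param signatures Named list of gene-id character vectors, or a
#'   tibble from [read_gmt()].
#' @param meta Optional sample sheet (`sample, donor, treatment`);
#'   when given, its columns are joined onto the result.
#' @param weight Rank-weight exponent (default 0.25).
#' @param min_overlap Signatures overlapping fewer than this many
#'   measured genes are skipped with a warning (default 5).
#' @return A long tibble `sample, signature, score` (plus metadata
#'   columns if `meta` is given).
#' @export
sample_enrichment <- function(expr, signatures, meta = NULL,
                              weight = 0.25, min_overlap = 5) {
  if (is.matrix(expr)) {
    expr <- tibble(gene = rownames(expr)) |>
      bind_cols_list(as.list(as.data.frame(expr)))
  }
  if (is.data.frame(signatures) && "set_name" %in% names(signatures)) {
    signatures <- setNames(signatures$genes, signatures$set_name)
  }
  genes <- expr$gene
  n <- length(genes)
  keep <- vapply(signatures, function(s) sum(s %in% genes) >= min_overlap,
                 logical(1))
  if (any(!keep)) {
    warn(paste0("Skipping signature(s) overlapping fewer than ",
                min_overlap, " measured genes: ",
                paste(names(signatures)[!keep], collapse = ", ")),
         class = "sigrev_overlap_warning")
  }
  signatures <- signatures[keep]
  if (!length(signatures)) {
    abort("No signature passes the overlap floor.",
          class = "sigrev_empty_overlap_error")
  }
  sample_cols <- setdiff(names(expr), "gene")
  rank_w <- (n - seq_len(n) + 1)^weight
  res <- purrr::map(sample_cols, function(smp) {
    ord <- order(-expr[[smp]], genes, method = "radix")
    gene_sorted <- genes[ord]
    scores <- vapply(signatures, function(sig) {
      hits <- gene_sorted %in% sig
      k <- sum(hits)
      step <- ifelse(hits, rank_w / sum(rank_w[hits]), -1 / (n - k))
      mean(cumsum(step))
    }, numeric(1))
    tibble(sample = smp, signature = names(signatures), score = scores)
  }) |> bind_rows()
  if (!is.null(meta)) res <- left_join(res, meta, by = "sample")
  res
}

#' Compare treated to control enrichment by Wilcoxon rank-sum
#'
#' Two-sided Wilcoxon rank-sum test of one treatment's per-sample
#' enrichment scores against the vehicle control for one signature,
#' with the median difference as effect size (negative = the treatment
#' reduces the signature). The test is exact when the combined sample
#' size is at most 20 and there are no ties, and uses the normal
#' approximation with continuity correction otherwise.
#'
#' @param enr Long enrichment tibble from [sample_enrichment()]
#'   including a `treatment` column.
#' @param treatment Treatment label to test.
#' @param signature Signature name to test.
#' @param control Control label (default `"DMSO"`).
#' @return A one-row tibble `treatment, signature, n_treated,
#'   n_control, delta_median, pvalue`.
#' @export
compare_to_control <- function(enr, treatment, signature,
                               control = "DMSO") {
  sub <- filter(enr, .data$signature == !!signature,
                .data$treatment %in% c(!!treatment, !!control))
  x <- sub$score[sub$treatment == treatment]
  y <- sub$score[sub$treatment == control]
  if (length(x) < 2 || length(y) < 2) {
    abort(sprintf(
      "Need >= 2 samples per group for %s vs %s on %s (got %d vs %d).",
      treatment, control, signature, length(x), length(y)),
      class = "sigrev_grouping_error")
  }
  combined <- c(x, y)
  if (length(unique(combined)) == 1L) {
    pvalue <- 1
  } else {
    use_exact <- length(combined) <= 20 && !any(duplicated(combined))
    pvalue <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                  correct = TRUE)$p.value)
    if (!is.finite(pvalue)) pvalue <- 1
  }
  tibble(treatment = treatment, signature = signature,
         n_treated = length(x), n_control = length(y),
         delta_median = median(x) - median(y), pvalue = pvalue)
}

#' Treatment-by-signature reversal report
#'
#' Runs [compare_to_control()] over every (treatment, signature) pair
#' and attaches the significance label used in the figures: `"**"` for
#' p < 0.01, `"*"` for p < 0.05 (strict inequalities), `"ns"`
#' otherwise. Per-comparison p-values are reported unadjusted by
#' default; `adjust = "BH"` applies Benjamini-Hochberg across the grid
#' before labelling.
#'
#' @inheritParams compare_to_control
#' @param treatments Treatment labels to report; defaults to every
#'   non-control treatment present.
#' @param signatures Signature names; defaults to every signature
#'   present.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A long tibble `treatment, signature, n_treated, n_control,
#'   delta_median, pvalue, significance`.
#' @export
reversal_report <- function(enr, treatments = NULL, signatures = NULL,
                            control = "DMSO",
                            adjust = c("none", "BH")) {
  adjust <- rlang::arg_match(adjust)
  treatments <- treatments %||%
    setdiff(sort(unique(enr$treatment)), control)
  signatures <- signatures %||% sort(unique(enr$signature))
  out <- tidyr::expand_grid(treatment = treatments,
                            signature = signatures) |>
    purrr::pmap(function(treatment, signature) {
      compare_to_control(enr, treatment, signature, control = control)
    }) |>
    bind_rows()
  if (adjust == "BH") out$pvalue <- p.adjust(out$pvalue, method = "BH")
  out |>
    mutate(significance = dplyr::case_when(
      .data$pvalue < 0.01 ~ "**",
      .data$pvalue < 0.05 ~ "*",
      TRUE ~ "ns"))
}
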