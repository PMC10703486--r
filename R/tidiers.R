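#' Tidy a GSEA result
#'
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @return One-row tibble `es, nes, pvalue, set_size_used, n_dropped,
#'   n_leading, n_perm_used`.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, pvalue = x$pvalue,
         set_size_used = x$set_size_used, n_dropped = x$n_dropped,
         n_leading = length(x$leading_edge),
         n_perm_used = x$n_perm_used)
}

#' @rdname tidy.gsea_result
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(nes = x$nes, pvalue = x$pvalue, weight = x$weight,
         n_perm_used = x$n_perm_used)
}

#' Tidy a reversal matrix
#'
#' @param x A `delta_nes_matrix`.
#' @param ... Unused.
#' @return Long tibble `signature_id, context, delta_nes` plus
#'   `cluster` once [cluster_matrix()] has run.
#' @method tidy delta_nes_matrix
#' @export
tidy.delta_nes_matrix <- function(x, ...) {
  out <- as_tibble(x$mat, rownames = "signature_id") |>
    tidyr::pivot_longer(-"signature_id", names_to = "context",
                        values_to = "delta_nes")
  if (!is.null(x$cluster)) {
    out$cluster <- unname(x$cluster[out$signature_id])
  }
  out
}

#' @rdname tidy.delta_nes_matrix
#' @method glance delta_nes_matrix
#' @export
glance.delta_nes_matrix <- function(x, ...) {
  tibble(n_drugs = nrow(x$mat), n_contexts = ncol(x$mat),
         k = x$k %||% NA_integer_,
         tot_withinss = x$tot_withinss %||% NA_real_,
         selected_cluster = if (is.null(x$cluster)) NA_integer_
                            else select_top_cluster(x))
}

#' @export
print.delta_nes_matrix <- function(x, ...) {
  cat(sprintf("<delta_nes_matrix> %d drugs x %d contexts (%s)\n",
              nrow(x$mat), ncol(x$mat),
              paste(colnames(x$mat), collapse = ", ")))
  if (!is.null(x$cluster)) {
    cat(sprintf("  clustered: k = %d, selected cluster = %d\n",
                x$k, select_top_cluster(x)))
  }
  invisible(x)
}
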