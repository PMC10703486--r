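#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than
#' three fields raise a parse error naming the offending line number.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description` and `genes`
#'   (list-column of character vectors). An empty file yields a
#'   zero-row tibble.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path), class = "sigrev_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(set_name = character(), description = character(),
                  genes = list()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("Malformed GMT line %d in %s: fewer than 3 tab-separated fields.",
                    i, path), class = "sigrev_parse_error")
    }
    list(set_name = fields[[1]], description = fields[[2]],
         genes = fields[-(1:2)])
  })
  tibble(set_name = vapply(parsed, `[[`, character(1), "set_name"),
         description = vapply(parsed, `[[`, character(1), "description"),
         genes = lapply(parsed, `[[`, "genes"))
}

#' Write gene sets to a GMT file
#'
#' @param sets A tibble as returned by [read_gmt()], or a named list of
#'   character vectors (description then defaults to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.list(sets) && !is.data.frame(sets)) {
    sets <- tibble(set_name = names(sets),
                   description = names(sets),
                   genes = unname(sets))
  }
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[[i]], sets$description[[i]], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a disease differential-expression table
#'
#' Tab-delimited with header `gene  log2fc  stat  padj`.
#'
#' @param path File path.
#' @param context Optional context label attached as the `"context"`
#'   attribute.
#' @return A tibble `gene, log2fc, stat, padj`.
#' @export
read_de_table <- function(path, context = NULL) {
  de <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), log2fc = readr::col_double(),
    stat = readr::col_double(), padj = readr::col_double()))
  validate_de_table(de)
  if (!is.null(context)) attr(de, "context") <- context
  de
}

#' @rdname read_de_table
#' @param de A DE tibble.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de[, c("gene", "log2fc", "stat", "padj")], path)
  invisible(path)
}

validate_de_table <- function(de) {
  need <- c("gene", "log2fc", "stat", "padj")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols)) {
    abort(paste0("DE table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "sigrev_validation_error")
  }
  if (anyDuplicated(de$gene)) {
    abort("DE table contains duplicate gene identifiers.",
          class = "sigrev_validation_error")
  }
  if (any(de$padj < 0 | de$padj > 1, na.rm = TRUE)) {
    abort("`padj` values must lie in [0, 1].",
          class = "sigrev_validation_error")
  }
  invisible(de)
}

#' Build a ranked gene list from a DE table
#'
#' Genes are sorted in descending order of the chosen signed metric
#' (the DE test statistic by default, which folds in dispersion; signed
#' log2 fold-change as the alternative). Ties are broken by ascending
#' lexicographic gene id so the ranking is deterministic and invariant
#' to input row order.
#'
#' @param de A DE tibble (`gene, log2fc, stat, padj`).
#' @param metric `"stat"` or `"log2fc"`.
#' @return A tibble `gene, score` sorted descending by `score`; the
#'   input's `"context"` attribute, if any, is carried over.
#' @export
build_ranking <- function(de, metric = c("stat", "log2fc")) {
  metric <- rlang::arg_match(metric)
  validate_de_table(de)
  score <- de[[metric]]
  if (any(!is.finite(score))) {
    abort(sprintf("Non-finite values in `%s`; cannot rank.", metric),
          class = "sigrev_validation_error")
  }
  ord <- order(-score, de$gene, method = "radix")
  out <- tibble(gene = de$gene[ord], score = score[ord])
  attr(out, "context") <- attr(de, "context")
  out
}

#' Select top differentially expressed genes
#'
#' Keeps genes passing the adjusted-p significance cutoff, optionally
#' restricted by sign of `log2fc`, ranks them by decreasing `|metric|`
#' and truncates to the first `n`. If fewer than `n` genes pass, all of
#' them are returned with a warning.
#'
#' @inheritParams build_ranking
#' @param n Number of genes to keep (>= 1).
#' @param direction `"both"`, `"up"` (log2fc > 0) or `"down"`
#'   (log2fc < 0).
#' @param padj_cutoff Significance threshold on `padj` (strict `<`).
#' @return Character vector of gene ids (possibly shorter than `n`).
#' @export
select_top_degs <- function(de, n, direction = c("both", "up", "down"),
                            metric = c("stat", "log2fc"),
                            padj_cutoff = 0.05) {
  direction <- rlang::arg_match(direction)
  metric <- rlang::arg_match(metric)
  stopifnot_scalar_num(n, "n", 1, Inf, TRUE)
  validate_de_table(de)
  keep <- de$padj < padj_cutoff
  if (direction == "up") keep <- keep & de$log2fc > 0
  if (direction == "down") keep <- keep & de$log2fc < 0
  sig <- de[keep & !is.na(keep), ]
  ord <- order(-abs(sig[[metric]]), sig$gene, method = "radix")
  genes <- sig$gene[ord]
  if (length(genes) < n) {
    warn(sprintf("Only %d of the requested %d genes pass padj < %g.",
                 length(genes), n, padj_cutoff),
         class = "sigrev_truncation_warning")
  }
  head(genes, n)
}

#' Build a drug signature from per-gene fold changes
#'
#' Orders genes by fold change and keeps at most `cap` genes per
#' direction: the up-set holds the largest positive fold changes, the
#' down-set the most negative. With `truncation = "overall"` the `cap`
#' genes of largest `|fold change|` are taken first and then split by
#' sign.
#'
#' @param fold_changes Named numeric vector: gene -> fold change.
#' @param drug_name,database,database_id Identifier triplet; the
#'   signature id is `"drug-name_database_database-id"`.
#' @param cap Maximum genes per set (default 300).
#' @param truncation `"per_direction"` (default) or `"overall"`.
#' @return A one-row tibble `signature_id, drug_name, database,
#'   database_id, up, down` (`up`/`down` list-columns).
#' @export
build_drug_signature <- function(fold_changes, drug_name, database,
                                 database_id, cap = 300,
                                 truncation = c("per_direction", "overall")) {
  truncation <- rlang::arg_match(truncation)
  if (is.null(names(fold_changes)) || anyDuplicated(names(fold_changes))) {
    abort("`fold_changes` must be uniquely named by gene.",
          class = "sigrev_validation_error")
  }
  fc <- fold_changes[fold_changes != 0]
  if (length(fc) < 2L) {
    abort("Degenerate signature: fewer than 2 genes with nonzero fold change.",
          class = "sigrev_degenerate_error")
  }
  if (truncation == "overall") {
    keep <- names(fc)[order(-abs(fc), names(fc), method = "radix")]
    fc <- fc[head(keep, cap)]
  }
  pos <- fc[fc > 0]
  neg <- fc[fc < 0]
  up <- names(pos)[order(-pos, names(pos), method = "radix")]
  down <- names(neg)[order(neg, names(neg), method = "radix")]
  tibble(signature_id = paste(drug_name, database, database_id, sep = "_"),
         drug_name = drug_name, database = database,
         database_id = database_id,
         up = list(head(up, cap)), down = list(head(down, cap)))
}

#' Read / write a drug-signature library
#'
#' A library on disk is a GMT pair (`<prefix>.up.gmt`,
#' `<prefix>.down.gmt`, one set per signature keyed by signature id)
#' plus a TSV manifest `<prefix>.manifest.tsv` with columns
#' `signature_id, drug_name, database, database_id`.
#'
#' @param prefix Path prefix for the three files.
#' @return For `read_drug_library()`, the library tibble
#'   (`signature_id, drug_name, database, database_id, up, down`).
#' @export
read_drug_library <- function(prefix) {
  manifest <- readr::read_tsv(paste0(prefix, ".manifest.tsv"),
                              col_types = readr::cols(.default = readr::col_character()))
  up <- read_gmt(paste0(prefix, ".up.gmt"))
  down <- read_gmt(paste0(prefix, ".down.gmt"))
  if (anyDuplicated(manifest$signature_id)) {
    abort("Duplicate signature_id in manifest.",
          class = "sigrev_validation_error")
  }
  manifest |>
    mutate(up = unname(setNames(up$genes, up$set_name)[.data$signature_id]),
           down = unname(setNames(down$genes, down$set_name)[.data$signature_id]))
}

#' @rdname read_drug_library
#' @param library A library tibble.
#' @export
write_drug_library <- function(library, prefix) {
  readr::write_tsv(library[, c("signature_id", "drug_name", "database",
                               "database_id")],
                   paste0(prefix, ".manifest.tsv"))
  write_gmt(tibble(set_name = library$signature_id,
                   description = library$drug_name,
                   genes = library$up),
            paste0(prefix, ".up.gmt"))
  write_gmt(tibble(set_name = library$signature_id,
                   description = library$drug_name,
                   genes = library$down),
            paste0(prefix, ".down.gmt"))
  invisible(prefix)
}

#' Read / write a two-column RNK ranked-list file
#'
#' Tab-delimited `gene<TAB>score`, no header, scores written with six
#' significant digits.
#'
#' @param path File path.
#' @return For `read_rnk()`, a tibble `gene, score` (descending).
#' @export
read_rnk <- function(path) {
  rnk <- readr::read_tsv(path, col_names = c("gene", "score"),
                         col_types = "cd")
  arrange(rnk, desc(.data$score), .data$gene)
}

#' @rdname read_rnk
#' @param ranking A tibble `gene, score`.
#' @export
write_rnk <- function(ranking, path) {
  writeLines(paste(ranking$gene, signif(ranking$score, 6), sep = "\t"),
             path)
  invisible(path)
}

#' Write / read the synthetic ground truth sidecar (test-only)
#'
#' JSON sidecar recording the planted module genes and drug classes.
#' It exists for parameter-recovery tests and is never an input to the
#' scoring pipeline.
#'
#' @param truth A `sigrev_truth` object.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(note = "synthetic ground truth; test-only, not a pipeline input",
         module_genes = truth$module_genes,
         drug_class = as.list(truth$drug_class)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(module_genes = x$module_genes,
                 drug_class = unlist(x$drug_class)),
            class = "sigrev_truth")
}
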