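#' Construct a probe-by-sample expression dataset
#'
#' A light container for a log2 expression matrix with a sample-to-group
#' annotation and a probe-to-gene mapping, the unit of input for the
#' differential-expression stage. Values are assumed to be on the log2 scale
#' already.
#'
#' @param values Numeric probe-by-sample matrix of log2 expression with probe
#'   IDs as rownames and sample IDs as colnames.
#' @param groups Per-sample group labels, each `"normal"` or `"BE"`, in column
#'   order (or a named vector keyed by sample).
#' @param gene_symbols Per-probe gene label, in row order; defaults to the
#'   probe IDs.
#' @param auto_log2 If `TRUE`, apply `log2(x + 1)` when the 99th percentile of
#'   values exceeds 100 (a common heuristic for repository matrices deposited
#'   on the linear scale); off by default, and a message is emitted when it
#'   fires.
#'
#' @return An object of class `expression_dataset` with elements `values`,
#'   `probe_ids`, `gene_symbols`, and `groups` (tibble of `sample`, `group`).
#' @export
expression_dataset <- function(values, groups, gene_symbols = NULL,
                               auto_log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have probe rownames and sample colnames",
          class = "beconcord_error_parse")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicated sample identifiers", class = "beconcord_error_parse")
  }
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    abort("one group label per sample is required",
          class = "beconcord_error_dimension")
  }
  bad <- setdiff(unique(groups), c("normal", "BE"))
  if (length(bad)) {
    abort(paste0("group labels must be 'normal' or 'BE'; found: ",
                 paste(bad, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  if (any(table(groups) < 2) || length(unique(groups)) < 2) {
    abort("at least 2 samples per group are required",
          class = "beconcord_error_grouping")
  }
  if (auto_log2 &&
      stats::quantile(values, 0.99, na.rm = TRUE) > 100) {
    rlang::inform("values look linear-scale; applying log2(x + 1)")
    values <- log2(values + 1)
  }
  if (any(is.infinite(values))) {
    abort("expression values must be finite where present",
          class = "beconcord_error_domain")
  }
  gene_symbols <- gene_symbols %||% rownames(values)
  if (length(gene_symbols) != nrow(values)) {
    abort("one gene symbol per probe is required",
          class = "beconcord_error_dimension")
  }
  structure(
    list(
      values = values,
      probe_ids = rownames(values),
      gene_symbols = as.character(gene_symbols),
      groups = tibble(sample = colnames(values), group = groups)
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$groups$group)
  cat(sprintf(
    "<expression_dataset> %d probes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Tidy an expression dataset into long form
#'
#' @param x An [expression_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per (probe, sample) holding `probe_id`,
#'   `gene_symbol`, `sample`, `group`, `log2_expr`.
#' @export
tidy.expression_dataset <- function(x, ...) {
  as_tibble(x$values, rownames = "probe_id") |>
    mutate(gene_symbol = x$gene_symbols, .after = "probe_id") |>
    tidyr::pivot_longer(-c("probe_id", "gene_symbol"),
                        names_to = "sample", values_to = "log2_expr") |>
    left_join(x$groups, by = "sample") |>
    select("probe_id", "gene_symbol", "sample", "group", "log2_expr")
}
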