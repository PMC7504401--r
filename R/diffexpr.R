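#' Per-probe log2 fold change between groups
#'
#' The least-squares two-group estimate: mean log2 expression in the BE
#' samples minus mean in the normal samples, per probe.
#'
#' @param dataset An [expression_dataset()].
#' @return A tibble of `probe_id`, `gene_symbol`, `logFC`.
#' @export
log2_fold_change <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  be <- dataset$groups$sample[dataset$groups$group == "BE"]
  nrm <- dataset$groups$sample[dataset$groups$group == "normal"]
  if (length(be) < 1 || length(nrm) < 1) {
    abort("both groups need at least one sample",
          class = "beconcord_error_grouping")
  }
  tibble(
    probe_id = dataset$probe_ids,
    gene_symbol = dataset$gene_symbols,
    logFC = unname(rowMeans(dataset$values[, be, drop = FALSE]) -
                     rowMeans(dataset$values[, nrm, drop = FALSE]))
  )
}

# Newton inversion of the trigamma function, used by the moment-matching
# hyperparameter estimator. Monotone decreasing on (0, Inf).
.trigamma_inverse <- function(x) {
  out <- x
  pos <- !is.na(x) & x > 0
  out[!pos & !is.na(x)] <- Inf
  y <- 0.5 + 1 / x[pos]
  for (i in seq_len(60)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[pos] <- y
  out
}

#' Estimate the gene-variance prior by moment matching
#'
#' Fits the hierarchical model in which true gene variances follow a scaled
#' inverse-chi-square prior with `d0` degrees of freedom and scale `s0_sq`,
#' so that observed residual variances are `s0_sq` times an F variate. The
#' hyperparameters are estimated by matching the first two moments of
#' `log(s_g^2)`, whose mean and variance have closed forms in digamma /
#' trigamma functions under the model. When the excess variance of the log
#' variances is non-positive the prior is degenerate and `d0 = Inf` is
#' returned (all genes share variance `s0_sq`).
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @return A list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(keep)) {
    abort("all residual variances are zero or undefined; cannot fit prior",
          class = "beconcord_error_degenerate")
  }
  s2 <- s2[keep]
  df <- df[keep]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-statistics for a two-group comparison
#'
#' Computes per-probe log2 fold changes, pools the per-probe residual
#' variance toward an estimated scaled inverse-chi-square prior,
#' `s_post^2 = (d0 s0^2 + df s_g^2) / (d0 + df)`, and tests the fold change
#' with `t = logFC / (s_post * sqrt(1/n1 + 1/n2))` on `df + d0` degrees of
#' freedom. Gaining the prior degrees of freedom stabilises the statistic for
#' small group sizes, the regime of the biopsy series this models. Two-sided
#' p-values are adjusted by [bh_adjust()].
#'
#' @param dataset An [expression_dataset()].
#' @param d0,s0_sq Optional prior overrides. `d0 = 0` gives the ordinary
#'   pooled two-sample t; `d0 = Inf` fixes every posterior variance at
#'   `s0_sq`. When `NULL` both are estimated with [fit_variance_prior()].
#'
#' @return An object of class `de_fit`. Use [tidy()] for the per-probe table
#'   (`probe_id`, `gene_symbol`, `logFC`, `t`, `df_total`, `p`, `adj_p`) and
#'   [glance()] for the fitted prior.
#' @export
moderated_t <- function(dataset, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  be <- dataset$groups$sample[dataset$groups$group == "BE"]
  nrm <- dataset$groups$sample[dataset$groups$group == "normal"]
  n1 <- length(nrm); n2 <- length(be)
  if (n1 < 2 || n2 < 2) {
    abort("at least 2 samples per group are required",
          class = "beconcord_error_grouping")
  }
  x1 <- dataset$values[, nrm, drop = FALSE]
  x2 <- dataset$values[, be, drop = FALSE]
  lfc <- unname(rowMeans(x2) - rowMeans(x1))
  df_resid <- n1 + n2 - 2
  s2 <- unname(rowSums((x1 - rowMeans(x1))^2) +
                 rowSums((x2 - rowMeans(x2))^2)) / df_resid
  if (all(s2 == 0)) {
    abort("all probe variances are zero", class = "beconcord_error_degenerate")
  }

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df_resid)
  } else {
    .assert_scalar_number(d0, "d0", lower = 0, allow_inf = TRUE)
    if (is.null(s0_sq)) {
      s0_sq <- if (d0 == 0) NA_real_ else fit_variance_prior(s2, df_resid)$s0_sq
    }
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }

  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
  } else if (prior$d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + df_resid * s2) / (prior$d0 + df_resid)
  }
  se_unscaled <- sqrt(1 / n1 + 1 / n2)
  tstat <- lfc / (sqrt(s2_post) * se_unscaled)
  df_total <- df_resid + prior$d0
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = df_total)
  }

  structure(
    list(
      table = tibble(
        probe_id = dataset$probe_ids,
        gene_symbol = dataset$gene_symbols,
        logFC = lfc,
        t = tstat,
        df_total = df_total,
        p = p,
        adj_p = bh_adjust(p)
      ),
      prior = prior,
      n_samples = c(normal = n1, BE = n2)
    ),
    class = "de_fit"
  )
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf(
    "<de_fit> %d probes; prior d0 = %.3g, s0_sq = %.4g; n = %d normal vs %d BE\n",
    nrow(x$table), x$prior$d0, x$prior$s0_sq,
    x$n_samples[["normal"]], x$n_samples[["BE"]]
  ))
  print(x$table, n = 6)
  invisible(x)
}

#' @rdname moderated_t
#' @param x,... A `de_fit` and unused arguments, for the tidiers.
#' @export
tidy.de_fit <- function(x, ...) x$table

#' @rdname moderated_t
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    d0 = x$prior$d0, s0_sq = x$prior$s0_sq,
    n_probes = nrow(x$table),
    n_normal = x$n_samples[["normal"]], n_be = x$n_samples[["BE"]]
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `adj_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in
#' the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "beconcord_error_domain")
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0) return(out)
  ord <- ok[order(p[ok], decreasing = TRUE)]
  adj <- cummin(p[ord] * n / seq(n, 1))
  out[ord] <- pmin(adj, 1)
  out
}

#' Select panel genes from multi-dataset differential-expression evidence
#'
#' Applies the panel-selection rule: a gene is selected as upregulated
#' (downregulated) when it is present in every dataset (if
#' `require_all_datasets`) and at least `min_significant_datasets` datasets
#' show `adj_p < alpha` together with `logFC` above `lfc_threshold` (below
#' `-lfc_threshold`). Genes with qualifying datasets of opposite sign are
#' flagged `conflict`; everything else is `excluded`. With multiple probes
#' per gene and dataset, a dataset qualifies if any of its probes does.
#'
#' @param evidence Tibble with columns `gene`, `dataset`, `logFC`, `adj_p`,
#'   and logical `present`; one row per (gene, probe, dataset). An optional
#'   `class` column (e.g. squamous/columnar) is carried through.
#' @param lfc_threshold Absolute log2-fold-change cutoff (strict; default 2).
#' @param alpha Adjusted-p cutoff (strict; default 0.05).
#' @param min_significant_datasets Qualifying datasets needed (default 1).
#' @param require_all_datasets Drop genes missing from any dataset
#'   (default `TRUE`).
#'
#' @return A tibble of `gene` (and `class` when supplied), `decision` in
#'   `selected_up`/`selected_down`/`conflict`/`excluded`, `n_present`,
#'   `n_up`, `n_down`.
#' @export
select_genes <- function(evidence, lfc_threshold = 2, alpha = 0.05,
                         min_significant_datasets = 1,
                         require_all_datasets = TRUE) {
  .assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  evidence <- as_tibble(evidence)
  if (nrow(evidence) == 0) {
    return(tibble(gene = character(), decision = character(),
                  n_present = integer(), n_up = integer(),
                  n_down = integer()))
  }
  req <- c("gene", "dataset", "logFC", "adj_p", "present")
  missing_cols <- setdiff(req, names(evidence))
  if (length(missing_cols)) {
    abort(paste0("evidence lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  n_datasets <- dplyr::n_distinct(evidence$dataset)
  has_class <- "class" %in% names(evidence)

  per_ds <- evidence |>
    group_by(.data$gene, .data$dataset) |>
    summarise(
      present = any(.data$present),
      up = any(.data$present & !is.na(.data$adj_p) & !is.na(.data$logFC) &
                 .data$adj_p < alpha & .data$logFC > lfc_threshold),
      down = any(.data$present & !is.na(.data$adj_p) & !is.na(.data$logFC) &
                   .data$adj_p < alpha & .data$logFC < -lfc_threshold),
      .groups = "drop"
    )

  out <- per_ds |>
    group_by(.data$gene) |>
    summarise(
      n_present = sum(.data$present),
      n_up = sum(.data$up),
      n_down = sum(.data$down),
      .groups = "drop"
    ) |>
    mutate(
      eligible = !require_all_datasets | .data$n_present == n_datasets,
      decision = dplyr::case_when(
        !eligible ~ "excluded",
        n_up >= min_significant_datasets &
          n_down >= min_significant_datasets ~ "conflict",
        n_up >= min_significant_datasets ~ "selected_up",
        n_down >= min_significant_datasets ~ "selected_down",
        .default = "excluded"
      )
    ) |>
    select("gene", "decision", "n_present", "n_up", "n_down")

  if (has_class) {
    out <- evidence |>
      distinct(.data$gene, .data$class) |>
      distinct(.data$gene, .keep_all = TRUE) |>
      inner_join(out, by = "gene")
  }
  # preserve the input gene order
  out <- out[match(unique(evidence$gene), out$gene), ]
  if (!any(out$decision %in% c("selected_up", "selected_down"))) {
    warn("no genes were selected under the given criteria")
  }
  out
}

#' Volcano plot of a moderated-t fit
#'
#' @param object A `de_fit`.
#' @param lfc_threshold,alpha Reference lines for the selection thresholds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_fit <- function(object, lfc_threshold = 2, alpha = 0.05, ...) {
  d <- tidy(object) |>
    mutate(hit = .data$adj_p < alpha & abs(.data$logFC) > lfc_threshold)
  ggplot2::ggplot(d, ggplot2::aes(.data$logFC, -log10(.data$p),
                                  colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (BE vs normal)",
                  y = expression(-log[10] * " p")) +
    ggplot2::theme_minimal()
}
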