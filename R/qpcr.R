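#' Average technical replicates of a Ct table
#'
#' Collapses replicate wells to one mean Ct per (sample, gene). A (sample,
#' gene) is flagged undetected when a majority of its replicates are missing
#' (half missing is not a majority: {30.0, missing} is still detected);
#' undetected combinations carry a missing mean.
#'
#' @param ct Tibble with columns `sample_id`, `condition`, `gene`,
#'   `replicate`, `ct` (missing Ct as `NA`).
#' @return A tibble of `sample_id`, `condition`, `gene`, `ct_mean`,
#'   `n_detected`, `n_replicates`, `detected`.
#' @export
aggregate_replicates <- function(ct) {
  ct <- .validate_ct(ct)
  ct |>
    group_by(.data$sample_id, .data$condition, .data$gene) |>
    summarise(
      n_detected = sum(!is.na(.data$ct)),
      n_replicates = dplyr::n(),
      detected = .data$n_detected * 2 >= .data$n_replicates &
        .data$n_detected > 0,
      ct_mean = dplyr::if_else(.data$detected,
                               mean(.data$ct, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    select("sample_id", "condition", "gene", "ct_mean",
           "n_detected", "n_replicates", "detected")
}

.validate_ct <- function(ct) {
  ct <- as_tibble(ct)
  req <- c("sample_id", "condition", "gene", "replicate", "ct")
  missing_cols <- setdiff(req, names(ct))
  if (length(missing_cols)) {
    abort(paste0("Ct table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  if (any(!is.na(ct$ct) & ct$ct <= 0)) {
    abort("Ct values must be positive cycles",
          class = "beconcord_error_domain")
  }
  if (anyDuplicated(ct[, c("sample_id", "gene", "replicate")])) {
    abort("(sample_id, gene, replicate) must be unique",
          class = "beconcord_error_parse")
  }
  ct
}

#' Relative quantification by the 2^-ddCt method with dual reference genes
#'
#' Per sample, dCt is the mean target Ct minus the arithmetic mean of the two
#' reference-gene mean Cts (equivalent to normalising by the geometric mean
#' of the reference quantities on the linear scale). ddCt for a condition is
#' its mean dCt minus the mean dCt of the reference condition, and the
#' relative quantity is `rq = 2^-ddCt`, so the reference condition has
#' `rq = 1` by construction. Group significance is assessed on the per-sample
#' dCt values with [compare_groups()].
#'
#' @param ct Replicate-level Ct tibble (see [aggregate_replicates()]).
#' @param reference_genes Character vector of the two reference genes.
#' @param ref_condition The control condition fold changes are relative to.
#' @param targets Genes to quantify; defaults to all non-reference genes.
#' @param test Whether to attach group-comparison p-values (needs >= 2
#'   samples per condition).
#'
#' @return A tibble of class `quant_result`: `gene`, `condition`,
#'   `n_samples`, `delta_ct` (condition mean), `delta_delta_ct`, `rq`, `p`,
#'   `detected`. A gene undetected in every sample of a condition has
#'   `detected = FALSE` and missing `rq`.
#' @export
delta_delta_ct <- function(ct, reference_genes = c("ACTB", "GAPDH"),
                           ref_condition, targets = NULL, test = TRUE) {
  agg <- aggregate_replicates(ct)
  if (!ref_condition %in% agg$condition) {
    abort(sprintf("reference condition '%s' absent from the Ct table",
                  ref_condition),
          class = "beconcord_error_config")
  }
  missing_refs <- setdiff(reference_genes, agg$gene)
  if (length(missing_refs)) {
    abort(paste0("reference gene(s) not in the Ct table: ",
                 paste(missing_refs, collapse = ", ")),
          class = "beconcord_error_reference")
  }

  refs <- agg |>
    filter(.data$gene %in% reference_genes)
  if (any(!refs$detected)) {
    bad <- unique(refs$sample_id[!refs$detected])
    abort(paste0("reference gene undetected in sample(s): ",
                 paste(bad, collapse = ", ")),
          class = "beconcord_error_reference")
  }
  ref_ct <- refs |>
    group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$ct_mean), .groups = "drop")

  targets <- targets %||% setdiff(unique(agg$gene), reference_genes)
  per_sample <- agg |>
    filter(.data$gene %in% targets) |>
    left_join(ref_ct, by = "sample_id") |>
    mutate(delta_ct = .data$ct_mean - .data$ref_ct)

  per_cond <- per_sample |>
    group_by(.data$gene, .data$condition) |>
    summarise(
      n_samples = dplyr::n(),
      detected = any(.data$detected),
      delta_ct = dplyr::if_else(.data$detected,
                                mean(.data$delta_ct, na.rm = TRUE),
                                NA_real_),
      .groups = "drop"
    )

  ref_dct <- per_cond |>
    filter(.data$condition == ref_condition) |>
    select("gene", ref_delta_ct = "delta_ct")

  out <- per_cond |>
    left_join(ref_dct, by = "gene") |>
    mutate(
      delta_delta_ct = .data$delta_ct - .data$ref_delta_ct,
      rq = 2^-.data$delta_delta_ct
    ) |>
    select("gene", "condition", "n_samples", "delta_ct",
           "delta_delta_ct", "rq", "detected")

  if (test) {
    pvals <- per_sample |>
      filter(.data$detected) |>
      tidyr::nest(.by = "gene") |>
      mutate(p = purrr::map(.data$data, function(d) {
        conds <- unique(d$condition)
        if (!ref_condition %in% conds || length(conds) < 2) {
          return(tibble(condition = character(), p = numeric()))
        }
        tryCatch(
          compare_groups(d, ref_condition = ref_condition) |>
            select("condition", "p"),
          beconcord_error_replication = function(e) {
            tibble(condition = character(), p = numeric())
          }
        )
      })) |>
      select("gene", "p") |>
      tidyr::unnest("p")
    out <- out |> left_join(pvals, by = c("gene", "condition"))
  } else {
    out$p <- NA_real_
  }

  out <- out |>
    dplyr::relocate("p", .before = "detected") |>
    arrange(match(.data$gene, targets), match(.data$condition,
                                              unique(agg$condition)))
  class(out) <- c("quant_result", class(out))
  out
}

#' Compare condition dCt values against a reference condition
#'
#' With exactly two conditions a two-sided Student t-test (pooled variance)
#' is used; with more, a one-way ANOVA is fitted and each condition is
#' compared to the reference with Dunnett's many-to-one procedure, returning
#' adjusted p-values.
#'
#' @param dct Tibble with one row per sample: columns `condition` and
#'   `delta_ct` (extra columns ignored).
#' @param ref_condition The control condition.
#' @return A tibble of `condition`, `estimate` (mean dCt difference vs
#'   control), `statistic`, `df`, `p` for every non-reference condition.
#' @export
compare_groups <- function(dct, ref_condition) {
  dct <- as_tibble(dct) |>
    filter(!is.na(.data$delta_ct))
  if (!ref_condition %in% dct$condition) {
    abort(sprintf("reference condition '%s' absent", ref_condition),
          class = "beconcord_error_config")
  }
  sizes <- table(dct$condition)
  if (any(sizes < 2)) {
    abort(paste0("condition(s) with fewer than 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "beconcord_error_replication")
  }
  conds <- setdiff(unique(dct$condition), ref_condition)
  x0 <- dct$delta_ct[dct$condition == ref_condition]

  if (length(conds) == 1) {
    x1 <- dct$delta_ct[dct$condition == conds]
    n0 <- length(x0); n1 <- length(x1)
    df <- n0 + n1 - 2
    sp2 <- ((n0 - 1) * var(x0) + (n1 - 1) * var(x1)) / df
    est <- mean(x1) - mean(x0)
    if (sp2 == 0) {
      tstat <- ifelse(est == 0, 0, sign(est) * Inf)
      p <- ifelse(est == 0, 1, 0)
    } else {
      tstat <- est / sqrt(sp2 * (1 / n0 + 1 / n1))
      p <- 2 * pt(-abs(tstat), df)
    }
    return(tibble(condition = conds, estimate = est, statistic = tstat,
                  df = df, p = p))
  }

  dunnett_test(dct$delta_ct, dct$condition, ref = ref_condition)
}

#' Dunnett many-to-one comparisons
#'
#' Compares each treatment group mean to the control using the pooled ANOVA
#' error variance, adjusting two-sided p-values over the family with the
#' joint distribution of the comparison statistics: an equicorrelated
#' (rho = 1/2) multivariate t for balanced designs, evaluated with
#' `mvtnorm::pmvt`; unbalanced designs use a fixed-seed Monte-Carlo
#' evaluation of the exact correlation structure (`mc_draws` draws, adjusted
#' p accurate to about 0.003 at 1e5 draws).
#'
#' @param values Numeric response (here, per-sample dCt).
#' @param groups Group labels, same length as `values`.
#' @param ref Control group label.
#' @param mc_draws Draws for the unbalanced-design Monte-Carlo evaluation.
#' @return A tibble of `condition`, `estimate`, `statistic`, `df`, `p`
#'   (adjusted), one row per non-control group.
#' @export
dunnett_test <- function(values, groups, ref, mc_draws = 1e5) {
  groups <- as.character(groups)
  if (!ref %in% groups) {
    abort("control group absent", class = "beconcord_error_config")
  }
  treat <- setdiff(unique(groups), ref)
  k <- length(treat)
  ns <- table(groups)
  if (any(ns < 2)) {
    abort("each group needs at least 2 observations",
          class = "beconcord_error_replication")
  }
  means <- tapply(values, groups, mean)
  df <- length(values) - (k + 1)
  s2 <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2))) / df
  n0 <- ns[[ref]]
  ni <- as.numeric(ns[treat])
  est <- as.numeric(means[treat] - means[[ref]])
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- est / se

  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  balanced <- length(unique(ni)) == 1

  p_adj <- vapply(abs(tstat), function(tq) {
    if (!is.finite(tq)) return(0)
    if (balanced) {
      # quasi-MC integration; seed pinned for reproducibility
      pr <- withr::with_seed(1L, mvtnorm::pmvt(
        lower = rep(-tq, k), upper = rep(tq, k), df = df, corr = R,
        algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 1e6)
      ))
      max(0, 1 - as.numeric(pr))
    } else {
      withr::with_seed(1L, {
        z <- mvtnorm::rmvnorm(mc_draws, sigma = R)
        w <- sqrt(rchisq(mc_draws, df) / df)
        mean(apply(abs(z / w), 1, max) >= tq)
      })
    }
  }, numeric(1))

  tibble(condition = treat, estimate = est, statistic = tstat,
         df = df, p = p_adj)
}

#' Convert relative quantities into direction calls
#'
#' A gene/condition is called `up` when `rq >= fold_threshold` with
#' `p < alpha`, `down` when `rq <= 1/fold_threshold` with `p < alpha`
#' (the fold boundary is inclusive: "at least" a two-fold change counts),
#' `na` when the target never amplified (`detected = FALSE`), and
#' `no_change` otherwise. Both the fold and the significance criterion must
#' hold for a biologically relevant call.
#'
#' @param quant A [delta_delta_ct()] result (or any tibble with `gene`,
#'   `condition`, `rq`, `p`, `detected`).
#' @param fold_threshold Linear fold-change cutoff (default 2).
#' @param alpha Significance cutoff on the group-comparison p (default 0.05).
#' @param system Optional system label attached to the calls (e.g.
#'   `"epc2"`), for assembly into a cross-system profile.
#' @param conditions Optional subset of conditions to call.
#' @return A tibble of `gene`, `condition`, `status` (and `system` when
#'   given), with `status` in up/down/no_change/na.
#' @export
call_direction <- function(quant, fold_threshold = 2, alpha = 0.05,
                           system = NULL, conditions = NULL) {
  .assert_scalar_number(fold_threshold, "fold_threshold", lower = 1)
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  quant <- as_tibble(quant)
  if (!is.null(conditions)) {
    quant <- quant |> filter(.data$condition %in% conditions)
  }
  out <- quant |>
    mutate(
      status = dplyr::case_when(
        !detected ~ "na",
        !is.na(p) & p < alpha & !is.na(rq) & rq >= fold_threshold ~ "up",
        !is.na(p) & p < alpha & !is.na(rq) & rq <= 1 / fold_threshold ~ "down",
        .default = "no_change"
      )
    ) |>
    select("gene", "condition", "status")
  if (!is.null(system)) out <- out |> mutate(system = system)
  out
}
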