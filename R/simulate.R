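#' Specify a two-group expression simulation
#'
#' Describes a synthetic two-group (normal vs Barrett's-metaplasia) log2
#' expression experiment. Gene-wise true variances are drawn from a scaled
#' inverse-chi-square distribution, `s0_sq * d0 / chisq(d0)`, the hierarchical
#' model under which variance moderation of the t-statistic is exact, so
#' downstream hyperparameter estimates can be checked against the truth.
#'
#' @param n_genes Number of genes (one probe per gene).
#' @param n_per_group Samples per group; at least 2 so each gene has residual
#'   degrees of freedom.
#' @param true_logfc Per-gene log2 effect size (BE minus normal), recycled to
#'   `n_genes`. Zero means a null gene.
#' @param d0 Prior degrees of freedom of the gene-variance distribution.
#' @param s0_sq Prior variance scale (log2 units squared).
#' @param baseline Mean log2 expression of the normal group.
#' @param seed Integer seed; identical specs and seeds give identical data.
#'
#' @return An object of class `expression_sim_spec`.
#' @seealso [simulate_expression()]
#' @export
expression_sim_spec <- function(n_genes, n_per_group, true_logfc = 0,
                                d0 = 4, s0_sq = 0.05, baseline = 8,
                                seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", lower = 1)
  .assert_scalar_number(n_per_group, "n_per_group", lower = 2)
  .assert_scalar_number(d0, "d0", lower = .Machine$double.eps)
  .assert_scalar_number(s0_sq, "s0_sq", lower = .Machine$double.eps)
  .assert_scalar_number(seed, "seed")
  if (!length(true_logfc) %in% c(1L, n_genes)) {
    abort("`true_logfc` must have length 1 or `n_genes`",
          class = "beconcord_error_dimension")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_per_group = as.integer(n_per_group),
      true_logfc = rep_len(as.numeric(true_logfc), n_genes),
      d0 = d0, s0_sq = s0_sq, baseline = baseline,
      seed = as.integer(seed)
    ),
    class = "expression_sim_spec"
  )
}

#' Simulate a two-group log2 expression dataset with known truth
#'
#' Draws gene-wise variances from the scaled inverse-chi-square prior of the
#' spec and per-sample log2 values from a Normal around the group mean; BE and
#' normal group means differ by the true log2 fold change. All randomness is
#' confined to the call via the spec seed.
#'
#' @param spec An [expression_sim_spec()].
#'
#' @return A list of class `expression_sim` with elements
#'   * `dataset`: an [expression_dataset()] (probe-by-sample log2 matrix plus
#'     sample-to-group annotation),
#'   * `truth`: tibble of `probe_id`, `gene_symbol`, `true_logfc`, `true_var`.
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "expression_sim_spec")) {
    abort("`spec` must be an expression_sim_spec",
          class = "beconcord_error_dimension")
  }
  ng <- spec$n_genes
  n <- spec$n_per_group
  probe_ids <- sprintf("probe_%04d", seq_len(ng))
  gene_symbols <- sprintf("gene_%04d", seq_len(ng))
  samples <- c(sprintf("normal_%02d", seq_len(n)),
               sprintf("be_%02d", seq_len(n)))
  groups <- c(rep("normal", n), rep("BE", n))

  out <- withr::with_seed(spec$seed, {
    true_var <- spec$s0_sq * spec$d0 / rchisq(ng, df = spec$d0)
    mu <- cbind(
      matrix(spec$baseline, ng, n),
      matrix(spec$baseline + spec$true_logfc, ng, n)
    )
    values <- mu + matrix(rnorm(ng * 2 * n, sd = sqrt(true_var)), ng, 2 * n)
    list(true_var = true_var, values = values)
  })
  dimnames(out$values) <- list(probe_ids, samples)

  structure(
    list(
      dataset = expression_dataset(out$values, groups = groups,
                                   gene_symbols = gene_symbols),
      truth = tibble(
        probe_id = probe_ids, gene_symbol = gene_symbols,
        true_logfc = spec$true_logfc, true_var = out$true_var
      )
    ),
    class = "expression_sim"
  )
}

#' Specify a qPCR Ct-table simulation
#'
#' Describes a synthetic qPCR experiment: replicate threshold-cycle (Ct)
#' values generated from true linear fold changes with Gaussian replicate
#' noise, two stable reference genes, and optional genes that never amplify
#' (all replicates missing).
#'
#' @param genes Character vector of assayed gene labels (reference genes are
#'   added automatically if absent).
#' @param conditions Character vector of condition labels, including the
#'   reference condition.
#' @param ref_condition The untreated/control condition all fold changes are
#'   relative to.
#' @param true_fold Tibble with columns `gene`, `condition`, `fold` giving the
#'   true linear fold change vs `ref_condition`; omitted pairs default to 1.
#'   Reference genes must have fold 1 everywhere (enforced).
#' @param reference_genes Two stable reference genes (default ACTB and GAPDH).
#' @param base_ct Named numeric of per-gene baseline Ct in cycles, or a single
#'   value for all genes (default 25; references at 18 and 20 unless named).
#' @param noise_sd Replicate Ct standard deviation in cycles (>= 0).
#' @param n_replicates Technical replicate wells per (sample, gene).
#' @param n_samples Biological samples per condition.
#' @param na_genes Genes that never amplify: every Ct is missing.
#' @param seed Integer seed.
#'
#' @return An object of class `ct_sim_spec`.
#' @seealso [simulate_ct()]
#' @export
ct_sim_spec <- function(genes, conditions, ref_condition,
                        true_fold = NULL,
                        reference_genes = c("ACTB", "GAPDH"),
                        base_ct = 25, noise_sd = 0.15,
                        n_replicates = 3L, n_samples = 5L,
                        na_genes = character(), seed = 1L) {
  .assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  .assert_scalar_number(n_replicates, "n_replicates", lower = 2)
  .assert_scalar_number(n_samples, "n_samples", lower = 1)
  .assert_scalar_number(seed, "seed")
  if (length(reference_genes) != 2) {
    abort("exactly two reference genes are required",
          class = "beconcord_error_config")
  }
  if (!ref_condition %in% conditions) {
    abort(sprintf("reference condition '%s' is not among the conditions",
                  ref_condition),
          class = "beconcord_error_config")
  }
  genes <- union(genes, reference_genes)

  fold <- tidyr::expand_grid(gene = genes, condition = conditions)
  fold$fold <- 1
  if (!is.null(true_fold)) {
    true_fold <- as_tibble(true_fold)
    if (!all(c("gene", "condition", "fold") %in% names(true_fold))) {
      abort("`true_fold` needs columns gene, condition, fold",
            class = "beconcord_error_config")
    }
    if (any(!is.na(true_fold$fold) & true_fold$fold <= 0)) {
      abort("true fold changes must be positive",
            class = "beconcord_error_domain")
    }
    if (any(true_fold$gene %in% reference_genes & true_fold$fold != 1)) {
      abort("reference genes must have true fold 1 in every condition",
            class = "beconcord_error_config")
    }
    fold <- fold |>
      left_join(true_fold, by = c("gene", "condition"),
                suffix = c("", ".user")) |>
      mutate(fold = dplyr::coalesce(.data$fold.user, .data$fold)) |>
      select(-"fold.user")
  }
  fold$fold[fold$condition == ref_condition] <- 1

  if (length(base_ct) == 1 && is.null(names(base_ct))) {
    bc <- setNames(rep(base_ct, length(genes)), genes)
    # give the two references distinct, realistic baselines
    bc[reference_genes] <- c(18, 20)
  } else {
    bc <- setNames(rep(25, length(genes)), genes)
    bc[names(base_ct)] <- base_ct
  }

  structure(
    list(
      genes = genes, conditions = conditions, ref_condition = ref_condition,
      true_fold = fold, reference_genes = reference_genes, base_ct = bc,
      noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
      n_samples = as.integer(n_samples), na_genes = na_genes,
      seed = as.integer(seed)
    ),
    class = "ct_sim_spec"
  )
}

#' Simulate a replicate-level qPCR Ct table with known truth
#'
#' For a non-reference gene g in condition c, each replicate Ct is drawn from
#' Normal(base_ct(g) - log2(true_fold(g, c)), noise_sd): a doubling of
#' template shifts Ct down by one cycle. Reference genes use fold 1; genes in
#' `na_genes` emit missing Ct in every replicate.
#'
#' @param spec A [ct_sim_spec()].
#'
#' @return A list of class `ct_sim` with elements
#'   * `ct`: tibble of `sample_id`, `condition`, `gene`, `replicate`, `ct`,
#'   * `truth`: tibble of `gene`, `condition`, `fold`.
#' @export
simulate_ct <- function(spec) {
  if (!inherits(spec, "ct_sim_spec")) {
    abort("`spec` must be a ct_sim_spec", class = "beconcord_error_config")
  }
  grid <- tidyr::expand_grid(
    condition = spec$conditions,
    sample = seq_len(spec$n_samples),
    gene = spec$genes,
    replicate = seq_len(spec$n_replicates)
  ) |>
    mutate(sample_id = paste(.data$condition, .data$sample, sep = "_")) |>
    left_join(spec$true_fold, by = c("gene", "condition"))

  mu <- unname(spec$base_ct[grid$gene]) - log2(grid$fold)
  ct <- withr::with_seed(
    spec$seed,
    mu + rnorm(nrow(grid), sd = spec$noise_sd)
  )
  ct[grid$gene %in% spec$na_genes] <- NA_real_

  structure(
    list(
      ct = grid |>
        mutate(ct = ct) |>
        select("sample_id", "condition", "gene", "replicate", "ct"),
      truth = spec$true_fold
    ),
    class = "ct_sim"
  )
}
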