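# Small builders shared across test files.

# A tiny two-condition Ct table with known folds and optional noise.
make_ct_sim <- function(folds = c(KRT4 = 0.25, KRT8 = 4, TFF3 = 1),
                        noise_sd = 0, n_samples = 5, n_replicates = 3,
                        na_genes = character(), seed = 1) {
  simulate_ct(ct_sim_spec(
    genes = names(folds),
    conditions = c("control", "treated"),
    ref_condition = "control",
    true_fold = data.frame(gene = names(folds), condition = "treated",
                           fold = unname(folds)),
    noise_sd = noise_sd, n_samples = n_samples,
    n_replicates = n_replicates, na_genes = na_genes, seed = seed
  ))
}

# An expression dataset built directly from a matrix.
make_dataset <- function(values, n_per_group = ncol(values) / 2) {
  colnames(values) <- c(sprintf("n%d", seq_len(n_per_group)),
                        sprintf("b%d", seq_len(ncol(values) - n_per_group)))
  rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  expression_dataset(values, groups = rep(c("normal", "BE"),
                                          c(n_per_group,
                                            ncol(values) - n_per_group)))
}

# Brute-force BH oracle: direct min-over-suffix of p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Classical pooled two-sample t for one probe row.
pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
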