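test_that("replicate aggregation applies the majority-missing rule", {
  ct <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    condition = "control",
    gene = "KRT8",
    replicate = c(1, 2, 1, 2, 3, 1, 2),
    ct = c(24.1, 24.3, NA, NA, NA, 30.0, NA)
  )
  agg <- aggregate_replicates(ct)
  s1 <- agg[agg$sample_id == "s1", ]
  expect_equal(s1$ct_mean, 24.2)
  expect_true(s1$detected)
  s2 <- agg[agg$sample_id == "s2", ]
  expect_false(s2$detected)
  expect_true(is.na(s2$ct_mean))
  # half missing is not a majority
  s3 <- agg[agg$sample_id == "s3", ]
  expect_true(s3$detected)
  expect_equal(s3$ct_mean, 30.0)
})

test_that("2^-ddCt matches the hand-computed example", {
  # control: target 25, refs (20, 22); treated: target 23, same refs
  ct <- tidyr::expand_grid(
    condition = c("control", "treated"),
    sample = 1:2, replicate = 1:2,
    gene = c("T", "ACTB", "GAPDH")
  ) |>
    dplyr::mutate(
      sample_id = paste(condition, sample, sep = "_"),
      ct = dplyr::case_when(
        gene == "ACTB" ~ 20, gene == "GAPDH" ~ 22,
        condition == "control" ~ 25, .default = 23
      )
    )
  q <- delta_delta_ct(ct, ref_condition = "control")
  trt <- q[q$condition == "treated", ]
  expect_equal(trt$delta_ct, 2)
  expect_equal(q$delta_ct[q$condition == "control"], 4)
  expect_equal(trt$delta_delta_ct, -2)
  expect_equal(trt$rq, 4)
  expect_equal(q$rq[q$condition == "control"], 1)  # reference condition
})

test_that("rq is invariant to a per-sample Ct shift", {
  sim <- make_ct_sim(noise_sd = 0.1, seed = 9)
  q1 <- delta_delta_ct(sim$ct, ref_condition = "control")
  shifted <- sim$ct |>
    dplyr::mutate(ct = ct + ifelse(sample_id == "treated_2", 3.0, 0))
  q2 <- delta_delta_ct(shifted, ref_condition = "control")
  expect_equal(q1$rq, q2$rq)
  expect_equal(q1$p, q2$p)
})

test_that("noiseless simulations recover rq = true_fold exactly", {
  sim <- make_ct_sim(folds = c(A = 4, B = 1, C = 0.25), noise_sd = 0)
  q <- delta_delta_ct(sim$ct, ref_condition = "control") |>
    dplyr::inner_join(sim$truth, by = c("gene", "condition"))
  expect_equal(q$rq, q$fold)
  expect_equal(q$delta_delta_ct, -log2(q$fold))
})

test_that("undetected targets and reference failures follow the contracts", {
  sim <- make_ct_sim(folds = c(A = 4, B = 1), noise_sd = 0.05,
                     na_genes = "B", seed = 4)
  q <- delta_delta_ct(sim$ct, ref_condition = "control")
  expect_true(all(!q$detected[q$gene == "B"]))
  expect_true(all(is.na(q$rq[q$gene == "B"])))

  broken <- sim$ct |>
    dplyr::mutate(ct = ifelse(gene == "GAPDH" & sample_id == "control_1",
                              NA, ct))
  expect_error(delta_delta_ct(broken, ref_condition = "control"),
               class = "beconcord_error_reference")
  expect_error(delta_delta_ct(sim$ct, ref_condition = "nope"),
               class = "beconcord_error_config")
})

test_that("two identical groups give t = 0, p = 1", {
  dct <- tibble::tibble(condition = rep(c("control", "treated"), each = 3),
                        delta_ct = rep(2.5, 6))
  res <- compare_groups(dct, "control")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(
    compare_groups(tibble::tibble(condition = c("control", "control", "t"),
                                  delta_ct = 1:3), "control"),
    class = "beconcord_error_replication"
  )
})

test_that("Dunnett with one comparison reduces to the ordinary t-test", {
  set.seed(6)
  vals <- c(rnorm(5, 0), rnorm(5, 1))
  grp <- rep(c("control", "treated"), each = 5)
  d <- dunnett_test(vals, grp, ref = "control")
  tt <- t.test(vals[grp == "treated"], vals[grp == "control"],
               var.equal = TRUE)
  expect_equal(d$p, tt$p.value, tolerance = 1e-6)
  expect_equal(d$statistic, unname(tt$statistic), tolerance = 1e-10)
})

test_that("balanced k = 3 Dunnett p matches the Monte-Carlo oracle", {
  set.seed(123)
  n <- 5; k <- 3
  vals <- c(rnorm(n, 0, 1), rnorm(n, 0.8, 1), rnorm(n, -0.5, 1),
            rnorm(n, 1.5, 1))
  grp <- rep(c("control", "t1", "t2", "t3"), each = n)
  res <- dunnett_test(vals, grp, ref = "control")

  # oracle: 10^6 draws of the equicorrelated multivariate t
  df <- (k + 1) * (n - 1)
  R <- matrix(0.5, k, k); diag(R) <- 1
  set.seed(77)
  z <- mvtnorm::rmvnorm(1e6, sigma = R)
  w <- sqrt(rchisq(1e6, df) / df)
  tmax <- apply(abs(z / w), 1, max)
  for (i in seq_len(k)) {
    p_mc <- mean(tmax >= abs(res$statistic[i]))
    expect_lt(abs(res$p[i] - p_mc), 0.005)
  }
})

test_that("Dunnett agrees with an independent many-to-one implementation", {
  skip_if_not_installed("multcomp")
  set.seed(10)
  vals <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 0.3))
  grp <- factor(rep(c("control", "t1", "t2"), each = 6),
                levels = c("control", "t1", "t2"))
  mine <- dunnett_test(vals, as.character(grp), ref = "control")
  fit <- stats::aov(vals ~ grp)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  ref_p <- summary(gl)$test$pvalues
  expect_equal(mine$p, as.numeric(ref_p), tolerance = 2e-4)
})

test_that("unbalanced designs use the exact correlation structure", {
  set.seed(14)
  vals <- c(rnorm(8, 0), rnorm(4, 1), rnorm(6, 0.5))
  grp <- rep(c("control", "t1", "t2"), c(8, 4, 6))
  mine <- dunnett_test(vals, grp, ref = "control", mc_draws = 2e5)
  skip_if_not_installed("multcomp")
  fit <- stats::aov(vals ~ factor(grp, levels = c("control", "t1", "t2")))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(`factor(grp, levels = c("control", "t1", "t2"))` = "Dunnett"))
  expect_equal(mine$p, as.numeric(summary(gl)$test$pvalues), tolerance = 5e-3)
})

test_that("direction calls implement the two-fold + significance gate", {
  q <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    condition = "treated",
    rq = c(0.25, 1.9, 3.0, 2.0, NA),
    p = c(0.001, 0.0001, 0.2, 0.01, NA),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  calls <- call_direction(q)
  expect_equal(calls$status, c("down", "no_change", "no_change", "up", "na"))

  # noiseless end-to-end: folds {4, 1, 0.25} -> {up, no_change, down}
  sim <- make_ct_sim(folds = c(up = 4, flat = 1, dn = 0.25), noise_sd = 0)
  q2 <- delta_delta_ct(sim$ct, ref_condition = "control")
  calls2 <- call_direction(q2, conditions = "treated")
  expect_equal(calls2$status[match(c("up", "flat", "dn"), calls2$gene)],
               c("up", "no_change", "down"))
})

test_that("mean recovered rq is unbiased at realistic noise", {
  # the 200-seed acceptance-scale version lives in the acceptance suite
  rq <- sapply(1:30, function(s) {
    sim <- make_ct_sim(folds = c(g = 0.25), noise_sd = 0.15, seed = s)
    q <- delta_delta_ct(sim$ct, ref_condition = "control", test = FALSE)
    q$rq[q$condition == "treated"]
  })
  expect_equal(mean(rq), 0.25, tolerance = 0.1)
  expect_true(all(rq > 0.18 & rq < 0.34))
})
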