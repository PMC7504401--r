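test_that("profile assembly fills missing systems with nd", {
  panel <- tibble::tibble(gene = "KRT4", decision = "selected_down")
  calls <- tibble::tibble(gene = "KRT4", system = "epc2", status = "down")
  prof <- build_profile_table(panel, calls)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$human, "down")
  expect_equal(prof$epc2, "down")

  # named-list form, empty calls -> all nd
  prof2 <- build_profile_table(
    tibble::tibble(gene = c("KRT4", "KRT8"),
                   decision = c("selected_down", "selected_up")),
    list(epc2 = tibble::tibble(gene = "KRT4", status = "down"),
         rat = tibble::tibble(gene = character(), status = character()))
  )
  expect_equal(prof2$rat, c("nd", "nd"))
  expect_equal(prof2$epc2, c("down", "nd"))
})

test_that("profile assembly enforces integrity and warns on stray calls", {
  panel <- tibble::tibble(gene = c("KRT4", "KRT8"),
                          decision = c("selected_down", "selected_up"))
  expect_error(
    build_profile_table(panel, tibble::tibble(
      gene = c("KRT4", "KRT4"), system = "rat", status = c("up", "down")
    )),
    class = "beconcord_error_integrity"
  )
  expect_warning(
    build_profile_table(panel, tibble::tibble(
      gene = c("KRT4", "NOT_A_PANEL_GENE"), system = "rat", status = "down"
    )),
    "non-panel"
  )
  expect_error(
    build_profile_table(tibble::tibble(gene = "x", decision = "excluded"),
                        tibble::tibble(gene = "x", system = "rat",
                                       status = "up")),
    class = "beconcord_error_config"
  )
})

test_that("the bundled profile reproduces the published summary shape", {
  prof <- table5_profile()
  expect_equal(nrow(prof), 23)
  expect_equal(sum(prof$class == "squamous"), 10)
  expect_equal(sum(prof$class == "columnar"), 13)
  expect_true(all(prof$human %in% c("up", "down")))
  # arrow dialect maps onto the ASCII tokens
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tclass\thuman\trat",
               "KRT1\tsquamous\t↓\t↑",
               "KRT15\tsquamous\t↓\tn.a.",
               "KRT23\tsquamous\t↓\t↔"), tmp)
  arrows <- read_profile_table(tmp)
  expect_equal(arrows$rat, c("up", "na", "no_change"))
  expect_equal(arrows$human, rep("down", 3))
})

test_that("per-system concordance uses the nd-exclusion denominator", {
  prof <- table5_profile()
  rat <- concordance_fraction(prof, "rat")
  expect_equal(rat$matches, 10)
  expect_equal(rat$denominator, 22)  # KRT6 is nd in the rat
  expect_equal(rat$pct_nearest, 45)

  # identity: a system equal to the human column scores 1
  prof$clone <- prof$human
  expect_equal(concordance_fraction(prof, "clone")$fraction, 1)

  expect_error(concordance_fraction(prof, "mouse"),
               class = "beconcord_error_lookup")
})

test_that("concordance is invariant to row order and nd padding", {
  prof <- table5_profile()
  base <- concordance_fraction(prof, "epc2")
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(concordance_fraction(shuffled, "epc2")[-8], base[-8])
  padded <- dplyr::bind_rows(
    prof, tibble::tibble(gene = "FAKE1", class = "columnar", human = "up",
                         het1a = "up", epc2 = "nd", rat = "up")
  )
  pad <- concordance_fraction(padded, "epc2")
  expect_equal(pad$matches, base$matches)
  expect_equal(pad$denominator, base$denominator)
})

test_that("combined concordance is the union of per-system match sets", {
  prof <- table5_profile()
  comb <- combined_concordance(prof, c("het1a", "epc2"))
  union_set <- union(match_set(prof, "het1a"), match_set(prof, "epc2"))
  expect_equal(comb$matches, length(union_set))
  expect_setequal(comb$matched_genes[[1]], union_set)

  # union of one system equals the per-system report
  single <- combined_concordance(prof, "rat")
  per <- concordance_fraction(prof, "rat")
  expect_equal(single$matches, per$matches)
  expect_equal(single$denominator, per$denominator)

  # union dominance over every subset system
  for (s in c("het1a", "epc2")) {
    expect_gte(comb$fraction, concordance_fraction(prof, s)$fraction)
  }
  expect_error(combined_concordance(prof, character()),
               class = "beconcord_error_argument")

  # disjoint match sets add up
  toy <- tibble::tibble(
    gene = c("a", "b", "c", "d"), human = c("up", "up", "down", "down"),
    s1 = c("up", "no_change", "no_change", "no_change"),
    s2 = c("no_change", "up", "down", "no_change")
  )
  class(toy) <- c("profile_table", class(toy))
  expect_equal(combined_concordance(toy, c("s1", "s2"))$matches, 1 + 2)
})

test_that("venn partition counts match a brute-force membership tally", {
  expect_equal(
    venn_partition(list(A = c("x", "y"), B = "z"))$count,
    c(2, 1, 0)
  )
  expect_equal(venn_partition(list(A = character(), B = character()))$count,
               c(0, 0, 0))
  expect_error(venn_partition(list(a = "x")),
               class = "beconcord_error_arity")
  expect_error(venn_partition(list("x", "y")),
               class = "beconcord_error_argument")

  set.seed(19)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:25) {
    sets <- list(A = sample(pool, sample(0:20, 1)),
                 B = sample(pool, sample(0:20, 1)),
                 C = sample(pool, sample(0:20, 1)))
    parts <- venn_partition(sets)
    # brute force over all elements
    uni <- unique(unlist(sets))
    memb <- sapply(uni, function(e) paste(names(sets)[sapply(sets, `%in%`, x = e)],
                                          collapse = "&"))
    tally <- table(memb)
    for (j in seq_len(nrow(parts))) {
      expected <- if (parts$region[j] %in% names(tally)) {
        as.integer(tally[[parts$region[j]]])
      } else 0L
      expect_identical(parts$count[j], expected)
    }
    expect_equal(sum(parts$count), length(uni))
  }
})

test_that("simulated direction calls reproduce the published profile end to end", {
  prof_ref <- table5_profile()
  panel <- select_genes(table1_evidence())

  # build noiseless Ct experiments whose true folds force each published call
  systems <- c("het1a", "epc2", "rat")
  calls <- lapply(systems, function(sys) {
    status <- prof_ref[[sys]]
    assayed <- prof_ref$gene[status != "nd"]
    folds <- ifelse(status == "up", 4, ifelse(status == "down", 0.25, 1))
    sim <- simulate_ct(ct_sim_spec(
      genes = assayed, conditions = c("control", "treated"),
      ref_condition = "control",
      true_fold = data.frame(gene = assayed, condition = "treated",
                             fold = folds[status != "nd"]),
      noise_sd = 0, n_samples = 3,
      na_genes = prof_ref$gene[status == "na"], seed = 1
    ))
    q <- delta_delta_ct(sim$ct, ref_condition = "control")
    call_direction(q, system = sys, conditions = "treated")
  })
  prof_sim <- build_profile_table(panel, dplyr::bind_rows(calls))
  prof_sim <- prof_sim[match(prof_ref$gene, prof_sim$gene), ]
  for (sys in systems) {
    expect_equal(prof_sim[[sys]], prof_ref[[sys]], label = sys)
  }
  for (sys in systems) {
    expect_equal(concordance_fraction(prof_sim, sys)[, 2:7],
                 concordance_fraction(prof_ref, sys)[, 2:7])
  }
})

test_that("concordance and venn plots build without error", {
  prof <- table5_profile()
  reports <- dplyr::bind_rows(concordance_fraction(prof, "rat"),
                              concordance_fraction(prof, "epc2"))
  p1 <- plot_concordance(reports)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_venn(list(het1a = match_set(prof, "het1a"),
                       epc2 = match_set(prof, "epc2")))
  expect_s3_class(p2, "ggplot")
  p3 <- plot_venn(list(A = c("x", "y"), B = "y", C = c("y", "z")))
  expect_s3_class(p3, "ggplot")
})
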