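#' Assemble a pipeline configuration
#'
#' A flat key-value configuration tying the stages together: selection
#' thresholds, qPCR reference settings, rounding convention, seed, and
#' input/output paths. Configurations round-trip losslessly through their
#' YAML file form ([read_config()] / [write_config()]).
#'
#' @param evidence Path to a differential-expression evidence CSV
#'   ([read_evidence()] format), the input of the selection stage.
#' @param profile Optional path to a ready-made profile TSV; when given, the
#'   qPCR stage is skipped and calls are taken from the file.
#' @param ct_tables Named list, one entry per model system, each a list with
#'   `path` (Ct CSV) and `condition` (the treated condition to call).
#' @param combine Character vector of systems for the combined (union)
#'   concordance.
#' @param lfc_threshold,alpha Selection thresholds (see [select_genes()]).
#' @param fold_threshold,qpcr_alpha Direction-call thresholds (see
#'   [call_direction()]).
#' @param reference_genes,ref_condition qPCR normalisation settings.
#' @param rounding `"nearest"` or `"floor"` for per-system printed
#'   percentages (the combined figure is always also reported under both).
#' @param seed Integer seed recorded and used for any stochastic step.
#' @param out Output directory for the report bundle (`NULL`: nothing
#'   written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(evidence, profile = NULL, ct_tables = NULL,
                            combine = NULL,
                            lfc_threshold = 2, alpha = 0.05,
                            fold_threshold = 2, qpcr_alpha = 0.05,
                            reference_genes = c("ACTB", "GAPDH"),
                            ref_condition = "control",
                            rounding = "nearest", seed = 1L, out = NULL) {
  .assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  .assert_scalar_number(fold_threshold, "fold_threshold", lower = 1)
  .assert_scalar_number(qpcr_alpha, "qpcr_alpha", lower = 0, upper = 1)
  if (!rounding %in% c("nearest", "floor")) {
    abort("`rounding` must be 'nearest' or 'floor'",
          class = "beconcord_error_config")
  }
  structure(
    list(evidence = evidence, profile = profile, ct_tables = ct_tables,
         combine = combine, lfc_threshold = lfc_threshold, alpha = alpha,
         fold_threshold = fold_threshold, qpcr_alpha = qpcr_alpha,
         reference_genes = reference_genes, ref_condition = ref_condition,
         rounding = rounding, seed = as.integer(seed), out = out),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration file
#'
#' @param path Path to a YAML key-value file.
#' @return For `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(purrr::discard(unclass(config), is.null), path)
  invisible(config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
          class = "beconcord_error_stage", parent = e)
  })
}

#' Run the full concordance pipeline
#'
#' Executes, in order: panel selection from the evidence table, per-system
#' qPCR relative quantification and direction calling (or a direct profile
#' read), profile assembly, and per-system plus combined concordance
#' scoring. Stage-level record counts are logged via messages, and with
#' `config$out` set the resolved configuration, the profile, the reports and
#' a run log are written as TSV/JSON. Identical configurations and seeds
#' give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return A list of class `pipeline_result`: `panel`, `profile`, `reports`
#'   (stacked concordance rows), `combined`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))

  evidence <- .stage("read_evidence", read_evidence(config$evidence))
  say("selection: %d evidence rows in", nrow(evidence))
  panel <- .stage("select_genes", select_genes(
    evidence, lfc_threshold = config$lfc_threshold, alpha = config$alpha
  ))
  n_sel <- sum(panel$decision %in% c("selected_up", "selected_down"))
  say("selection: %d/%d genes selected", n_sel, nrow(panel))

  if (!is.null(config$profile)) {
    profile <- .stage("read_profile", read_profile_table(config$profile))
    say("profile: %d genes x %d systems (from file)",
        nrow(profile), length(.profile_systems(profile)))
  } else if (!is.null(config$ct_tables)) {
    calls <- .stage("qpcr", purrr::imap(config$ct_tables, function(conf, sys) {
      ct <- read_ct_table(conf$path)
      quant <- delta_delta_ct(ct,
                              reference_genes = config$reference_genes,
                              ref_condition = config$ref_condition)
      call_direction(quant,
                     fold_threshold = config$fold_threshold,
                     alpha = config$qpcr_alpha,
                     system = sys, conditions = conf$condition)
    }) |> bind_rows())
    say("qpcr: %d direction calls across %d systems",
        nrow(calls), length(config$ct_tables))
    profile <- .stage("build_profile", build_profile_table(panel, calls))
  } else {
    abort("config needs either `profile` or `ct_tables`",
          class = "beconcord_error_config")
  }

  systems <- .profile_systems(profile)
  reports <- .stage("concordance", purrr::map(
    systems, \(s) concordance_fraction(profile, s, rounding = config$rounding)
  ) |> bind_rows())
  combined <- NULL
  if (!is.null(config$combine)) {
    combined <- .stage("combined_concordance",
                       combined_concordance(profile, config$combine))
    reports <- bind_rows(reports, combined)
  }
  say("concordance: %s",
      paste(sprintf("%s %d/%d (%d%%)", reports$system, reports$matches,
                    reports$denominator, reports$pct_printed),
            collapse = "; "))

  result <- structure(
    list(panel = panel, profile = profile, reports = reports,
         combined = combined, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out)) .write_report_bundle(result, config$out)
  result
}

.write_report_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(result$profile, file.path(dir, "profile.tsv"))
  readr::write_tsv(result$panel, file.path(dir, "panel.tsv"))
  rep <- result$reports |>
    mutate(matched_genes = purrr::map_chr(.data$matched_genes,
                                          paste, collapse = ","))
  jsonlite::write_json(
    list(
      config = purrr::discard(unclass(result$config), is.null),
      versions = list(beconcord = as.character(utils::packageVersion("beconcord")),
                      r = paste(R.version$major, R.version$minor, sep = ".")),
      panel_size = sum(result$panel$decision %in%
                         c("selected_up", "selected_down")),
      reports = rep
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  panel: %d selected genes\n",
              sum(x$panel$decision %in% c("selected_up", "selected_down"))))
  cat(sprintf("  profile: %d genes x %d systems\n",
              nrow(x$profile), length(.profile_systems(x$profile))))
  for (i in seq_len(nrow(x$reports))) {
    cat(sprintf("  %s: %d/%d (%d%%)\n", x$reports$system[i],
                x$reports$matches[i], x$reports$denominator[i],
                x$reports$pct_printed[i]))
  }
  invisible(x)
}
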