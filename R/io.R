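#' Read an expression matrix and its sample annotation
#'
#' Expects a tab-delimited matrix whose first column is the probe ID and
#' second the gene symbol, followed by one column per sample, plus a
#' two-column tab-delimited annotation (`sample`, `group` with group in
#' normal/BE). Samples present in the annotation but absent from the matrix
#' (or vice versa) raise an error naming them.
#'
#' @param matrix_path Path to the expression TSV.
#' @param annotation_path Path to the sample-annotation TSV.
#' @param auto_log2 Passed to [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, annotation_path, auto_log2 = FALSE) {
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  if (ncol(mat) < 4 || names(mat)[1] != "probe_id" ||
      names(mat)[2] != "gene_symbol") {
    abort(paste0(matrix_path, ": line 1: header must start with ",
                 "'probe_id<TAB>gene_symbol' followed by sample columns"),
          class = "beconcord_error_parse")
  }
  dup <- which(duplicated(mat$probe_id))
  if (length(dup)) {
    abort(paste0(matrix_path, ": duplicated probe ID(s) at data line(s) ",
                 paste(dup, collapse = ", "), ": ",
                 paste(unique(mat$probe_id[dup]), collapse = ", ")),
          class = "beconcord_error_parse")
  }
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  if (!all(c("sample", "group") %in% names(ann))) {
    abort(paste0(annotation_path,
                 ": line 1: header must be 'sample<TAB>group'"),
          class = "beconcord_error_parse")
  }
  samples <- names(mat)[-(1:2)]
  extra_ann <- setdiff(ann$sample, samples)
  if (length(extra_ann)) {
    abort(paste0("annotated sample(s) absent from the matrix: ",
                 paste(extra_ann, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  missing_ann <- setdiff(samples, ann$sample)
  if (length(missing_ann)) {
    abort(paste0("matrix sample(s) missing from the annotation: ",
                 paste(missing_ann, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  bad_group <- which(!ann$group %in% c("normal", "BE"))
  if (length(bad_group)) {
    abort(paste0(annotation_path, ": line(s) ",
                 paste(bad_group + 1, collapse = ", "),
                 ": group label must be 'normal' or 'BE'"),
          class = "beconcord_error_parse")
  }
  values <- as.matrix(mat[, -(1:2)])
  rownames(values) <- mat$probe_id
  expression_dataset(values,
                     groups = setNames(ann$group, ann$sample),
                     gene_symbols = mat$gene_symbol,
                     auto_log2 = auto_log2)
}

#' Write an expression dataset to matrix + annotation TSV files
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,annotation_path Output paths.
#' @return The dataset, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  as_tibble(dataset$values, rownames = "probe_id") |>
    mutate(gene_symbol = dataset$gene_symbols, .after = "probe_id") |>
    readr::write_tsv(matrix_path)
  readr::write_tsv(dataset$groups, annotation_path)
  invisible(dataset)
}

#' Read a replicate-level Ct table
#'
#' Comma-separated with header `sample_id,condition,gene,replicate,ct`.
#' Empty `ct` fields and the export token `"Undetermined"` are read as
#' missing (no amplification in that well).
#'
#' @param path Path to the CSV.
#' @return A validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          condition = readr::col_character(),
                          gene = readr::col_character(),
                          replicate = readr::col_integer(),
                          ct = readr::col_character()
                        ))
  req <- c("sample_id", "condition", "gene", "replicate", "ct")
  if (!all(req %in% names(ct))) {
    abort(paste0(path, ": line 1: header must be '",
                 paste(req, collapse = ","), "'"),
          class = "beconcord_error_parse")
  }
  ct$ct <- suppressWarnings(
    dplyr::if_else(trimws(ct$ct) %in% c("", "Undetermined", "undetermined"),
                   NA_real_, as.numeric(ct$ct))
  )
  .validate_ct(ct)
}

#' Write a Ct table (missing Ct as empty fields)
#'
#' @param ct A Ct tibble.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  readr::write_csv(ct, path, na = "")
  invisible(ct)
}

#' Read a cross-system direction profile table
#'
#' Tab-delimited with columns `gene`, `class`, `human`, then one column per
#' model system. Direction cells may use the ASCII tokens
#' (up/down/no_change/na/nd) or the arrow/abbreviation dialect of published
#' summary tables (up/down/left-right arrows, "n.a.", "n.d."); blank cells
#' are read as `nd`.
#'
#' @param path Path to the TSV.
#' @return A `profile_table` tibble.
#' @export
read_profile_table <- function(path) {
  prof <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (!all(c("gene", "human") %in% names(prof))) {
    abort(paste0(path, ": line 1: header must include 'gene' and 'human'"),
          class = "beconcord_error_parse")
  }
  dir_cols <- setdiff(names(prof), c("gene", "class"))
  prof <- prof |>
    mutate(across(dplyr::all_of(dir_cols), .normalize_direction))
  bad <- which(!prof$human %in% c("up", "down"))
  if (length(bad)) {
    abort(paste0(path, ": line(s) ", paste(bad + 1, collapse = ", "),
                 ": human panel status must be up or down"),
          class = "beconcord_error_parse")
  }
  class(prof) <- c("profile_table", class(prof))
  prof
}

#' Write a profile table as TSV (ASCII tokens)
#'
#' @param profile A profile table.
#' @param path Output TSV path.
#' @return The profile, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(profile)
}

#' Read a multi-dataset differential-expression evidence table
#'
#' Comma-separated with columns `gene`, `class`, `dataset`, `probe_id`,
#' `logFC`, `adj_p`, `present`; genes absent from a dataset have
#' `present = FALSE` and empty statistics. This is the input format of
#' [select_genes()], matching a published per-dataset logFC / adjusted-p
#' table transcribed as is.
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          gene = "c", class = "c", dataset = "c",
                          probe_id = "c", logFC = "d", adj_p = "d",
                          present = "l"
                        ))
  req <- c("gene", "dataset", "logFC", "adj_p", "present")
  if (!all(req %in% names(ev))) {
    abort(paste0(path, ": line 1: header must include ",
                 paste(req, collapse = ", ")),
          class = "beconcord_error_parse")
  }
  ev
}

#' Write simulated data plus its ground truth
#'
#' Writes an [simulate_expression()] result as matrix + annotation TSVs, or a
#' [simulate_ct()] result as a Ct CSV, with the ground truth as a sidecar
#' JSON next to the main file.
#'
#' @param sim An `expression_sim` or `ct_sim`.
#' @param path Output path for the main file (matrix TSV or Ct CSV).
#' @param annotation_path Annotation TSV path (expression only); defaults to
#'   `<path>_groups.tsv`.
#' @return `sim`, invisibly.
#' @export
write_simulation <- function(sim, path, annotation_path = NULL) {
  truth_path <- paste0(sub("\\.(tsv|csv)$", "", path), "_truth.json")
  if (inherits(sim, "expression_sim")) {
    annotation_path <- annotation_path %||%
      paste0(sub("\\.tsv$", "", path), "_groups.tsv")
    write_expression(sim$dataset, path, annotation_path)
  } else if (inherits(sim, "ct_sim")) {
    write_ct_table(sim$ct, path)
  } else {
    abort("`sim` must come from simulate_expression() or simulate_ct()",
          class = "beconcord_error_argument")
  }
  jsonlite::write_json(sim$truth, truth_path, digits = NA)
  invisible(sim)
}

#' Bundled example data files
#'
#' Paths to the plain-text tables shipped with the package: the transcribed
#' three-dataset human-biopsy evidence table (`table1_evidence.csv`) and the
#' published cross-system direction profile (`table5_profile.tsv`).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
beconcord_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "beconcord")))
  }
  path <- system.file("extdata", file, package = "beconcord")
  if (path == "") {
    abort(paste0("no bundled file called '", file, "'"),
          class = "beconcord_error_lookup")
  }
  path
}

#' The bundled human-biopsy evidence table
#'
#' Per-gene, per-dataset log2 fold changes and BH-adjusted p-values for the
#' squamous- and columnar-epithelium marker genes across the three human
#' biopsy microarray series (GSE13083, GSE34619, GSE1420), as published.
#' Genes not measured on a platform carry `present = FALSE`.
#'
#' @return A tibble in the [select_genes()] evidence format.
#' @export
table1_evidence <- function() {
  read_evidence(beconcord_example("table1_evidence.csv"))
}

#' The bundled cross-system direction profile
#'
#' Direction of expression change for the 23-gene human BE panel in the
#' Het-1A and EPC2 in vitro systems and the surgical rat reflux model,
#' alongside the human biopsy direction. The human entry for MUC5B is blank
#' in the published summary although the gene passes the selection criteria;
#' the bundled table records it as `up` per the evidence table, which is the
#' denominator convention the published percentages require.
#'
#' @return A `profile_table` tibble (23 genes: 10 squamous, 13 columnar).
#' @export
table5_profile <- function() {
  read_profile_table(beconcord_example("table5_profile.tsv"))
}
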