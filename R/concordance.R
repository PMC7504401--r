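#' Assemble a cross-system direction profile table
#'
#' Builds the gene-by-system profile: one row per human panel gene, with the
#' human direction taken from the selection stage (`selected_up`/`selected_down`)
#' and one direction call column per model system. Systems lacking a call for
#' a gene receive `nd` (not determined); calls for genes outside the panel
#' are dropped with a warning.
#'
#' @param panel Output of [select_genes()] (or any tibble of `gene`,
#'   `decision`, optionally `class`); only `selected_*` genes enter the
#'   profile.
#' @param calls A tibble of direction calls with columns `gene`, `system`,
#'   `status` (as from [call_direction()] with `system=`), or a named list of
#'   per-system call tibbles (`gene`, `status`).
#' @return A tibble of class `profile_table`: `gene`, `class` (if supplied),
#'   `human`, then one column per system with the five-token alphabet
#'   up/down/no_change/na/nd.
#' @export
build_profile_table <- function(panel, calls) {
  panel <- as_tibble(panel)
  if (!"decision" %in% names(panel)) {
    abort("`panel` needs a `decision` column", class = "beconcord_error_parse")
  }
  panel <- panel |>
    filter(.data$decision %in% c("selected_up", "selected_down")) |>
    mutate(human = dplyr::if_else(.data$decision == "selected_up",
                                  "up", "down"))
  if (nrow(panel) == 0) {
    abort("the panel contains no selected genes",
          class = "beconcord_error_config")
  }
  if (is.data.frame(calls)) {
    calls <- as_tibble(calls)
    declared_systems <- unique(calls$system)
  } else {
    declared_systems <- names(calls)
    calls <- purrr::imap(calls, \(d, s) mutate(as_tibble(d),
                                               system = s,
                                               status = as.character(.data$status))) |>
      bind_rows()
  }
  req <- c("gene", "system", "status")
  if (!all(req %in% names(calls))) {
    abort("`calls` needs columns gene, system, status",
          class = "beconcord_error_parse")
  }
  calls <- calls |>
    mutate(status = .normalize_direction(.data$status)) |>
    distinct(.data$gene, .data$system, .data$status)

  dup <- calls |> dplyr::count(.data$gene, .data$system) |> filter(n > 1)
  if (nrow(dup)) {
    abort(paste0("conflicting duplicate calls for: ",
                 paste(paste(dup$gene, dup$system, sep = "/"),
                       collapse = ", ")),
          class = "beconcord_error_integrity")
  }
  stray <- setdiff(unique(calls$gene), panel$gene)
  if (length(stray)) {
    warn(paste0("ignoring calls for non-panel gene(s): ",
                paste(stray, collapse = ", ")))
    calls <- calls |> filter(.data$gene %in% panel$gene)
  }

  keep <- intersect(c("gene", "class", "human"), names(panel))
  wide <- calls |>
    tidyr::pivot_wider(names_from = "system", values_from = "status",
                       values_fill = "nd")
  out <- panel |>
    select(dplyr::all_of(keep)) |>
    left_join(wide, by = "gene")
  for (sys in setdiff(declared_systems, names(out))) {
    out[[sys]] <- "nd"
  }
  out <- out |>
    mutate(across(-dplyr::all_of(keep), \(x) tidyr::replace_na(x, "nd")))
  class(out) <- c("profile_table", class(out))
  out
}

.profile_systems <- function(profile) {
  setdiff(names(profile), c("gene", "class", "human"))
}

.check_system <- function(profile, system) {
  missing_sys <- setdiff(system, .profile_systems(profile))
  if (length(missing_sys)) {
    abort(paste0("unknown system(s): ", paste(missing_sys, collapse = ", ")),
          class = "beconcord_error_lookup")
  }
}

#' Genes whose model direction matches the human panel direction
#'
#' @param profile A profile table (see [build_profile_table()]).
#' @param system A single system column name.
#' @return Character vector of matching genes. `na` (assayed, no
#'   amplification) and `no_change` never match since the human panel holds
#'   only up/down genes.
#' @export
match_set <- function(profile, system) {
  .check_system(profile, system)
  profile$gene[profile[[system]] == profile$human]
}

#' Direction concordance of one model system against the human panel
#'
#' The denominator is the number of panel genes actually evaluated in the
#' system: `nd` (not determined) genes are excluded, while `na` (assayed but
#' never amplified) and `no_change` genes stay in the denominator as
#' non-matches. The exact fraction is always reported; printed integer
#' percentages are available under both nearest and floor rounding.
#'
#' @param profile A profile table.
#' @param system A single system column name.
#' @param rounding Which convention fills `pct_printed`: `"nearest"`
#'   (default) or `"floor"`.
#' @return A one-row tibble of class `concordance_report`: `system`,
#'   `matches`, `denominator`, `fraction`, `pct_nearest`, `pct_floor`,
#'   `pct_printed`, and a list-column `matched_genes`.
#' @export
concordance_fraction <- function(profile, system,
                                 rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  .check_system(profile, system)
  if (length(system) != 1) {
    abort("`system` must name a single system",
          class = "beconcord_error_lookup")
  }
  status <- profile[[system]]
  eval_rows <- status != "nd"
  matches <- sum(eval_rows & status == profile$human)
  denom <- sum(eval_rows)
  .concordance_report(paste(system, collapse = "+"), matches, denom,
                      profile$gene[eval_rows & status == profile$human],
                      rounding)
}

#' Combined (union) concordance over several model systems
#'
#' A gene counts as matched when its call matches the human direction in at
#' least one of the listed systems. The denominator is the full panel except
#' genes that are `nd` in every listed system.
#'
#' @param profile A profile table.
#' @param systems Character vector of system column names (>= 1).
#' @param rounding Convention for `pct_printed`; the combined in vitro figure
#'   is conventionally printed under floor rounding.
#' @return A one-row `concordance_report` tibble (see
#'   [concordance_fraction()]).
#' @export
combined_concordance <- function(profile, systems,
                                 rounding = c("floor", "nearest")) {
  rounding <- match.arg(rounding)
  if (length(systems) < 1) {
    abort("at least one system is required",
          class = "beconcord_error_argument")
  }
  .check_system(profile, systems)
  status <- as.matrix(profile[, systems, drop = FALSE])
  all_nd <- apply(status == "nd", 1, all)
  matched <- apply(status == profile$human, 1, any) & !all_nd
  .concordance_report(paste(systems, collapse = "+"),
                      sum(matched), sum(!all_nd),
                      profile$gene[matched], rounding)
}

.concordance_report <- function(label, matches, denom, genes, rounding) {
  fraction <- if (denom > 0) matches / denom else NA_real_
  pct_nearest <- round(100 * fraction)
  pct_floor <- floor(100 * fraction)
  out <- tibble(
    system = label, matches = as.integer(matches),
    denominator = as.integer(denom), fraction = fraction,
    pct_nearest = pct_nearest, pct_floor = pct_floor,
    pct_printed = if (rounding == "nearest") pct_nearest else pct_floor,
    matched_genes = list(genes)
  )
  class(out) <- c("concordance_report", class(out))
  out
}

#' Partition two or three named gene sets into exclusive Venn regions
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @return A tibble of `region` (set names joined by `&` for intersections)
#'   and `count`; regions are mutually exclusive and sum to the union size.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list", class = "beconcord_error_argument")
  }
  k <- length(sets)
  if (k < 2 || k > 3) {
    abort("2 or 3 sets are supported", class = "beconcord_error_arity")
  }
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, \(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    membership <- matrix(logical(0), 0, k, dimnames = list(NULL, names(sets)))
  }
  if (is.null(dim(membership))) {
    membership <- matrix(membership, ncol = k, dimnames = list(NULL, names(sets)))
  }
  combos <- purrr::map(seq_len(k), \(m) utils::combn(names(sets), m,
                                                     simplify = FALSE)) |>
    purrr::flatten()
  purrr::map(combos, function(cm) {
    inside <- rowSums(membership[, cm, drop = FALSE]) == length(cm)
    outside <- rowSums(membership[, setdiff(names(sets), cm),
                                  drop = FALSE]) == 0
    tibble(region = paste(cm, collapse = "&"),
           count = as.integer(sum(inside & outside)))
  }) |>
    bind_rows()
}

#' Bar chart of per-system concordance
#'
#' @param reports One or more stacked `concordance_report` rows.
#' @return A ggplot object showing each system's matched fraction with the
#'   match/denominator counts annotated.
#' @export
plot_concordance <- function(reports) {
  d <- as_tibble(reports)
  ggplot2::ggplot(d, ggplot2::aes(.data$system, .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$matches,
                                                    .data$denominator)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "direction concordance with human panel") +
    ggplot2::theme_minimal()
}

#' @rdname plot_concordance
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @export
autoplot.concordance_report <- function(object, ...) plot_concordance(object)

#' Minimal Venn diagram of 2-3 gene sets
#'
#' Draws fixed-layout circles annotated with the exclusive region counts
#' from [venn_partition()]; layout fidelity (area proportionality) is not
#' attempted.
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @return A ggplot object.
#' @export
plot_venn <- function(sets) {
  parts <- venn_partition(sets)
  k <- length(sets)
  centers <- if (k == 2) {
    tibble(name = names(sets), x = c(-0.6, 0.6), y = c(0, 0))
  } else {
    tibble(name = names(sets), x = c(-0.6, 0.6, 0), y = c(-0.35, -0.35, 0.7))
  }
  lab_pos <- if (k == 2) {
    tibble(region = c(names(sets), paste(names(sets), collapse = "&")),
           x = c(-1, 1, 0), y = c(0, 0, 0))
  } else {
    tibble(
      region = c(names(sets),
                 paste(names(sets)[c(1, 2)], collapse = "&"),
                 paste(names(sets)[c(1, 3)], collapse = "&"),
                 paste(names(sets)[c(2, 3)], collapse = "&"),
                 paste(names(sets), collapse = "&")),
      x = c(-1, 1, 0, 0, -0.55, 0.55, 0),
      y = c(-0.6, -0.6, 1.25, -0.5, 0.35, 0.35, 0)
    )
  }
  lab <- lab_pos |> left_join(parts, by = "region")
  th <- seq(0, 2 * pi, length.out = 120)
  circles <- centers |>
    mutate(pts = purrr::map2(.data$x, .data$y, \(cx, cy)
      tibble(px = cx + cos(th), py = cy + sin(th)))) |>
    tidyr::unnest("pts")
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = circles,
                          ggplot2::aes(.data$px, .data$py, group = .data$name,
                                       fill = .data$name),
                          alpha = 0.25, colour = "grey30") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y,
                                    label = .data$count)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}
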