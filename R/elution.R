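#' Collapse a protein-level elution table to orthogroups
#'
#' Sums member-protein rows element-wise into orthogroup rows for one
#' experiment. Proteins absent from the map are either kept as singleton
#' rows under their own ID (`unmapped_policy = "keep"`, the default, which
#' conserves total PSM mass) or dropped.
#'
#' @param protein_elution Wide tibble: a `protein_id` column plus one
#'   numeric column per fraction of a single experiment.
#' @param og_map Tibble (`protein_id`, `og_id`), one orthogroup per protein.
#' @param unmapped_policy `"keep"` or `"drop"`.
#' @return Wide tibble: `og_id` plus the same fraction columns.
#' @export
#' @examples
#' pe <- tibble::tibble(protein_id = c("p1", "p2"),
#'                      f1 = c(1, 0), f2 = c(0, 3), f3 = c(2, 0))
#' map <- tibble::tibble(protein_id = c("p1", "p2"), og_id = "og1")
#' collapse_to_ogs(pe, map)
collapse_to_ogs <- function(protein_elution, og_map,
                            unmapped_policy = c("keep", "drop")) {
  unmapped_policy <- match.arg(unmapped_policy)
  if (anyDuplicated(protein_elution$protein_id)) {
    stop("duplicate protein rows in elution table", call. = FALSE)
  }
  if (anyDuplicated(og_map$protein_id)) {
    stop("`og_map` assigns some protein to several orthogroups",
         call. = FALSE)
  }
  joined <- dplyr::left_join(protein_elution, og_map, by = "protein_id")
  if (unmapped_policy == "keep") {
    joined$og_id <- dplyr::coalesce(joined$og_id, joined$protein_id)
  } else {
    joined <- dplyr::filter(joined, !is.na(.data$og_id))
  }
  joined |>
    dplyr::select(-"protein_id") |>
    dplyr::group_by(.data$og_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop")
}

#' Concatenate per-experiment elution tables into one matrix
#'
#' Stacks long-format elution tables from several experiments into the
#' concatenated multi-experiment matrix: the row universe is the union of
#' orthogroups, cells missing in an experiment are implicit zeros, and
#' total PSM mass is preserved.
#'
#' @param matrices A list of long elution tibbles (`og_id`,
#'   `experiment_id`, `species_id`, `fraction`, `psm`), one or more
#'   experiments each; experiment IDs must not collide across elements.
#' @return One long elution tibble.
#' @export
concatenate_experiments <- function(matrices) {
  if (inherits(matrices, "data.frame")) matrices <- list(matrices)
  ids <- purrr::map(matrices, ~ unique(.x$experiment_id))
  if (anyDuplicated(unlist(ids))) {
    stop("duplicate experiment IDs across matrices", call. = FALSE)
  }
  dplyr::bind_rows(matrices)
}

#' Filter orthogroups by grand-total PSM count
#'
#' Keeps exactly the orthogroups whose summed PSM count across every
#' fraction of every experiment is at least `min_total`. The default of
#' 150 retains only strongly observed orthogroups; the threshold is
#' inclusive.
#'
#' @param elution Long elution tibble.
#' @param min_total Minimum grand-total PSM count (>= 0).
#' @return The filtered elution tibble.
#' @export
filter_by_total_psms <- function(elution, min_total = 150) {
  if (min_total < 0) stop("`min_total` must be >= 0", call. = FALSE)
  totals <- elution |>
    dplyr::group_by(.data$og_id) |>
    dplyr::summarise(total = sum(.data$psm), .groups = "drop")
  keep <- totals$og_id[totals$total >= min_total]
  dplyr::filter(elution, .data$og_id %in% keep)
}

#' Normalize elution rows within experiment blocks
#'
#' `"l1_per_experiment"` divides each orthogroup's profile within each
#' experiment by its block sum, so every observed block sums to one
#' (all-zero blocks stay zero). `"none"` returns the counts unchanged.
#'
#' @param elution Long elution tibble.
#' @param scheme `"l1_per_experiment"` or `"none"`.
#' @return The elution tibble with `psm` replaced by the normalized value
#'   (column `psm`, now real-valued).
#' @export
normalize_rows <- function(elution, scheme = c("l1_per_experiment", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(elution)
  elution |>
    dplyr::group_by(.data$og_id, .data$experiment_id) |>
    dplyr::mutate(psm = if (sum(.data$psm) > 0) {
      .data$psm / sum(.data$psm)
    } else {
      .data$psm * 0
    }) |>
    dplyr::ungroup()
}

#' Dense orthogroup-by-fraction matrix of one experiment
#'
#' @param elution Long elution tibble.
#' @param experiment Experiment ID to extract.
#' @param n_fractions Number of fractions (default: the maximum observed
#'   fraction index).
#' @return A numeric matrix, rows named by orthogroup.
#' @export
elution_block_matrix <- function(elution, experiment, n_fractions = NULL) {
  block <- dplyr::filter(elution, .data$experiment_id == experiment)
  n_fr <- n_fractions %||% max(block$fraction)
  ogs <- sort(unique(block$og_id))
  m <- matrix(0, nrow = length(ogs), ncol = n_fr,
              dimnames = list(ogs, NULL))
  m[cbind(match(block$og_id, ogs), block$fraction)] <- block$psm
  m
}
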