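#' Species supporting each interaction
#'
#' A species supports a pair if at least one of its co-fractionation
#' experiments meets the support rule (Pearson correlation and co-detected
#' fraction count at or above the thresholds), or, when purification data
#' are supplied with a species column, if the pair co-purifies at least
#' once in that species.
#'
#' @param stats Per-experiment co-elution statistics from
#'   [coelution_stats()].
#' @param min_pearson Minimum Pearson correlation (default 0.5).
#' @param min_codetected Minimum co-detected fractions (default 3).
#' @param purifications Optional purification tibble with a `species_id`
#'   column plus (`purification_id`, `prey_id`).
#' @return A tibble (`og_a`, `og_b`, `species_id`), one row per supporting
#'   species per pair; pairs with no support are absent.
#' @export
species_support <- function(stats, min_pearson = 0.5, min_codetected = 3L,
                            purifications = NULL) {
  elu <- stats |>
    dplyr::filter(!is.na(.data$pearson),
                  .data$pearson >= min_pearson,
                  .data$n_codetected >= min_codetected) |>
    dplyr::distinct(.data$og_a, .data$og_b, .data$species_id)
  if (!is.null(purifications) && "species_id" %in% names(purifications)) {
    cop <- purifications |>
      dplyr::group_by(.data$purification_id, .data$species_id) |>
      dplyr::reframe({
        prey <- sort(unique(.data$prey_id))
        if (length(prey) < 2) {
          tibble(og_a = character(0), og_b = character(0))
        } else {
          idx <- combn(length(prey), 2)
          tibble(og_a = prey[idx[1, ]], og_b = prey[idx[2, ]])
        }
      }) |>
      dplyr::distinct(.data$og_a, .data$og_b, .data$species_id)
    elu <- dplyr::distinct(dplyr::bind_rows(elu, cop))
  }
  elu
}

#' Count distinct supergroups in a species set
#'
#' @param species Character vector of species IDs.
#' @param supergroup_map Tibble (`species_id`, `supergroup`), total over
#'   the species universe (see [species_supergroups()]).
#' @return Integer count of distinct supergroups represented.
#' @export
supergroup_count <- function(species, supergroup_map) {
  if (length(species) == 0L) return(0L)
  hit <- match(species, supergroup_map$species_id)
  if (anyNA(hit)) {
    stop("species without a supergroup label: ",
         paste(species[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  dplyr::n_distinct(supergroup_map$supergroup[hit])
}

#' Annotate network edges with supergroup conservation breadth
#'
#' Adds, per edge, the supporting species and the number of eukaryotic
#' supergroups those species span — the conservation breadth used to
#' color interactions from lineage-specific (1) to pan-eukaryotic (all
#' supergroups).
#'
#' @param edges Edge tibble (`og_a`, `og_b`, ...).
#' @param support Support tibble from [species_support()].
#' @param supergroup_map Tibble (`species_id`, `supergroup`).
#' @return `edges` with `supporting_species` (comma-joined) and
#'   `n_supergroups` columns.
#' @export
annotate_conservation <- function(edges, support, supergroup_map) {
  agg <- support |>
    dplyr::group_by(.data$og_a, .data$og_b) |>
    dplyr::summarise(
      supporting_species = paste(sort(unique(.data$species_id)),
                                 collapse = ","),
      n_supergroups = supergroup_count(unique(.data$species_id),
                                       supergroup_map),
      .groups = "drop"
    )
  edges |>
    dplyr::left_join(agg, by = c("og_a", "og_b")) |>
    dplyr::mutate(
      supporting_species = dplyr::coalesce(.data$supporting_species, ""),
      n_supergroups = dplyr::coalesce(.data$n_supergroups, 0L)
    )
}
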