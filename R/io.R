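# Readers/writers for the plain-text exchange formats: wide elution TSVs
# (one per experiment), 0/1 presence/absence TSVs, complex membership
# files (one complex per line, tab-separated members), and edge TSVs.

#' Write per-experiment elution tables as wide TSVs
#'
#' One file per experiment named `<experiment_id>.tsv`: first column
#' `og_id`, remaining columns `fraction_1..N`.
#'
#' @param elution Long elution tibble.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_elution_tsv <- function(elution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(unique(elution$experiment_id), function(eid) {
    wide <- elution |>
      dplyr::filter(.data$experiment_id == eid) |>
      dplyr::mutate(fraction = sprintf("fraction_%d", .data$fraction)) |>
      tidyr::pivot_wider(id_cols = "og_id", names_from = "fraction",
                         values_from = "psm", values_fill = 0)
    path <- file.path(dir, paste0(eid, ".tsv"))
    readr::write_tsv(wide, path)
    path
  })
  invisible(paths)
}

#' Read wide elution TSVs back into the long format
#'
#' @param paths TSV paths written by [write_elution_tsv()]; experiment ID
#'   is taken from the file name.
#' @param experiments Optional tibble (`experiment_id`, `species_id`) to
#'   restore species tags (otherwise `species_id` is NA).
#' @return A long elution tibble.
#' @export
read_elution_tsv <- function(paths, experiments = NULL) {
  out <- purrr::map_dfr(paths, function(p) {
    eid <- sub("\\.tsv$", "", basename(p))
    readr::read_tsv(p, show_col_types = FALSE) |>
      tidyr::pivot_longer(-"og_id", names_to = "fraction",
                          values_to = "psm") |>
      dplyr::mutate(
        experiment_id = eid,
        fraction = as.integer(sub("fraction_", "", .data$fraction))
      )
  })
  if (!is.null(experiments)) {
    out <- dplyr::left_join(out, experiments, by = "experiment_id")
  } else {
    out$species_id <- NA_character_
  }
  dplyr::select(out, "og_id", "experiment_id", "species_id", "fraction",
                "psm")
}

#' Write/read a complex set as a one-complex-per-line text file
#'
#' Each line holds the tab-separated member IDs of one complex.
#'
#' @param complexes Tibble (`complex_id`, `og_id`).
#' @param path File path.
#' @return `write_complexes()` returns the path invisibly;
#'   `read_complexes()` a tibble (`complex_id`, `og_id`) with complexes
#'   named `cpx001...` in file order.
#' @export
write_complexes <- function(complexes, path) {
  lines <- complexes |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::summarise(line = paste(sort(.data$og_id), collapse = "\t"),
                     .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_complexes
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(seq_along(lines), function(i) {
    tibble(complex_id = sprintf("cpx%03d", i),
           og_id = strsplit(lines[i], "\t", fixed = TRUE)[[1]])
  })
}

#' Write/read a presence/absence matrix TSV
#'
#' Rows are orthogroups, columns species, cells 0/1.
#'
#' @param presence Tibble (`og_id` + species columns).
#' @param path File path.
#' @export
write_presence_tsv <- function(presence, path) {
  readr::write_tsv(presence, path)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a scored edge table as TSV
#'
#' @param edges Edge/scored-network tibble.
#' @param path File path.
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}
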