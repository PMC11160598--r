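#' Simulate disease gene sets planted inside network communities
#'
#' For each disease, `round(coherence * set_size)` genes are drawn from one
#' planted complex (a complex large enough is required) and the remainder
#' uniformly at random from the gene universe. A matched collection of
#' fully random sets is also emitted, flagged as null, to serve as the
#' guilt-by-association negative control.
#'
#' @param complexes Tibble (`complex_id`, `og_id`).
#' @param n_diseases Number of coherent disease sets.
#' @param set_size Genes per set (>= 3).
#' @param coherence Fraction of each set drawn from a single complex.
#' @param seed Integer seed.
#' @param gene_universe Universe to draw random genes from (defaults to the
#'   complex members).
#' @return A tibble (`disease_id`, `gene_id`, `is_null`, `source_complex`);
#'   `source_complex` is NA for the random filler genes and null sets.
#' @export
simulate_disease_sets <- function(complexes, n_diseases, set_size, coherence,
                                  seed = 1L, gene_universe = NULL) {
  if (set_size < 3) stop("`set_size` must be >= 3", call. = FALSE)
  stopifnot_scalar_prob(coherence, "coherence")
  gene_universe <- gene_universe %||% unique(complexes$og_id)
  if (set_size > length(gene_universe)) {
    stop("`set_size` exceeds the gene universe", call. = FALSE)
  }
  k_core <- round(coherence * set_size)
  sizes <- dplyr::count(complexes, .data$complex_id)
  eligible <- sizes$complex_id[sizes$n >= k_core]
  if (k_core > 0 && length(eligible) == 0L) {
    stop("no planted complex is large enough for the requested coherence",
         call. = FALSE)
  }
  with_seed(seed, {
    coherent <- purrr::map_dfr(seq_len(n_diseases), function(i) {
      cpx <- if (k_core > 0) sample(rep(eligible, 2L), 1L) else NA_character_
      core <- if (k_core > 0) {
        members <- complexes$og_id[complexes$complex_id == cpx]
        sample(members, k_core)
      } else character(0)
      filler <- sample(setdiff(gene_universe, core), set_size - k_core)
      tibble(
        disease_id = sprintf("dis%03d", i),
        gene_id = c(core, filler),
        is_null = FALSE,
        source_complex = c(rep(cpx, k_core),
                           rep(NA_character_, set_size - k_core))
      )
    })
    nulls <- purrr::map_dfr(seq_len(n_diseases), function(i) {
      tibble(
        disease_id = sprintf("null%03d", i),
        gene_id = sample(gene_universe, set_size),
        is_null = TRUE,
        source_complex = NA_character_
      )
    })
    dplyr::bind_rows(coherent, nulls)
  })
}
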