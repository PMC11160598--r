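#' Simulate affinity-purification mass spectrometry evidence
#'
#' Each purification picks a bait from a planted complex; its co-members
#' are detected as prey with probability `detect_prob`, and background
#' orthogroups contaminate the prey list at a low fixed rate. Spectral
#' counts are Poisson-distributed (shifted so every listed prey has at
#' least one count).
#'
#' @param complexes Tibble (`complex_id`, `og_id`).
#' @param n_baits Number of purifications (>= 1).
#' @param detect_prob Probability a true co-member is detected, in (0, 1].
#' @param seed Integer seed.
#' @param background_rate Per-orthogroup contamination probability.
#' @param og_universe Orthogroup universe that background prey are drawn
#'   from (defaults to the complex members).
#' @return A tibble (`purification_id`, `prey_id`, `count`, `bait_id`,
#'   `bait_complex`); the last two columns record ground truth.
#' @export
simulate_apms <- function(complexes, n_baits, detect_prob, seed = 1L,
                          background_rate = 0.005, og_universe = NULL) {
  if (nrow(complexes) == 0L) stop("`complexes` must be nonempty", call. = FALSE)
  if (n_baits < 1) stop("`n_baits` must be >= 1", call. = FALSE)
  if (detect_prob <= 0 || detect_prob > 1) {
    stop("`detect_prob` must be in (0, 1]", call. = FALSE)
  }
  og_universe <- og_universe %||% unique(complexes$og_id)
  with_seed(seed, {
    baits <- complexes[sample.int(nrow(complexes), n_baits, replace = TRUE), ]
    purrr::map_dfr(seq_len(n_baits), function(i) {
      bait <- baits$og_id[i]
      cpx <- baits$complex_id[i]
      mates <- setdiff(complexes$og_id[complexes$complex_id == cpx], bait)
      prey <- c(bait, mates[runif(length(mates)) < detect_prob])
      bg_pool <- setdiff(og_universe, c(prey))
      bg <- bg_pool[runif(length(bg_pool)) < background_rate]
      prey <- c(prey, bg)
      tibble(
        purification_id = sprintf("pur%04d", i),
        prey_id = prey,
        count = rpois(length(prey), 4) + 1L,
        bait_id = bait,
        bait_complex = cpx
      )
    })
  })
}
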