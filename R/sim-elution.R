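#' Plant protein complexes over an orthogroup universe
#'
#' Partitions the first orthogroups of the universe into complexes with
#' sizes drawn uniformly from `size_range`; remaining orthogroups are
#' unassigned background.
#'
#' @param og_ids Character vector of orthogroup IDs.
#' @param n_complexes Number of complexes to plant.
#' @param size_range Length-2 min/max complex size (min >= 2).
#' @param seed Integer seed.
#' @return A tibble (`complex_id`, `og_id`).
#' @export
simulate_complexes <- function(og_ids, n_complexes, size_range = c(3L, 6L),
                               seed = 1L) {
  if (size_range[1] < 2) stop("complex sizes must be >= 2", call. = FALSE)
  with_seed(substream_seed(seed, 31L), {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_complexes,
                                  replace = TRUE)]
    while (sum(sizes) > length(og_ids)) sizes <- sizes[-length(sizes)]
    if (length(sizes) == 0L) {
      stop("orthogroup universe too small for any complex", call. = FALSE)
    }
    tibble(
      complex_id = rep(sprintf("cpx%03d", seq_along(sizes)), sizes),
      og_id = og_ids[seq_len(sum(sizes))]
    )
  })
}

#' Simulate one co-fractionation elution experiment
#'
#' Each planted complex draws one peak centre per experiment; every member's
#' expected profile is a Gaussian at that centre (plus per-member jitter)
#' scaled to the member's abundance. Background orthogroups get independent
#' peak centres. Observed counts are Poisson draws of the expected profile
#' plus cell-level spurious single PSMs at `noise_rate`; whole orthogroups
#' drop out of the experiment with probability `dropout_rate`. Peak centres
#' are sampled away from the fraction-range edges (margin of twice the peak
#' width) so edge truncation does not dominate profile correlations.
#'
#' @param complexes Tibble (`complex_id`, `og_id`) of planted complexes.
#' @param og_list Character vector of orthogroups present in this species
#'   (complex members outside `og_list` are skipped; extra IDs are
#'   background).
#' @param config A [simulation_config()].
#' @param species Species ID string for the emitted columns.
#' @param seed Integer seed.
#' @param experiment_id Experiment ID string.
#' @return A long tibble (`og_id`, `experiment_id`, `species_id`,
#'   `fraction`, `psm`) with a row for every fraction of every observed
#'   (non-dropout) orthogroup. The attribute `"expected"` carries the
#'   noiseless expected-profile matrix (orthogroup x fraction, before
#'   dropout) used by the generator.
#' @export
simulate_elution_experiment <- function(complexes, og_list, config,
                                        species = "sp01", seed = 1L,
                                        experiment_id = paste0(species, "_e1")) {
  if (nrow(complexes) == 0L) stop("`complexes` must be nonempty", call. = FALSE)
  n_fr <- config$n_fractions_per_experiment
  if (n_fr < 5) stop("need at least 5 fractions per experiment", call. = FALSE)
  with_seed(seed, {
    margin <- max(1L, ceiling(2 * config$peak_width))
    lo <- min(1L + margin, floor(n_fr / 2))
    hi <- max(n_fr - margin, ceiling(n_fr / 2) + 1L)
    ogs <- og_list
    member_of <- setNames(complexes$complex_id, complexes$og_id)
    cpx_ids <- unique(complexes$complex_id)
    cpx_center <- setNames(runif(length(cpx_ids), lo, hi), cpx_ids)
    centers <- vapply(ogs, function(og) {
      if (og %in% names(member_of)) {
        cpx_center[[member_of[[og]]]] + rnorm(1, 0, config$peak_jitter)
      } else {
        runif(1, lo, hi)
      }
    }, numeric(1))
    abundance <- stats::rgamma(length(ogs), shape = 2,
                               scale = config$abundance_mean / 2)
    fr <- seq_len(n_fr)
    expected <- t(vapply(seq_along(ogs), function(i) {
      w <- dnorm(fr, centers[i], config$peak_width)
      abundance[i] * w / sum(w)
    }, numeric(n_fr)))
    dimnames(expected) <- list(ogs, NULL)
    counts <- matrix(rpois(length(expected), expected), nrow = nrow(expected))
    counts <- counts + rbinom(length(counts), 1L, config$noise_rate)
    keep <- runif(length(ogs)) >= config$dropout_rate
    out <- tibble(
      og_id = rep(ogs[keep], each = n_fr),
      experiment_id = experiment_id,
      species_id = species,
      fraction = rep(fr, sum(keep)),
      psm = as.integer(t(counts[keep, , drop = FALSE]))
    )
    attr(out, "expected") <- expected
    out
  })
}

#' Simulate a complete multi-species co-fractionation study
#'
#' The one-stop generator: species tree with supergroup labels, planted
#' complexes, Dollo-consistent presence/absence, per-species elution
#' experiments (complex members only simulated in species carrying the
#' gene), affinity-purification evidence, and disease gene sets planted in
#' complexes. All downstream modules can be exercised against the returned
#' ground truth.
#'
#' @param config A [simulation_config()].
#' @param apms Logical; also simulate purification data.
#' @return A list: `config`, `tree`, `complexes`, `presence`, `gain_nodes`,
#'   `elution` (long tibble over all experiments), `experiments` (tibble
#'   `experiment_id`, `species_id`, `n_fractions`), `apms` (or NULL) and
#'   `diseases`.
#' @export
#' @examples
#' sim <- simulate_cfms_study(simulation_config(
#'   n_species = 3, n_ogs = 40, n_complexes = 6,
#'   n_fractions_per_experiment = 25, n_experiments_per_species = 2))
#' dplyr::count(sim$elution, experiment_id)
simulate_cfms_study <- function(config = simulation_config(), apms = TRUE) {
  seed <- config$seed
  tree <- simulate_species_tree(config$n_species, seed = seed)
  og_ids <- sprintf("og%04d", seq_len(config$n_ogs))
  complexes <- simulate_complexes(og_ids, config$n_complexes,
                                  config$complex_size_range, seed = seed)
  pa <- simulate_presence_absence(tree, config$n_ogs, config$loss_rate,
                                  seed = seed, og_ids = og_ids)
  pres_mat <- as.matrix(pa$presence[, -1])
  rownames(pres_mat) <- pa$presence$og_id

  runs <- tidyr::expand_grid(
    species_id = tree$tip.label,
    rep = seq_len(config$n_experiments_per_species)
  )
  runs$experiment_id <- sprintf("%s_e%d", runs$species_id, runs$rep)
  elution <- purrr::pmap_dfr(
    list(runs$species_id, runs$rep, runs$experiment_id, seq_len(nrow(runs))),
    function(sp, rep, eid, i) {
      present <- rownames(pres_mat)[pres_mat[, sp] == 1L]
      if (length(present) == 0L) return(NULL)
      simulate_elution_experiment(
        complexes, present, config, species = sp,
        seed = substream_seed(seed, 100L + i), experiment_id = eid
      )
    }
  )
  experiments <- tibble(
    experiment_id = runs$experiment_id,
    species_id = runs$species_id,
    n_fractions = config$n_fractions_per_experiment
  )
  apms_tbl <- NULL
  if (apms) {
    apms_tbl <- simulate_apms(complexes, n_baits = config$n_complexes,
                              detect_prob = 0.8,
                              seed = substream_seed(seed, 57L),
                              og_universe = og_ids)
  }
  diseases <- simulate_disease_sets(
    complexes, config$n_diseases, config$disease_set_size,
    config$disease_coherence, seed = substream_seed(seed, 71L),
    gene_universe = og_ids
  )
  list(config = config, tree = tree, complexes = complexes,
       presence = pa$presence, gain_nodes = pa$gain_nodes,
       elution = elution, experiments = experiments,
       apms = apms_tbl, diseases = diseases)
}
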