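#' Simulation configuration for synthetic co-fractionation studies
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a desk-scale study: a handful of species sampled from four eukaryotic
#' supergroups, each fractionated a few times, with planted protein
#' complexes whose members co-elute as Gaussian peaks and whose genes evolve
#' by single gain and multiple independent losses on the species tree.
#'
#' @param n_species Number of species (leaves of the simulated tree).
#' @param n_ogs Total number of orthogroups (complex members plus background).
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Length-2 integer vector, min/max members per
#'   complex (min must be >= 2).
#' @param n_fractions_per_experiment Fractions collected per separation.
#' @param n_experiments_per_species Independent separations per species.
#' @param peak_width Standard deviation (in fractions) of the Gaussian
#'   elution peak.
#' @param peak_jitter Standard deviation (in fractions) of each member's
#'   displacement from its complex's shared peak centre.
#' @param abundance_mean Expected total PSM count per orthogroup per
#'   experiment.
#' @param noise_rate Probability that any single matrix cell picks up one
#'   spurious PSM.
#' @param dropout_rate Probability that an orthogroup goes entirely
#'   unobserved in an experiment.
#' @param loss_rate Per-branch probability of gene loss below the gain node.
#' @param n_diseases Number of synthetic disease gene sets.
#' @param disease_set_size Genes per disease set (>= 3).
#' @param disease_coherence Fraction of each disease set drawn from a single
#'   planted complex; the remainder is random.
#' @param seed Global integer seed; stage-specific substreams are derived
#'   from it so stages are independently reproducible.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_species = 4, n_ogs = 60, n_complexes = 10)
#' cfg$n_fractions_per_experiment
simulation_config <- function(n_species = 8,
                              n_ogs = 800,
                              n_complexes = 100,
                              complex_size_range = c(3L, 10L),
                              n_fractions_per_experiment = 60,
                              n_experiments_per_species = 3,
                              peak_width = 2,
                              peak_jitter = 1,
                              abundance_mean = 300,
                              noise_rate = 0.01,
                              dropout_rate = 0.2,
                              loss_rate = 0.1,
                              n_diseases = 20,
                              disease_set_size = 10,
                              disease_coherence = 0.8,
                              seed = 1L) {
  counts <- list(
    n_species = n_species, n_ogs = n_ogs, n_complexes = n_complexes,
    n_fractions_per_experiment = n_fractions_per_experiment,
    n_experiments_per_species = n_experiments_per_species,
    n_diseases = n_diseases, disease_set_size = disease_set_size
  )
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop(sprintf("`%s` must be a count >= 1", nm), call. = FALSE)
    }
  }
  stopifnot_scalar_prob(noise_rate, "noise_rate")
  stopifnot_scalar_prob(dropout_rate, "dropout_rate")
  stopifnot_scalar_prob(loss_rate, "loss_rate")
  stopifnot_scalar_prob(disease_coherence, "disease_coherence")
  if (length(complex_size_range) != 2L || complex_size_range[1] < 2 ||
      complex_size_range[2] < complex_size_range[1]) {
    stop("`complex_size_range` must be (min >= 2, max >= min)", call. = FALSE)
  }
  if (peak_width <= 0 || peak_jitter < 0 || abundance_mean <= 0) {
    stop("peak_width and abundance_mean must be > 0; peak_jitter >= 0",
         call. = FALSE)
  }
  structure(
    list(
      n_species = as.integer(n_species),
      n_ogs = as.integer(n_ogs),
      n_complexes = as.integer(n_complexes),
      complex_size_range = as.integer(complex_size_range),
      n_fractions_per_experiment = as.integer(n_fractions_per_experiment),
      n_experiments_per_species = as.integer(n_experiments_per_species),
      peak_width = peak_width,
      peak_jitter = peak_jitter,
      abundance_mean = abundance_mean,
      noise_rate = noise_rate,
      dropout_rate = dropout_rate,
      loss_rate = loss_rate,
      n_diseases = as.integer(n_diseases),
      disease_set_size = as.integer(disease_set_size),
      disease_coherence = disease_coherence,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}
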