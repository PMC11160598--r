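#' Enumerate candidate orthogroup pairs
#'
#' Returns all unordered pairs of orthogroups that are both observed
#' (non-zero total PSMs) in at least `min_coobserved` common experiments.
#' Bounds the quadratic pair space before feature computation.
#'
#' @param elution Long elution tibble.
#' @param min_coobserved Minimum number of shared experiments (>= 1).
#' @return A tibble (`og_a`, `og_b`, `n_coobserved`), pairs in canonical
#'   lexicographic order.
#' @export
candidate_pairs <- function(elution, min_coobserved = 1L) {
  if (min_coobserved < 1) stop("`min_coobserved` must be >= 1", call. = FALSE)
  obs <- elution |>
    dplyr::group_by(.data$og_id, .data$experiment_id) |>
    dplyr::summarise(seen = sum(.data$psm) > 0, .groups = "drop") |>
    dplyr::filter(.data$seen)
  ogs <- sort(unique(obs$og_id))
  exps <- unique(obs$experiment_id)
  ind <- matrix(0L, length(ogs), length(exps), dimnames = list(ogs, exps))
  ind[cbind(match(obs$og_id, ogs), match(obs$experiment_id, exps))] <- 1L
  co <- tcrossprod(ind)
  idx <- which(upper.tri(co) & co >= min_coobserved, arr.ind = TRUE)
  tibble(
    og_a = ogs[idx[, 1]],
    og_b = ogs[idx[, 2]],
    n_coobserved = as.integer(co[idx])
  )
}

# Hypergeometric co-occurrence score: -log10 P(X >= k) for k co-detected
# fractions given per-row detection counts and the block length. Exact
# upper tail on the log scale to avoid underflow.
hyper_cooccurrence <- function(k, n_a, n_b, n_total) {
  lp <- phyper(k - 1, n_a, n_total - n_a, n_b, lower.tail = FALSE,
               log.p = TRUE)
  -lp / log(10)
}

#' Per-experiment co-elution statistics for candidate pairs
#'
#' Computes, for every requested pair within every experiment where both
#' orthogroups are observed: Pearson correlation; noise-regularized Pearson
#' (mean correlation over Poisson resamples of counts + 1 pseudocount);
#' Spearman correlation; Euclidean distance between L1-normalized profiles;
#' Bray-Curtis dissimilarity; a co-apex indicator (profile argmax fractions
#' within one fraction of each other); the maximal lagged cross-correlation
#' over lags up to 3 fractions; the hypergeometric co-occurrence score
#' (-log10 of the exact upper-tail probability of the observed number of
#' co-detected fractions); and the co-detected fraction count itself.
#' Detection means count >= 1.
#'
#' @param elution Long elution tibble.
#' @param pairs Tibble with columns `og_a`, `og_b` (canonical order), e.g.
#'   from [candidate_pairs()].
#' @param n_resamples Poisson resampling replicates for the
#'   noise-regularized Pearson.
#' @param max_lag Maximum lag (fractions) for the cross-correlation.
#' @param seed Integer seed for the resampling.
#' @return A tibble with one row per (pair, experiment): `og_a`, `og_b`,
#'   `experiment_id`, `species_id`, and the statistics above.
#' @export
coelution_stats <- function(elution, pairs, n_resamples = 5L, max_lag = 3L,
                            seed = 1L) {
  exps <- elution |>
    dplyr::distinct(.data$experiment_id, .data$species_id)
  key_wanted <- pair_key(pairs$og_a, pairs$og_b)
  out <- purrr::map_dfr(seq_len(nrow(exps)), function(j) {
    eid <- exps$experiment_id[j]
    X <- elution_block_matrix(elution, eid)
    X <- X[rowSums(X) > 0, , drop = FALSE]
    ogs <- rownames(X)
    if (length(ogs) < 2L) return(NULL)
    sel <- pairs$og_a %in% ogs & pairs$og_b %in% ogs
    if (!any(sel)) return(NULL)
    ia <- match(pairs$og_a[sel], ogs)
    ib <- match(pairs$og_b[sel], ogs)
    ij <- cbind(ia, ib)
    m <- ncol(X)

    pear <- suppressWarnings(cor(t(X)))
    spear <- suppressWarnings(cor(t(X), method = "spearman"))
    Xn <- X / rowSums(X)
    eucl <- as.matrix(dist(Xn))
    bray <- as.matrix(vegan::vegdist(Xn, method = "bray"))
    apex <- max.col(X, ties.method = "first")
    coapex <- abs(apex[ia] - apex[ib]) <= 1L

    xc <- pear
    for (l in seq_len(max_lag)) {
      if (l >= m) break
      Cl <- suppressWarnings(
        cor(t(X[, seq_len(m - l), drop = FALSE]),
            t(X[, (l + 1):m, drop = FALSE]))
      )
      xc <- pmax(xc, Cl, t(Cl), na.rm = TRUE)
    }

    det <- X >= 1
    ndet <- rowSums(det)
    K <- tcrossprod(det * 1)
    hyp <- hyper_cooccurrence(K[ij], ndet[ia], ndet[ib], m)

    pnr <- with_seed(substream_seed(seed, 300L + j), {
      acc <- matrix(0, length(ogs), length(ogs))
      for (r in seq_len(n_resamples)) {
        Xr <- matrix(rpois(length(X), X + 1), nrow = nrow(X))
        acc <- acc + suppressWarnings(cor(t(Xr)))
      }
      acc / n_resamples
    })

    tibble(
      og_a = pairs$og_a[sel], og_b = pairs$og_b[sel],
      experiment_id = eid, species_id = exps$species_id[j],
      pearson = pear[ij], pearson_nr = pnr[ij], spearman = spear[ij],
      euclidean = eucl[ij], braycurtis = bray[ij],
      coapex = as.numeric(coapex), xcorr = xc[ij], hyper = hyp,
      n_codetected = as.integer(K[ij])
    )
  })
  out
}

#' Aggregate co-elution statistics into per-pair features
#'
#' Runs [coelution_stats()] and aggregates across experiments: the mean and
#' max of each similarity statistic, the mean and min of each dissimilarity,
#' and the number of experiments in which the pair was co-observed.
#' Experiments where a pair's statistics are undefined (constant profile)
#' are skipped for that pair. Pairs never co-observed get all-zero features
#' with `n_experiments_coobserved = 0`.
#'
#' @inheritParams coelution_stats
#' @param stats Optionally, a precomputed result of [coelution_stats()]
#'   (skips recomputation).
#' @return A feature tibble: `og_a`, `og_b`, the aggregate feature columns,
#'   `n_experiments_coobserved`, and `n_species_coobserved`.
#' @export
coelution_features <- function(elution, pairs, n_resamples = 5L,
                               max_lag = 3L, seed = 1L, stats = NULL) {
  stats <- stats %||%
    coelution_stats(elution, pairs, n_resamples, max_lag, seed)
  agg <- stats |>
    dplyr::filter(!is.na(.data$pearson)) |>
    dplyr::group_by(.data$og_a, .data$og_b) |>
    dplyr::summarise(
      mean_pearson = mean(.data$pearson),
      max_pearson = max(.data$pearson),
      mean_pearson_nr = mean(.data$pearson_nr, na.rm = TRUE),
      max_pearson_nr = max(.data$pearson_nr, na.rm = TRUE),
      mean_spearman = mean(.data$spearman, na.rm = TRUE),
      max_spearman = max(.data$spearman, na.rm = TRUE),
      mean_coapex = mean(.data$coapex),
      max_coapex = max(.data$coapex),
      mean_xcorr = mean(.data$xcorr, na.rm = TRUE),
      max_xcorr = max(.data$xcorr, na.rm = TRUE),
      mean_hyper = mean(.data$hyper),
      max_hyper = max(.data$hyper),
      mean_euclidean = mean(.data$euclidean),
      min_euclidean = min(.data$euclidean),
      mean_braycurtis = mean(.data$braycurtis),
      min_braycurtis = min(.data$braycurtis),
      n_experiments_coobserved = dplyr::n(),
      n_species_coobserved = dplyr::n_distinct(.data$species_id),
      .groups = "drop"
    )
  pairs |>
    dplyr::select("og_a", "og_b") |>
    dplyr::left_join(agg, by = c("og_a", "og_b")) |>
    dplyr::mutate(dplyr::across(-c("og_a", "og_b"),
                                ~ tidyr::replace_na(.x, 0)))
}

#' Co-purification features for candidate pairs
#'
#' For every pair: the number of purifications in which both orthogroups
#' appear as prey, the Jaccard index of their purification sets, and the
#' hypergeometric co-occurrence score of the overlap over the dataset's
#' purification universe.
#'
#' @param purifications Tibble (`purification_id`, `prey_id`, `count`).
#' @param pairs Tibble with `og_a`, `og_b`.
#' @return A feature tibble (`og_a`, `og_b`, `copurification_count`,
#'   `copurification_jaccard`, `copurification_hyper`).
#' @export
purification_features <- function(purifications, pairs) {
  empty <- tibble(
    og_a = pairs$og_a, og_b = pairs$og_b,
    copurification_count = 0L, copurification_jaccard = 0,
    copurification_hyper = 0
  )
  if (is.null(purifications) || nrow(purifications) == 0L) return(empty)
  if (anyDuplicated(purifications[, c("purification_id", "prey_id")])) {
    stop("duplicate (purification, prey) rows", call. = FALSE)
  }
  prey <- sort(unique(purifications$prey_id))
  purs <- unique(purifications$purification_id)
  Mm <- matrix(0L, length(prey), length(purs), dimnames = list(prey, purs))
  Mm[cbind(match(purifications$prey_id, prey),
           match(purifications$purification_id, purs))] <- 1L
  sel <- pairs$og_a %in% prey & pairs$og_b %in% prey
  if (!any(sel)) return(empty)
  ia <- match(pairs$og_a[sel], prey)
  ib <- match(pairs$og_b[sel], prey)
  K <- tcrossprod(Mm)
  n_sets <- rowSums(Mm)
  ov <- K[cbind(ia, ib)]
  jac <- ov / (n_sets[ia] + n_sets[ib] - ov)
  hyp <- ifelse(ov > 0,
                hyper_cooccurrence(ov, n_sets[ia], n_sets[ib], length(purs)),
                0)
  out <- empty
  out$copurification_count[sel] <- as.integer(ov)
  out$copurification_jaccard[sel] <- jac
  out$copurification_hyper[sel] <- hyp
  out
}

#' Merge feature tables over a shared pair namespace
#'
#' Outer union of pairs across tables; features absent for a pair are
#' encoded as zero. Feature names must be unique across tables.
#'
#' @param tables List of feature tibbles (each with `og_a`, `og_b`).
#' @return One merged feature tibble; column order is the concatenation of
#'   the input tables' feature columns.
#' @export
merge_feature_tables <- function(tables) {
  if (inherits(tables, "data.frame")) return(as_tibble(tables))
  feat_names <- unlist(purrr::map(tables, ~ setdiff(names(.x),
                                                    c("og_a", "og_b"))))
  if (anyDuplicated(feat_names)) {
    stop("duplicate feature names across tables", call. = FALSE)
  }
  out <- purrr::reduce(tables, dplyr::full_join, by = c("og_a", "og_b"))
  dplyr::mutate(out, dplyr::across(-c("og_a", "og_b"),
                                   ~ tidyr::replace_na(.x, 0)))
}
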