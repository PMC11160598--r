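#' Build labeled pairs from a reference complex set
#'
#' Positives are all within-complex pairs. Negatives are sampled
#' cross-complex pairs among the reference orthogroups, at `negative_ratio`
#' times the positive count, excluding any pair that co-occurs in any
#' complex. Complexes sharing at least one member are merged into a single
#' leakage group before splitting, so that no shared protein can bridge
#' train and test folds.
#'
#' @param complexes Tibble (`complex_id`, `og_id`) of reference complexes
#'   (>= 2 complexes).
#' @param negative_ratio Negatives per positive (sampling is capped by the
#'   number of eligible cross pairs).
#' @param seed Integer seed.
#' @return A tibble (`og_a`, `og_b`, `label` in {1, 0}, `group_a`,
#'   `group_b`): the merged leakage-group IDs of the two endpoints (equal
#'   for positives).
#' @export
build_reference_labels <- function(complexes, negative_ratio = 5, seed = 1L) {
  if (dplyr::n_distinct(complexes$complex_id) < 2) {
    stop("need at least 2 reference complexes", call. = FALSE)
  }
  # merge complexes sharing members into groups
  cpx_ids <- sort(unique(complexes$complex_id))
  uf <- uf_new(cpx_ids)
  shared <- complexes |>
    dplyr::group_by(.data$og_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(cpx = list(unique(.data$complex_id)), .groups = "drop")
  for (cl in shared$cpx) {
    for (i in seq_along(cl)[-1]) uf_union(uf, cl[[1]], cl[[i]])
  }
  group_of_cpx <- vapply(cpx_ids, function(x) uf_find(uf, x), character(1))
  members <- complexes |>
    dplyr::mutate(group_id = group_of_cpx[.data$complex_id])
  group_of_og <- members |>
    dplyr::distinct(.data$og_id, .data$group_id)

  positives <- members |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::reframe({
      og <- sort(unique(.data$og_id))
      if (length(og) < 2) {
        tibble(og_a = character(0), og_b = character(0))
      } else {
        idx <- combn(length(og), 2)
        tibble(og_a = og[idx[1, ]], og_b = og[idx[2, ]])
      }
    }) |>
    dplyr::distinct(.data$og_a, .data$og_b) |>
    dplyr::mutate(label = 1L)

  pos_key <- pair_key(positives$og_a, positives$og_b)
  ogs <- sort(unique(complexes$og_id))
  # co-membership exclusion: any pair sharing a complex is ineligible
  co_member <- members |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::reframe({
      og <- sort(unique(.data$og_id))
      if (length(og) < 2) {
        tibble(k = character(0))
      } else {
        idx <- combn(length(og), 2)
        tibble(k = pair_key(og[idx[1, ]], og[idx[2, ]]))
      }
    })
  n_neg <- round(negative_ratio * nrow(positives))
  negatives <- with_seed(substream_seed(seed, 41L), {
    idx <- combn(length(ogs), 2)
    k <- pair_key(ogs[idx[1, ]], ogs[idx[2, ]])
    eligible <- which(!(k %in% co_member$k) & !(k %in% pos_key))
    take <- sample(eligible, min(n_neg, length(eligible)))
    tibble(og_a = ogs[idx[1, take]], og_b = ogs[idx[2, take]], label = 0L)
  })

  dplyr::bind_rows(positives, negatives) |>
    dplyr::left_join(dplyr::rename(group_of_og, og_a = "og_id",
                                   group_a = "group_id"), by = "og_a") |>
    dplyr::left_join(dplyr::rename(group_of_og, og_b = "og_id",
                                   group_b = "group_id"), by = "og_b")
}

#' Split labeled pairs by complex group
#'
#' Assigns whole leakage groups (merged complexes) to train or test folds
#' so that no orthogroup contributes pairs to both folds. Random
#' assignments are retried until the kept-pair test fraction is within 5
#' percentage points of the target; pairs whose endpoints straddle the two
#' folds are discarded.
#'
#' @param labels Labeled pairs from [build_reference_labels()].
#' @param test_fraction Target fraction of labeled pairs in the test fold,
#'   in (0, 1).
#' @param seed Integer seed.
#' @param max_tries Maximum random assignments attempted.
#' @return `labels` with a `fold` column (`"train"`, `"test"`, or
#'   `"discard"`).
#' @export
split_by_complex <- function(labels, test_fraction = 0.3, seed = 1L,
                             max_tries = 200L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  groups <- sort(unique(c(labels$group_a, labels$group_b)))
  if (length(groups) < 2) {
    stop("cannot split a single complex group", call. = FALSE)
  }
  with_seed(substream_seed(seed, 43L), {
    best <- NULL
    best_err <- Inf
    for (try in seq_len(max_tries)) {
      test_groups <- groups[runif(length(groups)) < test_fraction]
      fold_a <- ifelse(labels$group_a %in% test_groups, "test", "train")
      fold_b <- ifelse(labels$group_b %in% test_groups, "test", "train")
      fold <- ifelse(fold_a == fold_b, fold_a, "discard")
      kept <- fold != "discard"
      frac <- if (any(kept)) mean(fold[kept] == "test") else NA_real_
      err <- abs(frac - test_fraction)
      if (!is.na(err) && err < best_err &&
          any(fold == "test" & labels$label == 1L) &&
          any(fold == "train" & labels$label == 1L)) {
        best <- fold
        best_err <- err
      }
      if (best_err <= 0.05) break
    }
    if (is.null(best)) {
      stop("could not find a valid complex-level split", call. = FALSE)
    }
    if (best_err > 0.05) {
      warning("test fraction off target by more than 5 percentage points")
    }
    dplyr::mutate(labels, fold = best)
  })
}

#' Stratified negative downsampling of the training fold
#'
#' Within the training fold, negatives are downsampled per complex-group
#' stratum to at most `ratio` negatives per positive, so no group dominates
#' the loss. Strata without positives are dropped with a warning. The test
#' fold is returned untouched, preserving its natural class imbalance.
#'
#' @param split Labeled pairs with a `fold` column from
#'   [split_by_complex()].
#' @param ratio Maximum negatives per positive per stratum (0 keeps
#'   positives only).
#' @param seed Integer seed.
#' @return The input tibble with training-fold negatives downsampled.
#' @export
stratify_training <- function(split, ratio = 5, seed = 1L) {
  train <- dplyr::filter(split, .data$fold == "train")
  rest <- dplyr::filter(split, .data$fold != "train")
  # stratum = lexicographically smaller of the two group IDs
  train <- dplyr::mutate(train, stratum = pmin(.data$group_a, .data$group_b))
  pos_per <- train |>
    dplyr::filter(.data$label == 1L) |>
    dplyr::count(.data$stratum, name = "n_pos")
  empty <- setdiff(unique(train$stratum), pos_per$stratum)
  if (length(empty) > 0) {
    warning(sprintf("%d training strata have no positives and were dropped",
                    length(empty)))
  }
  with_seed(substream_seed(seed, 47L), {
    kept <- train |>
      dplyr::inner_join(pos_per, by = "stratum") |>
      dplyr::group_by(.data$stratum) |>
      dplyr::group_modify(function(df, key) {
        pos <- dplyr::filter(df, .data$label == 1L)
        neg <- dplyr::filter(df, .data$label == 0L)
        cap <- floor(df$n_pos[1] * ratio)
        if (nrow(neg) > cap) {
          neg <- neg[sample.int(nrow(neg), cap), ]
        }
        dplyr::bind_rows(pos, neg)
      }) |>
      dplyr::ungroup() |>
      dplyr::select(-"stratum", -"n_pos")
    dplyr::bind_rows(kept, rest)
  })
}
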