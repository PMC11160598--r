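#' Run the full synthetic-to-network analysis pipeline
#'
#' Orchestrates every stage end-to-end on synthetic data: simulation;
#' Dollo parsimony and root-orthogroup calling; elution assembly and the
#' strong-observation PSM filter; co-elution/co-purification features;
#' complex-withheld training of the interaction classifier; FDR
#' calibration and scoring; walktrap hierarchy with evaluation against
#' the planted complexes; conservation annotation; and guilt-by-
#' association disease ranking. A manifest records per-stage row counts
#' and timings; any stage failure aborts with the stage name.
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param min_total_psms Grand-total PSM filter (default 150).
#' @param target_fdr FDR operating point (default 0.10).
#' @param walk_length Walktrap walk length (default 4).
#' @param min_cluster_size Minimum cluster size for subdivision.
#' @param auroc_threshold Disease flag threshold (default 0.7).
#' @param family Classifier family (default linear max-margin SVM).
#' @param negative_ratio,test_fraction,stratify_ratio Label construction
#'   and split parameters.
#' @param min_coobserved Candidate-pair co-observation floor.
#' @return A list with all stage outputs (`sim`, `dollo`, `leca_ogs`,
#'   `elution`, `features`, `model`, `scored`, `calibration`, `graph`,
#'   `hierarchy`, `hierarchy_eval`, `conservation`, `gba`) plus
#'   `manifest`, a tibble (`stage`, `n_rows`, `seconds`).
#' @export
run_pipeline <- function(config = simulation_config(),
                         min_total_psms = 150,
                         target_fdr = 0.10,
                         walk_length = 4L,
                         min_cluster_size = 4L,
                         auroc_threshold = 0.7,
                         family = "linear_svm",
                         negative_ratio = 5,
                         test_fraction = 0.3,
                         stratify_ratio = 5,
                         min_coobserved = 2L) {
  manifest <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    n <- if (is.data.frame(out)) nrow(out) else NA_integer_
    manifest[[name]] <<- tibble(
      stage = name, n_rows = n,
      seconds = round(proc.time()[["elapsed"]] - t0, 2)
    )
    out
  }
  seed <- config$seed

  sim <- stage("simulate", simulate_cfms_study(config))
  dollo <- stage("dollo", infer_dollo(sim$presence, sim$tree))
  leca <- call_leca_ogs(dollo)
  elution <- stage("elution", {
    sim$elution |>
      dplyr::filter(.data$og_id %in% leca) |>
      filter_by_total_psms(min_total_psms)
  })
  pairs <- stage("candidate_pairs", candidate_pairs(elution, min_coobserved))
  stats <- stage("coelution_stats",
                 coelution_stats(elution, pairs, seed = seed))
  features <- stage("features", {
    merge_feature_tables(list(
      coelution_features(elution, pairs, stats = stats),
      purification_features(sim$apms, pairs)
    ))
  })
  labeled <- stage("labels", {
    build_reference_labels(
      dplyr::filter(sim$complexes, .data$og_id %in% features$og_a |
                      .data$og_id %in% features$og_b),
      negative_ratio = negative_ratio, seed = seed
    ) |>
      dplyr::left_join(features, by = c("og_a", "og_b")) |>
      dplyr::mutate(dplyr::across(
        -c("og_a", "og_b", "label", "group_a", "group_b"),
        ~ tidyr::replace_na(.x, 0)))
  })
  split <- stage("split", split_by_complex(labeled, test_fraction, seed))
  train <- stage("stratify",
                 dplyr::filter(stratify_training(split, stratify_ratio, seed),
                               .data$fold == "train"))
  test <- dplyr::filter(split, .data$fold == "test")
  model <- stage("train",
                 fit_ppi_classifier(train, family = family, seed = seed))
  scored_test <- dplyr::mutate(test, score = predict(model, test))
  calibration <- stage("calibrate", calibrate_fdr(scored_test, target_fdr))
  scored <- stage("score", {
    apply_fdr(score_all_pairs(features, model), calibration)
  })
  graph <- stage("graph", build_graph(scored, q_max = target_fdr))
  hierarchy <- stage("cluster", {
    recursive_subdivide(graph, min_size = min_cluster_size,
                        walk_length = walk_length)
  })
  hierarchy_eval <- stage("evaluate",
                          evaluate_hierarchy(hierarchy, sim$complexes))
  conservation <- stage("conservation", {
    annotate_conservation(graph, species_support(stats),
                          species_supergroups(sim$tree))
  })
  gba <- stage("gba", {
    rank_candidates(graph,
                    dplyr::filter(sim$diseases, !.data$is_null),
                    auroc_threshold)$diseases
  })

  list(sim = sim, dollo = dollo, leca_ogs = leca, elution = elution,
       features = features, model = model, scored = scored,
       calibration = calibration, graph = graph, hierarchy = hierarchy,
       hierarchy_eval = hierarchy_eval, conservation = conservation,
       gba = gba, manifest = dplyr::bind_rows(manifest))
}
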