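#' Recursively subdivide communities into a cluster hierarchy
#'
#' Level 0 is the top walktrap partition. At each subsequent level, every
#' cluster with at least `min_size` nodes whose induced subgraph splits
#' into more than one walktrap community is replaced by its
#' subcommunities; all other clusters are carried down unchanged, so each
#' level refines the previous one. Nodes of a cluster that are isolated in
#' its induced subgraph become singleton subclusters. Recursion stops at
#' `max_depth` or when no cluster splits.
#'
#' @param edges Edge tibble (`og_a`, `og_b`, `weight`).
#' @param top_partition Tibble (`node`, `cluster`), e.g.
#'   `walktrap(edges)$partition`. Default: computed by [walktrap()].
#' @param min_size Minimum cluster size eligible for splitting (>= 2).
#' @param max_depth Maximum number of refinement levels below the top.
#' @param walk_length Walk length passed to [walktrap()].
#' @return A tibble (`node`, `level`, `cluster_id`); `cluster_id` encodes
#'   the parent path (e.g. `"c002.1.3"`), so containment is explicit.
#' @export
recursive_subdivide <- function(edges, top_partition = NULL, min_size = 4L,
                                max_depth = 4L, walk_length = 4L) {
  if (min_size < 2) stop("`min_size` must be >= 2", call. = FALSE)
  top_partition <- top_partition %||% walktrap(edges, walk_length)$partition
  current <- tibble(node = top_partition$node,
                    cluster_id = top_partition$cluster)
  out <- dplyr::mutate(current, level = 0L)
  level <- 0L
  repeat {
    if (level >= max_depth) break
    pieces <- split(current$node, current$cluster_id)
    changed <- FALSE
    nxt <- purrr::map_dfr(names(pieces), function(cid) {
      nodes <- pieces[[cid]]
      if (length(nodes) < min_size) {
        return(tibble(node = nodes, cluster_id = cid))
      }
      sub <- edges[edges$og_a %in% nodes & edges$og_b %in% nodes, ]
      if (nrow(sub) == 0L) {
        return(tibble(node = nodes, cluster_id = cid))
      }
      part <- walktrap(sub, walk_length)$partition
      lonely <- setdiff(nodes, part$node)
      if (length(lonely) > 0) {
        part <- dplyr::bind_rows(
          part, tibble(node = lonely, cluster = paste0("iso_", lonely)))
      }
      if (dplyr::n_distinct(part$cluster) <= 1L) {
        return(tibble(node = nodes, cluster_id = cid))
      }
      changed <<- TRUE
      sub_ids <- sort(unique(part$cluster))
      tibble(node = part$node,
             cluster_id = paste0(cid, ".",
                                 match(part$cluster, sub_ids)))
    })
    if (!changed) break
    level <- level + 1L
    current <- nxt
    out <- dplyr::bind_rows(out, dplyr::mutate(current, level = level))
  }
  dplyr::select(out, "node", "level", "cluster_id") |>
    dplyr::arrange(.data$level, .data$cluster_id, .data$node)
}

#' Evaluate a cluster hierarchy against known complexes
#'
#' For every cluster at every level, finds the reference complex with the
#' largest overlap (ties go to the larger complex, then lexicographically)
#' and reports precision (overlap over the cluster's members that belong
#' to the reference universe) and recall (overlap over the complex size).
#' Clusters with no members in the reference universe are kept with NA
#' precision/recall so they can be counted but excluded from averages.
#'
#' @param hierarchy Tibble (`node`, `level`, `cluster_id`) from
#'   [recursive_subdivide()].
#' @param complexes Reference tibble (`complex_id`, `og_id`); must be
#'   nonempty.
#' @return A tibble (`level`, `cluster_id`, `n_nodes`, `n_reference`,
#'   `match`, `overlap`, `precision`, `recall`, `f1`).
#' @export
evaluate_hierarchy <- function(hierarchy, complexes) {
  if (nrow(complexes) == 0L) stop("reference complexes must be nonempty",
                                  call. = FALSE)
  ref_universe <- unique(complexes$og_id)
  cpx_sets <- split(complexes$og_id, complexes$complex_id)
  cpx_sizes <- lengths(cpx_sets)
  hierarchy |>
    dplyr::group_by(.data$level, .data$cluster_id) |>
    dplyr::group_modify(function(df, key) {
      nodes <- df$node
      in_ref <- intersect(nodes, ref_universe)
      if (length(in_ref) == 0L) {
        return(tibble(n_nodes = length(nodes), n_reference = 0L,
                      match = NA_character_, overlap = 0L,
                      precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_))
      }
      ov <- vapply(cpx_sets, function(s) length(intersect(s, in_ref)), 1L)
      ord <- order(-ov, -cpx_sizes, names(cpx_sets))
      best <- ord[1]
      p <- ov[best] / length(in_ref)
      r <- ov[best] / cpx_sizes[best]
      tibble(n_nodes = length(nodes), n_reference = length(in_ref),
             match = names(cpx_sets)[best], overlap = unname(ov[best]),
             precision = unname(p), recall = unname(r),
             f1 = unname(ifelse(p + r == 0, 0, 2 * p * r / (p + r))))
    }) |>
    dplyr::ungroup()
}

#' Per-level summary of a hierarchy evaluation
#'
#' Node-weighted mean precision and recall per level (weights are each
#' cluster's reference-universe member count); clusters without reference
#' members are excluded from the means and counted separately.
#'
#' @param evaluation Output of [evaluate_hierarchy()].
#' @return A tibble (`level`, `n_clusters`, `n_evaluable`,
#'   `mean_precision`, `mean_recall`, `mean_f1`).
#' @export
hierarchy_level_summary <- function(evaluation) {
  evaluation |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      n_evaluable = sum(!is.na(.data$precision)),
      mean_precision = stats::weighted.mean(.data$precision,
                                            .data$n_reference, na.rm = TRUE),
      mean_recall = stats::weighted.mean(.data$recall, .data$n_reference,
                                         na.rm = TRUE),
      mean_f1 = stats::weighted.mean(.data$f1, .data$n_reference,
                                     na.rm = TRUE),
      .groups = "drop"
    )
}
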