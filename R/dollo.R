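#' Infer orthogroup gain nodes by Dollo parsimony
#'
#' Under Dollo parsimony a gene family arises exactly once and can only be
#' lost thereafter. For each orthogroup the gain node is therefore the last
#' common ancestor (LCA) of the species carrying it, and the loss count is
#' the number of maximal subtrees below the gain node that contain no
#' carrier. Orthogroups present in a single species gain at that leaf;
#' orthogroups with no presences are flagged absent.
#'
#' @param presence Tibble or data frame: an `og_id` column plus one 0/1
#'   column per species. Species columns must match the tree's tips
#'   exactly (any order).
#' @param tree Rooted [ape::phylo] tree over the same species. Polytomies
#'   are allowed.
#' @return A tibble (`og_id`, `gain_node`, `n_losses`, `is_root_og`,
#'   `n_present`). `gain_node` is a tip label or internal node label
#'   (`n<k>` when the tree carries none); absent orthogroups have
#'   `gain_node = NA` and `n_losses = NA`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' pa <- tibble::tibble(og_id = c("x", "y"),
#'                      A = c(1, 1), B = c(1, 0), C = c(0, 1), D = c(0, 0))
#' infer_dollo(pa, tr)
infer_dollo <- function(presence, tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted", call. = FALSE)
  sp_cols <- setdiff(names(presence), "og_id")
  if (!setequal(sp_cols, tree$tip.label)) {
    stop("presence/absence columns do not match the tree's leaf set",
         call. = FALSE)
  }
  mat <- as.matrix(presence[, tree$tip.label, drop = FALSE])
  storage.mode(mat) <- "integer"
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_nodes <- n_tip + tree$Nnode
  nm <- node_names(tree)

  # clade membership matrix: M[node, tip] = tip belongs to node's clade
  leaf_sets <- node_leaf_sets(tree)
  M <- matrix(FALSE, n_nodes, n_tip)
  for (v in seq_len(n_nodes)) M[v, leaf_sets[[v]]] <- TRUE
  clade_size <- rowSums(M)
  edges <- tree$edge
  in_clade <- function(gain) {
    v <- logical(n_nodes)
    v[descendant_cache[[gain]]] <- TRUE
    v
  }
  descendant_cache <- descendant_node_sets(tree)

  res <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    p <- mat[i, ] == 1L
    k <- sum(p)
    if (k == 0L) {
      return(tibble(og_id = presence$og_id[i], gain_node = NA_character_,
                    n_losses = NA_integer_, is_root_og = FALSE,
                    n_present = 0L))
    }
    # nodes whose subtree contains >= 1 carrier
    has_pres <- as.vector(M %*% p) > 0
    # LCA = smallest clade containing all carriers
    covers <- as.vector(M %*% p) == k
    gain <- which(covers)[which.min(clade_size[covers])]
    inc <- in_clade(gain)
    losses <- sum(inc[edges[, 1]] & has_pres[edges[, 1]] & !has_pres[edges[, 2]])
    tibble(og_id = presence$og_id[i], gain_node = nm[gain],
           n_losses = as.integer(losses), is_root_og = gain == root,
           n_present = as.integer(k))
  })
  res
}

#' Call root-origin (LECA) orthogroups
#'
#' Returns the orthogroups whose Dollo gain node is the species-tree root,
#' i.e. the families inferred to have been present in the last common
#' ancestor of all sampled species.
#'
#' @param dollo A result tibble from [infer_dollo()].
#' @return Character vector of orthogroup IDs.
#' @export
call_leca_ogs <- function(dollo) {
  dollo$og_id[dollo$is_root_og]
}

#' Transfer member-protein annotations to unannotated orthogroups
#'
#' Orthogroups that already carry an algorithmic functional label keep it.
#' Orthogroups labelled "function unknown" receive the most frequent label
#' among their member proteins (ties broken lexicographically) and are
#' marked `source = "transferred"`; orthogroups whose members are all
#' unlabelled stay unknown.
#'
#' @param og_annotations Tibble (`og_id`, `label`) of existing orthogroup
#'   labels; the literal label `"function unknown"` (or NA) marks
#'   unannotated orthogroups.
#' @param og_members Tibble (`og_id`, `protein_id`) mapping orthogroups to
#'   member proteins.
#' @param member_annotations Tibble (`protein_id`, `label`) of per-protein
#'   labels.
#' @return A tibble (`og_id`, `label`, `source`) with `source` one of
#'   `"algorithmic"`, `"transferred"`, `"unknown"`.
#' @export
transfer_annotations <- function(og_annotations, og_members,
                                 member_annotations) {
  unknown <- is.na(og_annotations$label) |
    og_annotations$label == "function unknown"
  member_votes <- og_members |>
    dplyr::inner_join(member_annotations, by = "protein_id") |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::count(.data$og_id, .data$label) |>
    dplyr::group_by(.data$og_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("og_id", transferred_label = "label")

  og_annotations |>
    dplyr::left_join(member_votes, by = "og_id") |>
    dplyr::mutate(
      source = dplyr::case_when(
        !unknown ~ "algorithmic",
        unknown & !is.na(.data$transferred_label) ~ "transferred",
        TRUE ~ "unknown"
      ),
      label = dplyr::case_when(
        source == "transferred" ~ .data$transferred_label,
        source == "unknown" ~ "function unknown",
        TRUE ~ .data$label
      )
    ) |>
    dplyr::select("og_id", "label", "source")
}
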