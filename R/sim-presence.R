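#' Simulate orthogroup presence/absence by single gain and multiple losses
#'
#' Each orthogroup originates once at a gain node (the root with probability
#' `root_fraction`, otherwise a uniformly chosen non-root internal node) and
#' then evolves down the tree: every branch below the gain node loses the
#' gene independently with probability `loss_rate`, and loss is absorbing.
#' The emitted patterns are therefore Dollo-consistent by construction.
#'
#' @param tree Rooted tree from [simulate_species_tree()] (any rooted
#'   [ape::phylo] works).
#' @param n_ogs Number of orthogroups to simulate.
#' @param loss_rate Per-branch loss probability in \[0, 1\].
#' @param root_fraction Probability that an orthogroup's gain node is the
#'   root (an ancestral, LECA-age family).
#' @param seed Integer seed.
#' @param og_ids Optional character vector of orthogroup IDs
#'   (default `og0001...`).
#' @return A list with `presence`: a tibble (`og_id` + one 0/1 column per
#'   species) and `gain_nodes`: a tibble (`og_id`, `gain_node`) recording
#'   each orthogroup's true origin.
#' @export
#' @examples
#' tr <- simulate_species_tree(6, seed = 2)
#' pa <- simulate_presence_absence(tr, 20, loss_rate = 0.1, seed = 3)
#' head(pa$presence)
simulate_presence_absence <- function(tree, n_ogs, loss_rate,
                                      root_fraction = 0.7, seed = 1L,
                                      og_ids = NULL) {
  if (!inherits(tree, "phylo") || !ape::is.rooted(tree)) {
    stop("`tree` must be a rooted phylo object", call. = FALSE)
  }
  stopifnot_scalar_prob(loss_rate, "loss_rate")
  stopifnot_scalar_prob(root_fraction, "root_fraction")
  n_ogs <- as.integer(n_ogs)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  internal <- n_tip + seq_len(tree$Nnode)
  non_root_internal <- setdiff(internal, root)
  nm <- node_names(tree)
  og_ids <- og_ids %||% sprintf("og%04d", seq_len(n_ogs))

  # preorder edge list: parents always precede children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  n_nodes <- n_tip + tree$Nnode

  with_seed(substream_seed(seed, 23L), {
    gains <- ifelse(
      runif(n_ogs) < root_fraction | length(non_root_internal) == 0L,
      root,
      sample(rep(non_root_internal, 2L), n_ogs, replace = TRUE)
    )
    mat <- matrix(0L, nrow = n_ogs, ncol = n_tip,
                  dimnames = list(og_ids, tree$tip.label))
    # ancestor test: clade membership per gain node
    leaf_sets <- node_leaf_sets(tree)
    desc_nodes <- descendant_node_sets(tree)
    for (i in seq_len(n_ogs)) {
      present <- logical(n_nodes)
      present[gains[i]] <- TRUE
      in_clade <- logical(n_nodes)
      in_clade[desc_nodes[[gains[i]]]] <- TRUE
      for (e in seq_len(nrow(edges))) {
        p <- edges[e, 1]; ch <- edges[e, 2]
        if (in_clade[p] && present[p]) {
          present[ch] <- runif(1) >= loss_rate
        }
      }
      mat[i, ] <- as.integer(present[seq_len(n_tip)])
    }
    list(
      presence = dplyr::bind_cols(tibble(og_id = og_ids), as_tibble(mat)),
      gain_nodes = tibble(og_id = og_ids, gain_node = nm[gains])
    )
  })
}

# for each node, the set of nodes (incl. itself) in its subtree
descendant_node_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) sets[[i]] <- i
  ord <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  for (child in ord) {
    parent <- tree$edge[tree$edge[, 2] == child, 1]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}
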