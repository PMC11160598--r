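#' Simulate a rooted binary species tree with supergroup labels
#'
#' Generates a random rooted binary topology over `n_species` uniquely named
#' leaves and assigns each leaf one of (up to) four supergroup labels by
#' clade, mimicking the deep structure of the eukaryotic tree
#' (Amorphea, Excavata, TSAR, Archaeplastida).
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param supergroups Character vector of clade labels to distribute.
#' @return An [ape::phylo] tree with unique tip labels `sp01, sp02, ...`,
#'   internal node labels `n<k>`, and an extra element `supergroup`: a named
#'   character vector mapping each tip to its supergroup.
#' @export
#' @examples
#' tr <- simulate_species_tree(8, seed = 1)
#' table(tr$supergroup)
simulate_species_tree <- function(n_species, seed = 1L,
                                  supergroups = c("Amorphea", "Excavata",
                                                  "TSAR", "Archaeplastida")) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2) {
    stop("`n_species` must be a single integer >= 2", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  tree <- with_seed(substream_seed(seed, 11L), {
    if (n_species == 2L) {
      ape::read.tree(text = "(a:1,b:1);")
    } else {
      ape::rtree(n_species, rooted = TRUE)
    }
  })
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree$node.label <- sprintf("n%d", n_species + seq_len(tree$Nnode))

  # Partition leaves into clades by repeatedly splitting the largest clade,
  # then label clades with supergroups.
  k <- min(length(supergroups), n_species)
  kids <- tree_children(tree)
  clade_leaves <- node_leaf_sets(tree)
  open <- as.integer(n_species + 1L)  # root
  while (length(open) < k) {
    sizes <- lengths(clade_leaves[open])
    splittable <- open[open > n_species]
    if (length(splittable) == 0L) break
    big <- splittable[which.max(lengths(clade_leaves[splittable]))]
    open <- c(setdiff(open, big), kids[[big]])
  }
  open <- open[order(vapply(clade_leaves[open], min, 1L))]
  sg <- character(n_species)
  for (i in seq_along(open)) {
    sg[clade_leaves[[open[i]]]] <- supergroups[i]
  }
  tree$supergroup <- setNames(sg, tree$tip.label)
  tree
}

#' Species-to-supergroup map of a simulated tree
#'
#' @param tree A tree from [simulate_species_tree()].
#' @return A tibble with columns `species_id`, `supergroup`.
#' @export
species_supergroups <- function(tree) {
  tibble(species_id = names(tree$supergroup),
         supergroup = unname(tree$supergroup))
}

# children list indexed by node id (tips have integer(0))
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

# leaf (tip index) sets per node, computed bottom-up
node_leaf_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  # process edges in reverse order of a preorder edge list => postorder
  ord <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  for (child in ord) {
    parent <- tree$edge[tree$edge[, 2] == child, 1]
    sets[[parent]] <- sort(unique(c(sets[[parent]], sets[[child]])))
  }
  sets
}

# node id -> printable name (tip label or internal node label)
node_names <- function(tree) {
  c(tree$tip.label, tree$node.label %||%
      sprintf("n%d", ape::Ntip(tree) + seq_len(tree$Nnode)))
}
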