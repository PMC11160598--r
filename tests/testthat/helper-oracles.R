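# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration for Dollo scenarios,
# replay-based dendrogram cuts scored with igraph's modularity, and plain
# double loops for pairwise quantities.

# Enumerate every single-gain / arbitrary-loss scenario on a rooted binary
# tree and return, for a 0/1 presence vector over tips, the minimal loss
# count and the gain node(s) achieving it.
brute_force_dollo <- function(tree, pattern) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  edges <- tree$edge
  parent_of <- rep(NA_integer_, n_nodes)
  parent_of[edges[, 2]] <- edges[, 1]
  edge_to <- setNames(seq_len(nrow(edges)), edges[, 2])

  # path (edge indices) from node up to ancestor `anc`; NULL if not under
  path_edges <- function(node, anc) {
    path <- integer(0)
    v <- node
    while (v != anc) {
      p <- parent_of[v]
      if (is.na(p)) return(NULL)
      path <- c(path, edge_to[[as.character(v)]])
      v <- p
    }
    path
  }

  best_losses <- Inf
  best_gains <- integer(0)
  for (gain in seq_len(n_nodes)) {
    paths <- lapply(seq_len(n_tip), path_edges, anc = gain)
    under <- !vapply(paths, is.null, logical(1))
    if (any(pattern == 1 & !under)) next  # carrier outside the clade
    clade_edges <- sort(unique(unlist(paths[under])))
    n_e <- length(clade_edges)
    for (mask in 0:(2^n_e - 1)) {
      lost <- clade_edges[bitwAnd(bitwShiftL(1, seq_len(n_e) - 1L),
                                  mask) > 0]
      leaf_state <- vapply(seq_len(n_tip), function(l) {
        if (!under[l]) return(0L)
        as.integer(!any(paths[[l]] %in% lost))
      }, integer(1))
      if (all(leaf_state == pattern)) {
        if (length(lost) < best_losses) {
          best_losses <- length(lost)
          best_gains <- gain
        } else if (length(lost) == best_losses) {
          best_gains <- union(best_gains, gain)
        }
      }
    }
  }
  list(n_losses = best_losses, gains = best_gains)
}

# One-sweep variant: enumerate every (gain, loss-edge-set) scenario once
# and collect, for every reachable leaf pattern, the minimal loss count
# and the gain nodes achieving it. Patterns are keyed by sum(2^(tip-1)).
brute_force_dollo_all <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  edges <- tree$edge
  parent_of <- rep(NA_integer_, n_nodes)
  parent_of[edges[, 2]] <- edges[, 1]
  edge_to <- rep(NA_integer_, n_nodes)
  edge_to[edges[, 2]] <- seq_len(nrow(edges))

  best_losses <- rep(Inf, 2^n_tip)
  best_gains <- vector("list", 2^n_tip)
  for (gain in seq_len(n_nodes)) {
    # per-leaf bitmask over the edges on the gain->leaf path
    path_mask <- rep(NA_real_, n_tip)
    clade_edges <- integer(0)
    for (l in seq_len(n_tip)) {
      v <- l; mask <- 0; ok <- TRUE; path <- integer(0)
      while (v != gain) {
        p <- parent_of[v]
        if (is.na(p)) { ok <- FALSE; break }
        path <- c(path, edge_to[v]); v <- p
      }
      if (ok) { path_mask[l] <- sum(2^(match(path, path) - 1)) }
      if (ok) clade_edges <- union(clade_edges, path)
    }
    clade_edges <- sort(clade_edges)
    n_e <- length(clade_edges)
    # recode path masks over the clade-local edge indexing
    local_mask <- vapply(seq_len(n_tip), function(l) {
      v <- l; path <- integer(0)
      while (!is.na(v) && v != gain) {
        path <- c(path, edge_to[v]); v <- parent_of[v]
      }
      if (is.na(v)) return(NA_real_)
      sum(2^(match(path, clade_edges) - 1))
    }, numeric(1))
    under <- !is.na(local_mask)
    for (mask in 0:(2^n_e - 1)) {
      present <- under & bitwAnd(local_mask, mask) %in% 0
      present[is.na(present)] <- FALSE
      key <- sum(2^(which(present) - 1)) + 1
      losses <- sum(bitwAnd(2^(seq_len(n_e) - 1), mask) > 0)
      if (losses < best_losses[key]) {
        best_losses[key] <- losses
        best_gains[[key]] <- gain
      } else if (losses == best_losses[key]) {
        best_gains[[key]] <- union(best_gains[[key]], gain)
      }
    }
  }
  list(losses = best_losses, gains = best_gains)
}

# Random connected undirected graph on n nodes (unit or random weights).
random_connected_graph <- function(n, p = 0.4, weighted = FALSE,
                                   seed = 1L) {
  set.seed(seed)
  repeat {
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < p
    # spanning chain guarantees connectivity candidates; reject otherwise
    if (sum(keep) < n - 1) next
    a <- sprintf("v%02d", idx[1, keep])
    b <- sprintf("v%02d", idx[2, keep])
    g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
    if (igraph::is_connected(g) && igraph::vcount(g) == n) {
      w <- if (weighted) round(stats::runif(sum(keep), 0.2, 1), 3) else 1
      return(tibble::tibble(og_a = pmin(a, b), og_b = pmax(a, b),
                            weight = w))
    }
  }
}

# Modularity of every dendrogram cut, recomputed independently of the
# walktrap internals: replay the merge list with a plain membership vector
# and score each partition with igraph's weighted modularity.
best_cut_modularity_oracle <- function(edges, wt) {
  nodes <- sort(unique(c(edges$og_a, edges$og_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(edges$og_a, edges$og_b, weight = edges$weight),
    directed = FALSE, vertices = nodes
  )
  merges <- wt$merges
  stopifnot(nrow(merges) > 0, length(unique(merges$component)) == 1)
  n <- nrow(merges) + 1L
  comm <- seq_len(n)  # initial singleton communities, walktrap's indexing
  qs <- numeric(nrow(merges) + 1L)
  # node i corresponds to community i; walktrap numbers component nodes
  # in sorted order
  part_q <- function(comm_vec) {
    igraph::modularity(g, membership = as.integer(factor(comm_vec)),
                       weights = igraph::E(g)$weight)
  }
  qs[1] <- part_q(comm)
  for (s in seq_len(nrow(merges))) {
    comm[comm %in% c(merges$comm_a[s], merges$comm_b[s])] <-
      merges$new_comm[s]
    qs[s + 1L] <- part_q(comm)
  }
  max(qs)
}

# Small fully-manual elution builder: one experiment, rows given as a
# named list of count vectors.
toy_elution <- function(rows, experiment = "e1", species = "sp01") {
  purrr::map_dfr(names(rows), function(og) {
    tibble::tibble(og_id = og, experiment_id = experiment,
                   species_id = species,
                   fraction = seq_along(rows[[og]]),
                   psm = as.numeric(rows[[og]]))
  })
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  x[sample.int(length(x))]
}

two_triangles_graph <- function() {
  tibble::tibble(
    og_a = c("a", "a", "b", "d", "d", "e", "c"),
    og_b = c("b", "c", "c", "e", "f", "f", "d"),
    weight = 1
  )
}

small_study <- function(seed = 11, ...) {
  cfg <- simulation_config(
    n_species = 4, n_ogs = 120, n_complexes = 15,
    n_fractions_per_experiment = 30, n_experiments_per_species = 2,
    disease_set_size = 5, disease_coherence = 1, seed = seed, ...
  )
  simulate_cfms_study(cfg)
}
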