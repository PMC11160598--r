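#' Build a weighted interaction graph from a scored network
#'
#' Keeps edges whose q-value is at or below `q_max` (default: the 10% FDR
#' operating point), drops isolated nodes, and uses classifier scores as
#' edge weights.
#'
#' @param scored_network Tibble (`og_a`, `og_b`, `score`, `q_value`).
#' @param q_max Maximum q-value for an edge, in (0, 1].
#' @return An edge tibble (`og_a`, `og_b`, `weight`).
#' @export
build_graph <- function(scored_network, q_max = 0.10) {
  if (q_max <= 0 || q_max > 1) stop("`q_max` must be in (0, 1]",
                                    call. = FALSE)
  edges <- scored_network |>
    dplyr::filter(.data$q_value <= q_max, .data$og_a != .data$og_b) |>
    dplyr::transmute(.data$og_a, .data$og_b, weight = .data$score)
  if (nrow(edges) == 0L) stop("no edges pass the q-value cutoff",
                              call. = FALSE)
  edges
}

#' Weighted modularity of a node partition
#'
#' Modularity compares the edge weight that falls within communities to
#' its expectation under a degree-preserving random rewiring:
#' `Q = sum_c (w_c / m - (S_c / 2m)^2)` where `m` is the total edge
#' weight, `w_c` the weight inside community c and `S_c` the summed node
#' strengths of c.
#'
#' @param edges Edge tibble (`og_a`, `og_b`, `weight`).
#' @param partition Tibble (`node`, `cluster`).
#' @return A single number.
#' @export
graph_modularity <- function(edges, partition) {
  cl <- setNames(partition$cluster, partition$node)
  m <- sum(edges$weight)
  ca <- cl[edges$og_a]
  cb <- cl[edges$og_b]
  w_in <- tapply(edges$weight[ca == cb], ca[ca == cb], sum)
  strength <- tapply(c(edges$weight, edges$weight),
                     c(edges$og_a, edges$og_b), sum)
  s_node <- strength[partition$node]
  s_node[is.na(s_node)] <- 0
  S_c <- tapply(s_node, cl[partition$node], sum)
  sum(unlist(w_in)) / m - sum((S_c / (2 * m))^2)
}

# connected components of an edge list; returns list of node-name vectors
edge_components <- function(edges, nodes) {
  adj <- split(c(edges$og_b, edges$og_a), c(edges$og_a, edges$og_b))
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    queue <- start
    seen[[start]] <- TRUE
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adj[[v]] %||% character(0)) {
        if (!seen[[u]]) {
          seen[[u]] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Random-walk (walktrap) community detection
#'
#' Implements the walktrap algorithm from first principles on a weighted
#' undirected graph. Transition probabilities are proportional to edge
#' weights; each vertex is represented by its `walk_length`-step
#' random-walk distribution, and the squared distance between two
#' communities is the degree-normalized Euclidean distance between their
#' (size-averaged) walk distributions. Communities are merged
#' agglomeratively, always choosing the adjacent pair whose merge gives
#' the smallest Ward-style increase in within-community walk variance
#' (ties broken by the lexicographically smallest pair of community
#' labels, a community being labelled by its smallest member). The
#' returned partition is the dendrogram cut with maximal weighted
#' modularity. Connected components are processed independently; their
#' dendrogram cuts are chosen against the global modularity and the
#' partitions concatenated.
#'
#' @param edges Edge tibble (`og_a`, `og_b`, `weight` > 0), a simple
#'   undirected graph without self-loops.
#' @param walk_length Random-walk length (default 4, >= 2).
#' @return An object of class `"walktrap_partition"`: a list with
#'   `partition` (tibble `node`, `cluster`), `n_communities`,
#'   `modularity` (of the chosen partition), `merges` (tibble of merge
#'   steps with per-step modularity), and `walk_length`.
#' @export
#' @examples
#' tri2 <- tibble::tibble(
#'   og_a = c("a", "a", "b", "d", "d", "e", "c"),
#'   og_b = c("b", "c", "c", "e", "f", "f", "d"),
#'   weight = 1)
#' walktrap(tri2)$partition
walktrap <- function(edges, walk_length = 4L) {
  if (walk_length < 2) stop("`walk_length` must be >= 2", call. = FALSE)
  if (any(edges$weight <= 0)) stop("edge weights must be > 0", call. = FALSE)
  if (any(edges$og_a == edges$og_b)) stop("self-loops not allowed",
                                          call. = FALSE)
  nodes <- sort(unique(c(edges$og_a, edges$og_b)))
  m_global <- sum(edges$weight)
  comps <- edge_components(edges, nodes)
  parts <- list()
  merges <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    sub <- edges[edges$og_a %in% comp & edges$og_b %in% comp, ]
    res <- wt_component(comp, sub, m_global, walk_length)
    res$partition$cluster <- sprintf("comp%d_%s", ci, res$partition$cluster)
    parts[[ci]] <- res$partition
    if (nrow(res$merges) > 0) {
      res$merges$component <- ci
      merges[[length(merges) + 1L]] <- res$merges
    }
  }
  partition <- dplyr::bind_rows(parts)
  # relabel clusters deterministically by smallest member
  relabel <- partition |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(key = min(.data$node), .groups = "drop") |>
    dplyr::arrange(.data$key)
  relabel$new <- sprintf("c%03d", seq_len(nrow(relabel)))
  partition$cluster <- relabel$new[match(partition$cluster, relabel$cluster)]
  structure(
    list(
      partition = dplyr::arrange(partition, .data$node),
      n_communities = dplyr::n_distinct(partition$cluster),
      modularity = graph_modularity(edges, partition),
      merges = if (length(merges)) dplyr::bind_rows(merges) else tibble(),
      walk_length = walk_length
    ),
    class = "walktrap_partition"
  )
}

#' @export
print.walktrap_partition <- function(x, ...) {
  cat(sprintf("<walktrap_partition> %d nodes, %d communities, Q=%.4f\n",
              nrow(x$partition), x$n_communities, x$modularity))
  invisible(x)
}

#' @export
tidy.walktrap_partition <- function(x, ...) x$partition

# Walktrap on one connected component. `m_global` is the total edge weight
# of the full graph, so per-component best cuts maximize global modularity.
wt_component <- function(comp, sub, m_global, walk_length) {
  n <- length(comp)
  if (n == 1L) {
    return(list(partition = tibble(node = comp, cluster = comp),
                merges = tibble()))
  }
  W <- matrix(0, n, n, dimnames = list(comp, comp))
  ia <- match(sub$og_a, comp)
  ib <- match(sub$og_b, comp)
  W[cbind(ia, ib)] <- W[cbind(ia, ib)] + sub$weight
  W[cbind(ib, ia)] <- W[cbind(ib, ia)] + sub$weight
  d <- rowSums(W)
  P <- W / d
  Pt <- P
  for (i in seq_len(walk_length - 1L)) Pt <- Pt %*% P

  max_c <- 2L * n - 1L
  Pc <- matrix(0, max_c, n)
  Pc[seq_len(n), ] <- Pt
  sz <- integer(max_c); sz[seq_len(n)] <- 1L
  S <- numeric(max_c); S[seq_len(n)] <- d
  w_in <- numeric(max_c)
  Wc <- matrix(0, max_c, max_c)
  Wc[seq_len(n), seq_len(n)] <- W
  active <- logical(max_c); active[seq_len(n)] <- TRUE
  minname <- character(max_c); minname[seq_len(n)] <- comp

  dsig <- matrix(Inf, max_c, max_c)
  pair_dsig <- function(i, j) {
    (sz[i] * sz[j] / (sz[i] + sz[j])) *
      sum((Pc[i, ] - Pc[j, ])^2 / d) / n
  }
  init_pairs <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(init_pairs))) {
    i <- init_pairs[r, 1]; j <- init_pairs[r, 2]
    dsig[i, j] <- pair_dsig(i, j)
  }

  q_term <- function(c) w_in[c] / m_global - (S[c] / (2 * m_global))^2
  Q <- sum(vapply(seq_len(n), q_term, numeric(1)))
  q_steps <- Q  # Q at step 0 (all singletons)

  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    cand <- which(dsig == min(dsig), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys1 <- pmin(minname[cand[, 1]], minname[cand[, 2]])
      keys2 <- pmax(minname[cand[, 1]], minname[cand[, 2]])
      cand <- cand[order(keys1, keys2)[1], , drop = FALSE]
    }
    a <- cand[1, 1]; b <- cand[1, 2]
    new <- n + step
    delta <- dsig[a, b]
    Pc[new, ] <- (sz[a] * Pc[a, ] + sz[b] * Pc[b, ]) / (sz[a] + sz[b])
    sz[new] <- sz[a] + sz[b]
    S[new] <- S[a] + S[b]
    w_in[new] <- w_in[a] + w_in[b] + Wc[a, b]
    Wc[new, ] <- Wc[a, ] + Wc[b, ]
    Wc[, new] <- Wc[new, ]
    Wc[new, new] <- 0
    Q <- Q + q_term(new) - q_term(a) - q_term(b)
    active[a] <- FALSE; active[b] <- FALSE; active[new] <- TRUE
    minname[new] <- min(minname[a], minname[b])
    dsig[c(a, b), ] <- Inf
    dsig[, c(a, b)] <- Inf
    nbr <- which(active & Wc[new, ] > 0)
    nbr <- setdiff(nbr, new)
    for (x in nbr) {
      dsig[min(x, new), max(x, new)] <- pair_dsig(x, new)
    }
    merges[[step]] <- tibble(step = step, comm_a = a, comm_b = b,
                             new_comm = new, delta_sigma = delta,
                             modularity = Q)
    q_steps <- c(q_steps, Q)
  }
  best_step <- which.max(q_steps) - 1L  # 0-based: number of merges applied

  # replay merges to reconstruct the chosen partition
  comm <- seq_len(n)
  if (best_step > 0) {
    for (s in seq_len(best_step)) {
      mg <- merges[[s]]
      comm[comm %in% c(mg$comm_a, mg$comm_b)] <- mg$new_comm
    }
  }
  cluster <- vapply(split(comp, comm), min, character(1))[as.character(comm)]
  list(
    partition = tibble(node = comp, cluster = unname(cluster)),
    merges = dplyr::bind_rows(merges)
  )
}
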