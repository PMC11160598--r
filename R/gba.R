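# Cross-validated network guilt-by-association for disease-gene
# prioritization: degree-normalized neighbor voting, leave-one-out AUROC,
# random-set baselines, and candidate ranking.

gba_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges$og_a, edges$og_b)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ia <- match(edges$og_a, nodes)
  ib <- match(edges$og_b, nodes)
  A[cbind(ia, ib)] <- A[cbind(ia, ib)] + edges$weight
  A[cbind(ib, ia)] <- A[cbind(ib, ia)] + edges$weight
  A
}

#' Degree-normalized neighbor-voting scores
#'
#' Scores every node by the fraction of its edge weight that connects to
#' the seed set: `score(g) = sum of weights from g to seeds / total edge
#' weight of g`. Seeds are scored by the same formula excluding
#' themselves; isolated nodes score 0. Scores are invariant to uniform
#' rescaling of the edge weights.
#'
#' @param edges Edge tibble (`og_a`, `og_b`, `weight`).
#' @param seed_genes Nonempty character vector of seed nodes (must be in
#'   the graph).
#' @return A tibble (`node`, `score`, `is_seed`).
#' @export
neighbor_voting <- function(edges, seed_genes) {
  if (length(seed_genes) == 0L) stop("`seed_genes` must be nonempty",
                                     call. = FALSE)
  A <- gba_adjacency(edges)
  nodes <- rownames(A)
  seeds <- intersect(seed_genes, nodes)
  if (length(seeds) == 0L) stop("no seed gene is in the graph",
                                call. = FALSE)
  strength <- rowSums(A)
  seed_w <- rowSums(A[, seeds, drop = FALSE])
  score <- ifelse(strength > 0, seed_w / strength, 0)
  tibble(node = nodes, score = unname(score),
         is_seed = nodes %in% seeds)
}

# Internal fast path: LOO neighbor-voting AUROCs for one gene set against
# a precomputed adjacency matrix.
loocv_auroc_matrix <- function(A, genes) {
  nodes <- rownames(A)
  genes <- intersect(genes, nodes)
  if (length(genes) < 3L) return(NA_real_)
  strength <- rowSums(A)
  others <- setdiff(nodes, genes)
  seed_w_full <- rowSums(A[, genes, drop = FALSE])
  per_gene <- vapply(genes, function(g) {
    seed_w <- seed_w_full - A[, g]
    sc <- ifelse(strength > 0, seed_w / strength, 0)
    s_g <- sc[[g]]
    s_other <- sc[others]
    # midrank Mann-Whitney: P(held-out gene outranks a random negative)
    (sum(s_other < s_g) + 0.5 * sum(s_other == s_g)) / length(s_other)
  }, numeric(1))
  mean(per_gene)
}

#' Leave-one-out cross-validated AUROC of a gene set
#'
#' For each annotated gene, removes it from the seed set, recomputes
#' neighbor-voting scores, and compares the held-out gene's score against
#' the scores of all unannotated nodes. The AUROC is the midrank
#' Mann-Whitney statistic — the probability that a held-out gene outranks
#' a random unannotated node — averaged over the held-out genes.
#'
#' @param edges Edge tibble (`og_a`, `og_b`, `weight`).
#' @param gene_set Character vector; at least 3 members must map into the
#'   graph, otherwise NA is returned with a warning.
#' @return A single AUROC in \[0, 1\] (NA if fewer than 3 genes map).
#' @export
loocv_auroc <- function(edges, gene_set) {
  A <- gba_adjacency(edges)
  out <- loocv_auroc_matrix(A, gene_set)
  if (is.na(out)) {
    warning("fewer than 3 genes map into the network; AUROC is NA")
  }
  out
}

#' AUROC distribution of random gene sets
#'
#' Draws `n_reps` random gene sets of `set_size` (optionally matched to
#' the degree profile of a reference set by stratified sampling over
#' degree bins) and evaluates each by [loocv_auroc()]. Random sets have no
#' relation to the network structure, so their AUROCs distribute around
#' 0.5.
#'
#' @param edges Edge tibble.
#' @param set_size Genes per random set.
#' @param n_reps Number of random sets (>= 50).
#' @param seed Integer seed.
#' @param degree_matched Optional character vector: a reference gene set
#'   whose degree profile the random sets should match.
#' @return A list with `aurocs` (length `n_reps`), `mean`, and `sd`.
#' @export
random_baseline <- function(edges, set_size, n_reps = 200L, seed = 1L,
                            degree_matched = NULL) {
  if (n_reps < 50) stop("`n_reps` must be >= 50", call. = FALSE)
  A <- gba_adjacency(edges)
  nodes <- rownames(A)
  if (set_size > length(nodes)) {
    stop("`set_size` exceeds the number of network nodes", call. = FALSE)
  }
  if (set_size >= length(nodes) - 1L) {
    warning("degenerate set size: almost every node is a seed")
  }
  draw <- if (is.null(degree_matched)) {
    function() sample(nodes, set_size)
  } else {
    deg <- rowSums(A > 0)
    brk <- unique(quantile(deg, probs = seq(0, 1, 0.2)))
    bin_of <- cut(deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    ref_bins <- bin_of[match(intersect(degree_matched, nodes), nodes)]
    function() {
      unlist(lapply(sample(ref_bins, set_size, replace = TRUE),
                    function(b) sample(nodes[bin_of == b], 1L)))
    }
  }
  aurocs <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      loocv_auroc_matrix(A, draw())
    }, numeric(1))
  })
  list(aurocs = aurocs, mean = mean(aurocs, na.rm = TRUE),
       sd = sd(aurocs, na.rm = TRUE))
}

#' Rank disease-gene candidates by guilt-by-association
#'
#' Evaluates every disease gene set by leave-one-out AUROC; diseases at or
#' above `auroc_threshold` (default 0.7) are flagged prediction-worthy.
#' For those, unannotated genes are ranked by full-seed neighbor-voting
#' score, with ties broken by node degree and then lexicographically.
#'
#' @param edges Edge tibble.
#' @param disease_sets Tibble (`disease_id`, `gene_id`); an optional
#'   `is_null` column is carried through.
#' @param auroc_threshold AUROC flag threshold in (0.5, 1).
#' @param max_candidates Candidates reported per flagged disease.
#' @return A list of class `"gba_result"`: `diseases`, a tibble
#'   (`disease_id`, `n_genes`, `n_mapped`, `auroc`, `pass`), and
#'   `candidates`, a tibble (`disease_id`, `gene_id`, `score`, `rank`)
#'   for flagged diseases only.
#' @export
rank_candidates <- function(edges, disease_sets, auroc_threshold = 0.7,
                            max_candidates = 20L) {
  if (auroc_threshold <= 0.5 || auroc_threshold >= 1) {
    stop("`auroc_threshold` must be in (0.5, 1)", call. = FALSE)
  }
  A <- gba_adjacency(edges)
  nodes <- rownames(A)
  strength <- rowSums(A)
  degree <- rowSums(A > 0)
  sets <- split(disease_sets$gene_id, disease_sets$disease_id)
  diseases <- purrr::map_dfr(names(sets), function(d) {
    genes <- unique(sets[[d]])
    mapped <- intersect(genes, nodes)
    auroc <- loocv_auroc_matrix(A, mapped)
    tibble(disease_id = d, n_genes = length(genes),
           n_mapped = length(mapped), auroc = auroc,
           pass = !is.na(auroc) && auroc >= auroc_threshold)
  })
  candidates <- purrr::map_dfr(
    diseases$disease_id[diseases$pass],
    function(d) {
      genes <- intersect(unique(sets[[d]]), nodes)
      seed_w <- rowSums(A[, genes, drop = FALSE])
      sc <- ifelse(strength > 0, seed_w / strength, 0)
      cand <- setdiff(nodes, genes)
      ord <- order(-sc[cand], -degree[cand], cand)
      take <- head(ord, max_candidates)
      tibble(disease_id = d, gene_id = cand[take],
             score = unname(sc[cand[take]]),
             rank = seq_along(take))
    }
  )
  structure(list(diseases = diseases, candidates = candidates,
                 auroc_threshold = auroc_threshold),
            class = "gba_result")
}

#' @export
print.gba_result <- function(x, ...) {
  cat(sprintf("<gba_result> %d diseases, %d pass AUROC >= %.2f\n",
              nrow(x$diseases), sum(x$diseases$pass), x$auroc_threshold))
  invisible(x)
}

#' @export
tidy.gba_result <- function(x, ...) x$diseases

#' @export
glance.gba_result <- function(x, ...) {
  tibble(n_diseases = nrow(x$diseases), n_pass = sum(x$diseases$pass),
         mean_auroc = mean(x$diseases$auroc, na.rm = TRUE),
         auroc_threshold = x$auroc_threshold)
}
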