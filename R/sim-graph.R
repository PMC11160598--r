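#' Simulate a weighted interaction network with planted complexes
#'
#' Draws a random graph over the complex members (plus optional background
#' nodes): node pairs within a complex are connected with probability
#' `p_within`, pairs whose complexes share a module (when `modules` is
#' given) with `p_module`, and all remaining pairs with `p_between`. Edge
#' weights mimic classifier confidence scores: uniform on `w_within` for
#' within-complex edges and on `w_between` otherwise.
#'
#' Used to test community detection and guilt-by-association directly,
#' without running the full scoring pipeline.
#'
#' @param complexes Tibble (`complex_id`, `og_id`).
#' @param p_within,p_between,p_module Edge probabilities.
#' @param modules Optional tibble (`complex_id`, `module_id`) nesting
#'   complexes into super-modules.
#' @param n_background Extra unassigned nodes appended to the universe.
#' @param w_within,w_between Length-2 uniform weight ranges.
#' @param seed Integer seed.
#' @return An edge tibble (`og_a`, `og_b`, `weight`).
#' @export
simulate_planted_graph <- function(complexes, p_within = 0.9,
                                   p_between = 0.01, modules = NULL,
                                   p_module = 0.3, n_background = 0,
                                   w_within = c(0.6, 1), w_between = c(0.05, 0.3),
                                   seed = 1L) {
  nodes <- unique(complexes$og_id)
  if (n_background > 0) {
    nodes <- c(nodes, sprintf("bg%04d", seq_len(n_background)))
  }
  cpx_of <- setNames(complexes$complex_id, complexes$og_id)
  mod_of <- if (!is.null(modules)) {
    setNames(modules$module_id, modules$complex_id)
  } else NULL
  with_seed(seed, {
    idx <- combn(length(nodes), 2)
    a <- nodes[idx[1, ]]
    b <- nodes[idx[2, ]]
    ca <- unname(cpx_of[a]); cb <- unname(cpx_of[b])
    same_cpx <- !is.na(ca) & !is.na(cb) & ca == cb
    same_mod <- if (!is.null(mod_of)) {
      !same_cpx & !is.na(ca) & !is.na(cb) &
        mod_of[ca] == mod_of[cb]
    } else rep(FALSE, length(a))
    p <- ifelse(same_cpx, p_within, ifelse(same_mod, p_module, p_between))
    keep <- runif(length(p)) < p
    w <- ifelse(same_cpx[keep],
                runif(sum(keep), w_within[1], w_within[2]),
                runif(sum(keep), w_between[1], w_between[2]))
    dplyr::bind_cols(canonical_pairs(a[keep], b[keep]), tibble(weight = w))
  })
}
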