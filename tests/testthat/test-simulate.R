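test_that("species trees are rooted, binary, labelled, and reproducible", {
  tr2 <- simulate_species_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)  # a cherry: both leaves children of the root

  tr <- simulate_species_tree(8, seed = 1)
  expect_equal(ape::Ntip(tr), 8)
  expect_equal(tr$Nnode, 7)  # rooted binary: n - 1 internal nodes
  kid_counts <- table(tr$edge[, 1])
  expect_true(all(kid_counts == 2))
  expect_equal(sort(unique(unname(tr$supergroup))),
               sort(c("Amorphea", "Excavata", "TSAR", "Archaeplastida")))

  again <- simulate_species_tree(8, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(again))
  expect_error(simulate_species_tree(1), "n_species")
})

test_that("supergroup labels are assigned by clade", {
  tr <- simulate_species_tree(10, seed = 3)
  # each supergroup's species must form a monophyletic clade
  for (sg in unique(tr$supergroup)) {
    tips <- names(tr$supergroup)[tr$supergroup == sg]
    if (length(tips) == 1) next
    expect_true(ape::is.monophyletic(tr, tips))
  }
})

test_that("presence/absence evolution respects the gain/loss model", {
  tr <- simulate_species_tree(6, seed = 2)
  all_on <- simulate_presence_absence(tr, 15, loss_rate = 0,
                                      root_fraction = 1, seed = 4)
  expect_true(all(as.matrix(all_on$presence[, -1]) == 1))
  expect_true(all(all_on$gain_nodes$gain_node == "n7"))

  all_off <- simulate_presence_absence(tr, 15, loss_rate = 1, seed = 4)
  expect_true(all(as.matrix(all_off$presence[, -1]) == 0))

  expect_error(
    simulate_presence_absence(ape::unroot(ape::rtree(5)), 5, 0.1),
    "rooted"
  )
})

test_that("presence patterns are Dollo-consistent with recorded gains", {
  tr <- simulate_species_tree(7, seed = 5)
  pa <- simulate_presence_absence(tr, 200, loss_rate = 0.3, seed = 6)
  mat <- as.matrix(pa$presence[, -1])
  nm <- c(tr$tip.label, tr$node.label)
  leaf_sets <- lapply(seq_len(ape::Ntip(tr) + tr$Nnode), function(v) {
    if (v <= ape::Ntip(tr)) tr$tip.label[v]
    else ape::extract.clade(tr, v)$tip.label
  })
  names(leaf_sets) <- nm
  for (i in seq_len(nrow(mat))) {
    carriers <- colnames(mat)[mat[i, ] == 1]
    clade <- leaf_sets[[pa$gain_nodes$gain_node[i]]]
    expect_true(all(carriers %in% clade))
  }
})

test_that("noiseless complex members co-elute perfectly", {
  cfg <- simulation_config(
    n_species = 2, n_ogs = 30, n_complexes = 5,
    complex_size_range = c(3, 5), n_fractions_per_experiment = 40,
    peak_jitter = 0, noise_rate = 0, dropout_rate = 0,
    abundance_mean = 500, seed = 9
  )
  cpx <- simulate_complexes(sprintf("og%04d", 1:30), 5, c(3, 5), seed = 9)
  el <- simulate_elution_experiment(cpx, sprintf("og%04d", 1:30), cfg,
                                    seed = 10)
  expected <- attr(el, "expected")
  by_cpx <- split(cpx$og_id, cpx$complex_id)
  for (members in by_cpx) {
    prs <- utils::combn(members, 2)
    for (j in seq_len(ncol(prs))) {
      r_exp <- cor(expected[prs[1, j], ], expected[prs[2, j], ])
      expect_equal(r_exp, 1, tolerance = 1e-12)
      # Poisson-sampled profiles stay tightly correlated at high abundance
      m <- elution_block_matrix(el, unique(el$experiment_id))
      r_obs <- cor(m[prs[1, j], ], m[prs[2, j], ])
      expect_gt(r_obs, 0.95)
    }
  }
})

test_that("within-complex correlation exceeds between-complex correlation", {
  sim <- small_study(seed = 21)
  eid <- sim$experiments$experiment_id[1]
  m <- elution_block_matrix(sim$elution, eid)
  cpx_of <- setNames(sim$complexes$complex_id, sim$complexes$og_id)
  ogs <- intersect(rownames(m), names(cpx_of))
  m <- m[ogs, ]
  cm <- suppressWarnings(cor(t(m)))
  same <- outer(cpx_of[ogs], cpx_of[ogs], "==")
  ut <- upper.tri(cm)
  within <- cm[ut & same]
  between <- cm[ut & !same]
  expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
})

test_that("elution generator handles edge cases and is deterministic", {
  cpx <- tibble::tibble(complex_id = "c1", og_id = c("a", "b"))
  cfg <- simulation_config(n_ogs = 2, n_complexes = 1,
                           n_fractions_per_experiment = 20,
                           dropout_rate = 1)
  empty <- simulate_elution_experiment(cpx, c("a", "b"), cfg, seed = 1)
  expect_equal(nrow(empty), 0)

  cfg2 <- simulation_config(n_fractions_per_experiment = 4)
  expect_error(simulate_elution_experiment(cpx, c("a", "b"), cfg2),
               "fraction")

  cfg3 <- simulation_config(n_ogs = 10, n_complexes = 2,
                            n_fractions_per_experiment = 20)
  e1 <- simulate_elution_experiment(cpx, letters[1:8], cfg3, seed = 7)
  e2 <- simulate_elution_experiment(cpx, letters[1:8], cfg3, seed = 7)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("purification recovery tracks the detection probability", {
  cpx <- simulate_complexes(sprintf("og%04d", 1:60), 10, c(5, 7), seed = 3)
  ap <- simulate_apms(cpx, n_baits = 300, detect_prob = 0.8, seed = 4,
                      background_rate = 0)
  by_pur <- split(ap, ap$purification_id)
  recovery <- vapply(by_pur, function(df) {
    mates <- setdiff(cpx$og_id[cpx$complex_id == df$bait_complex[1]],
                     df$bait_id[1])
    length(intersect(df$prey_id, mates)) / length(mates)
  }, numeric(1))
  expect_equal(mean(recovery), 0.8, tolerance = 0.05)

  full <- simulate_apms(cpx, n_baits = 20, detect_prob = 1, seed = 5,
                        background_rate = 0)
  for (df in split(full, full$purification_id)) {
    members <- cpx$og_id[cpx$complex_id == df$bait_complex[1]]
    expect_setequal(df$prey_id, members)
  }
  expect_error(simulate_apms(cpx, n_baits = 0, detect_prob = 1), "n_baits")
  expect_error(simulate_apms(cpx[0, ], 5, 1), "nonempty")
})

test_that("disease sets respect the coherence parameter exactly", {
  cpx <- simulate_complexes(sprintf("og%04d", 1:80), 8, c(8, 12), seed = 2)
  ds <- simulate_disease_sets(cpx, n_diseases = 10, set_size = 10,
                              coherence = 0.8, seed = 3,
                              gene_universe = sprintf("og%04d", 1:200))
  coherent <- dplyr::filter(ds, !is_null)
  for (d in split(coherent, coherent$disease_id)) {
    expect_equal(nrow(d), 10)
    core <- d[!is.na(d$source_complex), ]
    expect_equal(nrow(core), 8)  # round(0.8 * 10) from one complex
    expect_equal(length(unique(core$source_complex)), 1)
    members <- cpx$og_id[cpx$complex_id == core$source_complex[1]]
    expect_true(all(core$gene_id %in% members))
  }
  nulls <- dplyr::filter(ds, is_null)
  expect_equal(dplyr::n_distinct(nulls$disease_id), 10)

  full <- simulate_disease_sets(cpx, 5, set_size = 8, coherence = 1,
                                seed = 4)
  for (d in split(full[!full$is_null, ],
                  full$disease_id[!full$is_null])) {
    members <- cpx$og_id[cpx$complex_id == d$source_complex[1]]
    expect_true(all(d$gene_id %in% members))
  }
  expect_error(simulate_disease_sets(cpx, 2, set_size = 2, coherence = 1),
               "set_size")
})

test_that("a fixed seed reproduces the whole study byte-for-byte", {
  cfg <- simulation_config(n_species = 3, n_ogs = 40, n_complexes = 6,
                           n_fractions_per_experiment = 20,
                           disease_set_size = 4, seed = 13)
  s1 <- simulate_cfms_study(cfg)
  s2 <- simulate_cfms_study(cfg)
  expect_identical(as.data.frame(s1$elution), as.data.frame(s2$elution))
  expect_identical(s1$presence, s2$presence)
  expect_identical(s1$apms, s2$apms)
  expect_identical(s1$diseases, s2$diseases)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})
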