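make_complexes <- function(members) {
  purrr::imap_dfr(members, function(m, i) {
    tibble::tibble(complex_id = paste0("cpx", i), og_id = m)
  })
}

# labeled synthetic features: one informative dimension separates classes
labeled_toy <- function(n_groups = 20, per_group = 6, seed = 1,
                        informative = TRUE) {
  set.seed(seed)
  members <- lapply(seq_len(n_groups), function(i) {
    sprintf("g%02d_%s", i, letters[seq_len(per_group)])
  })
  cpx <- make_complexes(members)
  lab <- build_reference_labels(cpx, negative_ratio = 3, seed = seed)
  mu <- if (informative) 2 else 0
  lab$signal <- rnorm(nrow(lab), mean = mu * lab$label)
  lab$noise1 <- rnorm(nrow(lab))
  lab$noise2 <- rnorm(nrow(lab))
  lab
}

test_that("reference labels enumerate positives and exclude co-members", {
  cpx <- make_complexes(list(c("A", "B", "C"), c("D", "E")))
  lab <- build_reference_labels(cpx, negative_ratio = 100, seed = 1)
  pos <- lab[lab$label == 1, ]
  expect_setequal(paste(pos$og_a, pos$og_b),
                  c("A B", "A C", "B C", "D E"))
  neg <- lab[lab$label == 0, ]
  expect_equal(nrow(neg), 6)  # all cross pairs eligible
  expect_true(all(interaction(neg$og_a, neg$og_b) %in%
                    interaction(c("A", "A", "B", "B", "C", "C"),
                                c("D", "E", "D", "E", "D", "E"))))
  expect_error(build_reference_labels(cpx[1:3, ]), "2 reference")
})

test_that("complexes sharing members merge into one leakage group", {
  cpx <- make_complexes(list(c("A", "B"), c("B", "C")))
  lab <- build_reference_labels(cpx, negative_ratio = 10, seed = 1)
  expect_equal(dplyr::n_distinct(c(lab$group_a, lab$group_b)), 1)
  # BC is a positive (within complex 2), so it can never be a negative
  bc <- lab[lab$og_a == "B" & lab$og_b == "C", ]
  expect_equal(bc$label, 1L)
})

test_that("negatives never intersect positives across random references", {
  set.seed(2)
  members <- lapply(1:20, function(i) {
    sample(sprintf("og%03d", 1:120), sample(3:6, 1))
  })
  lab <- build_reference_labels(make_complexes(members),
                                negative_ratio = 5, seed = 3)
  keys <- paste(lab$og_a, lab$og_b)
  expect_equal(length(intersect(keys[lab$label == 1],
                                keys[lab$label == 0])), 0)
  expect_equal(anyDuplicated(keys), 0)
})

test_that("complex-level splits are leakage-free", {
  lab <- labeled_toy(n_groups = 50, seed = 4)
  sp <- split_by_complex(lab, test_fraction = 0.3, seed = 5)
  train_ogs <- unique(c(sp$og_a[sp$fold == "train"],
                        sp$og_b[sp$fold == "train"]))
  test_ogs <- unique(c(sp$og_a[sp$fold == "test"],
                       sp$og_b[sp$fold == "test"]))
  expect_equal(length(intersect(train_ogs, test_ogs)), 0)
  frac <- mean(sp$fold[sp$fold != "discard"] == "test")
  expect_lt(abs(frac - 0.3), 0.05 + 1e-9)

  two <- labeled_toy(n_groups = 2, seed = 6)
  sp2 <- split_by_complex(two, 0.5, seed = 7)
  expect_setequal(unique(sp2$fold[sp2$label == 1]), c("train", "test"))

  one <- make_complexes(list(c("A", "B", "C"), c("A", "D")))
  lab1 <- build_reference_labels(one, seed = 1)
  expect_error(split_by_complex(lab1, 0.5), "single complex group")
})

test_that("stratification caps negatives per stratum and keeps positives", {
  lab <- labeled_toy(n_groups = 30, seed = 8)
  sp <- split_by_complex(lab, 0.3, seed = 8)
  st <- stratify_training(sp, ratio = 2, seed = 9)
  train <- st[st$fold == "train", ]
  tallies <- train |>
    dplyr::mutate(stratum = pmin(group_a, group_b)) |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(n_pos = sum(label == 1), n_neg = sum(label == 0))
  expect_true(all(tallies$n_neg <= 2 * tallies$n_pos))
  expect_true(all(tallies$n_pos >= 1))
  # positives preserved
  expect_equal(sum(train$label), sum(sp$label[sp$fold == "train"]))
  # test fold untouched
  expect_equal(sum(st$fold == "test"), sum(sp$fold == "test"))

  pos_only <- stratify_training(sp, ratio = 0, seed = 9)
  expect_true(all(pos_only$label[pos_only$fold == "train"] == 1))
})

test_that("feature ranking puts the separator first for every family", {
  lab <- labeled_toy(seed = 10)
  for (fam in c("linear_svm", "extra_trees", "sgd_logistic")) {
    rk <- rank_features(lab, fam, features = c("signal", "noise1", "noise2"),
                        seed = 2)
    expect_equal(rk$feature[1], "signal")
  }
  # constant feature ranked last and flagged
  lab$flat <- 1
  rk <- rank_features(lab, "linear_svm",
                      features = c("signal", "noise1", "flat"), seed = 2)
  expect_equal(rk$feature[3], "flat")
  expect_true(rk$constant[3])
})

test_that("classifiers separate planted signal and score deterministically", {
  lab <- labeled_toy(n_groups = 40, seed = 11)
  sp <- split_by_complex(lab, 0.3, seed = 11)
  train <- sp[sp$fold == "train", ]
  test <- sp[sp$fold == "test", ]
  for (fam in c("linear_svm", "extra_trees", "sgd_logistic")) {
    m <- fit_ppi_classifier(train, fam, seed = 3)
    s1 <- predict(m, test)
    s2 <- predict(m, test)
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
    pr <- pr_curve(dplyr::mutate(test, score = s1))
    expect_gt(recall_at_precision(pr, 0.9), 0.5)
  }
  m1 <- fit_ppi_classifier(train, "linear_svm", seed = 3)
  m2 <- fit_ppi_classifier(train, "linear_svm", seed = 3)
  expect_identical(predict(m1, test), predict(m2, test))

  tt <- tidy(m1)
  expect_equal(tt$feature[which.max(abs(tt$estimate))], "signal")
  gl <- glance(m1)
  expect_equal(gl$family, "linear_svm")
})

test_that("the feature sweep reports recall at the precision floor", {
  lab <- labeled_toy(n_groups = 40, seed = 12)
  sp <- split_by_complex(lab, 0.3, seed = 12)
  sw <- evaluate_feature_sweep(sp[sp$fold == "train", ],
                               sp[sp$fold == "test", ],
                               "linear_svm", feature_counts = c(1, 3),
                               seed = 4)
  expect_equal(sw$n_features, c(1, 3))
  expect_true(all(sw$recall_at_precision >= 0 &
                    sw$recall_at_precision <= 1))
  expect_gt(sw$recall_at_precision[1], 0.5)  # separator alone suffices
  expect_warning(
    evaluate_feature_sweep(sp[sp$fold == "train", ],
                           sp[sp$fold == "test", ], "linear_svm",
                           feature_counts = c(2, 50), seed = 4),
    "clamped")
})

test_that("precision-recall bookkeeping is monotone where it must be", {
  set.seed(13)
  scored <- tibble::tibble(score = runif(400),
                           label = rbinom(400, 1, 0.3))
  pr <- pr_curve(scored)
  expect_true(all(diff(pr$recall) >= 0))  # recall grows as threshold drops
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_equal(max(pr$recall), 1)
})

test_that("FDR calibration reproduces the hand-enumerated example", {
  scored <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.6, 0.5),
                           label = c(1, 1, 0, 1, 0))
  cal <- calibrate_fdr(scored, target_fdr = 0.30)
  expect_equal(cal$curve$raw_fdr, c(0, 0, 1 / 3, 1 / 4, 2 / 5))
  expect_equal(cal$curve$q_value, c(0, 0, 1 / 4, 1 / 4, 2 / 5))
  # smallest threshold whose q-value meets the target
  expect_equal(cal$threshold, 0.6)

  perfect <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                            label = c(1, 1, 0, 0))
  cal <- calibrate_fdr(perfect, 0.1)
  expect_equal(cal$threshold, 0.8)
  expect_equal(cal$curve$q_value[cal$curve$threshold == 0.8], 0)

  none <- tibble::tibble(score = c(0.9, 0.8), label = c(0, 1))
  expect_warning(cal0 <- calibrate_fdr(none, 0.05), "nothing")
  expect_true(is.na(cal0$threshold))
  expect_error(calibrate_fdr(tibble::tibble(score = 1, label = 0), 0.1),
               "no positive")
})

test_that("q-values applied to a network are monotone in score", {
  set.seed(14)
  scored <- tibble::tibble(score = runif(300),
                           label = rbinom(300, 1, plogis(-2 + 4 * runif(300))))
  scored$label <- rbinom(300, 1, plogis(6 * scored$score - 3))
  cal <- calibrate_fdr(scored, 0.1)
  net <- tibble::tibble(og_a = "x", og_b = paste0("y", 1:100),
                        score = sort(runif(100)))
  out <- apply_fdr(net, cal)
  expect_true(all(diff(out$q_value) <= 1e-12))  # higher score, lower q
  expect_true(all(out$accepted == (out$q_value <= 0.1)))
})

test_that("external agreement is enriched for true pairs and flat for noise", {
  set.seed(15)
  nodes <- sprintf("n%02d", 1:40)
  idx <- utils::combn(40, 2)
  net <- tibble::tibble(og_a = nodes[idx[1, ]], og_b = nodes[idx[2, ]],
                        score = runif(ncol(idx)))
  top <- dplyr::slice_max(net, score, n = 50)
  enr <- external_agreement(net, top[, c("og_a", "og_b")], n_bins = 5)
  expect_gt(enr$enrichment[5], 3)  # top-scoring bin maximally enriched
  expect_equal(enr$n_external[1], 0)
  expect_equal(sum(enr$n_external), 50)

  random_ext <- net[sample.int(nrow(net), 300), c("og_a", "og_b")]
  enr2 <- external_agreement(net, random_ext, n_bins = 4)
  expect_true(all(abs(enr2$enrichment - 1) < 0.35))  # Monte-Carlo tolerance
  expect_error(external_agreement(net, net[0, 1:2]), "nonempty")
})
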