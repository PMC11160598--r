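# Supervised PPI classifiers: extremely randomized trees, a linear
# max-margin SVM (the default final model), and an SGD-trained logistic
# linear model. All emit scores in [0, 1].

ppi_families <- c("linear_svm", "extra_trees", "sgd_logistic")

feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("feature columns missing from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(data[, features, drop = FALSE])
}

default_feature_columns <- function(data) {
  drop <- c("og_a", "og_b", "label", "fold", "group_a", "group_b", "score",
            "q_value", "accepted")
  nm <- setdiff(names(data), drop)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

#' Fit a supervised protein-interaction classifier
#'
#' Trains one of three classifier families on labeled pair features:
#' `"linear_svm"` (a linear max-margin support vector classifier with
#' Platt-scaled probabilities; the default final model), `"extra_trees"`
#' (an extremely randomized tree ensemble), or `"sgd_logistic"` (an
#' L2-regularized linear model trained by stochastic gradient descent on
#' the logistic loss). Features are standardized internally; constant
#' features get unit scale.
#'
#' @param data Tibble with feature columns and an integer `label` column
#'   (1 = within-complex, 0 = cross-complex).
#' @param family Classifier family.
#' @param features Character vector of feature columns (default: every
#'   numeric column that is not an identifier or label).
#' @param seed Integer seed (tree ensemble and SGD shuffling).
#' @param num_trees,cost,sgd_epochs,sgd_lambda Hyperparameters, fixed and
#'   recorded on the fitted object.
#' @return An object of class `"ppi_model"`.
#' @export
fit_ppi_classifier <- function(data, family = ppi_families, features = NULL,
                               seed = 1L, num_trees = 300L, cost = 1,
                               sgd_epochs = 40L, sgd_lambda = 1e-4) {
  family <- match.arg(family)
  features <- features %||% default_feature_columns(data)
  if (length(features) < 1) stop("no feature columns found", call. = FALSE)
  X <- feature_matrix(data, features)
  y <- as.integer(data$label)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  fit <- switch(
    family,
    extra_trees = ranger::ranger(
      x = Xs, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = num_trees, splitrule = "extratrees",
      num.random.splits = 1L, importance = "impurity", seed = seed
    ),
    linear_svm = {
      svm_fit <- e1071::svm(
        x = Xs, y = factor(y, levels = c(0, 1)), kernel = "linear",
        cost = cost, scale = FALSE
      )
      # deterministic Platt scaling: logistic map of the SVM margin
      dv <- as.vector(attr(predict(svm_fit, Xs, decision.values = TRUE),
                           "decision.values"))
      platt <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial())
      )
      list(svm = svm_fit, platt_coef = stats::coef(platt))
    },
    sgd_logistic = sgd_logistic_fit(Xs, y, epochs = sgd_epochs,
                                    lambda = sgd_lambda, seed = seed)
  )
  structure(
    list(family = family, features = features, center = ctr, scale = scl,
         fit = fit, seed = seed, n_train = nrow(Xs),
         prevalence = mean(y),
         hyperparameters = list(num_trees = num_trees, cost = cost,
                                sgd_epochs = sgd_epochs,
                                sgd_lambda = sgd_lambda)),
    class = "ppi_model"
  )
}

sgd_logistic_fit <- function(X, y, epochs = 40L, lambda = 1e-4,
                             eta0 = 0.5, seed = 1L) {
  w <- rep(0, ncol(X))
  b <- 0
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(X))) {
        t <- t + 1
        eta <- eta0 / (1 + eta0 * lambda * t)
        p <- stats::plogis(sum(X[i, ] * w) + b)
        g <- p - y[i]
        w <- w * (1 - eta * lambda) - eta * g * X[i, ]
        b <- b - eta * g
      }
    }
  })
  list(w = setNames(w, colnames(X)), b = b)
}

#' @export
predict.ppi_model <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$features)
  Xs <- scale(X, center = object$center, scale = object$scale)
  switch(
    object$family,
    extra_trees = {
      p <- predict(object$fit, data = as.data.frame(Xs))$predictions
      unname(p[, "1"])
    },
    linear_svm = {
      dv <- as.vector(attr(predict(object$fit$svm, Xs,
                                   decision.values = TRUE),
                           "decision.values"))
      b <- object$fit$platt_coef
      unname(stats::plogis(b[1] + b[2] * dv))
    },
    sgd_logistic = unname(
      stats::plogis(as.vector(Xs %*% object$fit$w) + object$fit$b)
    )
  )
}

#' @export
print.ppi_model <- function(x, ...) {
  cat(sprintf("<ppi_model> family=%s, %d features, %d training pairs\n",
              x$family, length(x$features), x$n_train))
  invisible(x)
}

#' Linear weights or tree importances of a fitted PPI classifier
#'
#' @param x A `"ppi_model"`.
#' @param ... Unused.
#' @return A tibble (`feature`, `estimate`) with standardized linear
#'   weights (linear families) or impurity importances (tree ensemble).
#' @export
tidy.ppi_model <- function(x, ...) {
  est <- switch(
    x$family,
    extra_trees = ranger::importance(x$fit)[x$features],
    linear_svm = {
      # weight vector of the separating hyperplane, oriented so that
      # positive weights push toward the positive class (the Platt slope
      # records how the margin maps to the positive-class probability)
      w <- as.vector(t(x$fit$svm$coefs) %*% x$fit$svm$SV)
      w <- w * sign(x$fit$platt_coef[2])
      setNames(w, x$features)
    },
    sgd_logistic = x$fit$w
  )
  tibble(feature = x$features, estimate = unname(est[x$features]))
}

#' One-line summary of a fitted PPI classifier
#'
#' @param x A `"ppi_model"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ppi_model <- function(x, ...) {
  tibble(family = x$family, n_features = length(x$features),
         n_train = x$n_train, prevalence = x$prevalence, seed = x$seed)
}

#' Rank features by classifier-specific importance
#'
#' Tree ensembles rank by impurity importance; linear families by the
#' absolute standardized coefficient after unit-variance scaling.
#' Constant features are ranked last and flagged; ties are broken by
#' column order.
#'
#' @param data Labeled feature tibble (with `label`).
#' @param family Classifier family.
#' @param features Feature columns (default: auto-detected).
#' @param seed Integer seed.
#' @return A tibble (`feature`, `importance`, `rank`, `constant`) sorted by
#'   rank.
#' @export
rank_features <- function(data, family = ppi_families, features = NULL,
                          seed = 1L) {
  family <- match.arg(family)
  features <- features %||% default_feature_columns(data)
  if (length(features) < 2) stop("need at least 2 features", call. = FALSE)
  X <- feature_matrix(data, features)
  constant <- apply(X, 2, sd) == 0
  model <- fit_ppi_classifier(data, family, features = features, seed = seed)
  imp <- abs(tidy(model)$estimate)
  imp[constant] <- -Inf
  ord <- order(-imp)  # stable: ties keep column order
  tibble(
    feature = features[ord],
    importance = ifelse(is.finite(imp[ord]), imp[ord], 0),
    rank = seq_along(ord),
    constant = constant[ord]
  )
}

#' Precision-recall curve of scored labeled pairs
#'
#' @param scored Tibble with `score` and `label` columns.
#' @return A tibble (`threshold`, `precision`, `recall`, `n_accepted`) at
#'   every distinct score, thresholds descending.
#' @export
pr_curve <- function(scored) {
  ord <- order(-scored$score)
  s <- scored$score[ord]
  y <- scored$label[ord]
  tp <- cumsum(y)
  n <- seq_along(y)
  last <- !duplicated(s, fromLast = TRUE)  # last index at each threshold
  tibble(
    threshold = s[last],
    precision = (tp / n)[last],
    recall = (tp / sum(y))[last],
    n_accepted = n[last]
  )
}

#' Maximum recall at a precision floor
#'
#' @param pr A tibble from [pr_curve()].
#' @param precision Precision floor (default 0.9).
#' @return The largest recall among thresholds whose precision meets the
#'   floor; 0 if none does.
#' @export
recall_at_precision <- function(pr, precision = 0.9) {
  ok <- pr$precision >= precision
  if (!any(ok)) 0 else max(pr$recall[ok])
}

#' Sweep classifier performance over growing ranked feature sets
#'
#' Ranks features on the training fold, then for each requested feature
#' count trains a model on the top-k features and evaluates its
#' precision-recall curve on the withheld test pairs, reporting recall at
#' 90% precision per k.
#'
#' @param train,test Labeled feature tibbles (train should already be
#'   stratified).
#' @param family Classifier family.
#' @param feature_counts Increasing integer vector of feature-set sizes
#'   (values above the number of features are clamped with a warning).
#' @param seed Integer seed.
#' @param precision Precision floor for the summary (default 0.9).
#' @return A tibble (`n_features`, `recall_at_precision`, `pr`), with the
#'   full PR curve per k in the `pr` list-column.
#' @export
evaluate_feature_sweep <- function(train, test, family = ppi_families,
                                   feature_counts = c(2L, 5L, 10L),
                                   seed = 1L, precision = 0.9) {
  family <- match.arg(family)
  ranking <- rank_features(train, family, seed = seed)
  n_feat <- nrow(ranking)
  if (any(feature_counts > n_feat)) {
    warning("feature counts above the number of features were clamped")
    feature_counts <- pmin(feature_counts, n_feat)
  }
  feature_counts <- sort(unique(feature_counts))
  purrr::map_dfr(feature_counts, function(k) {
    feats <- ranking$feature[seq_len(k)]
    model <- fit_ppi_classifier(train, family, features = feats, seed = seed)
    scored <- dplyr::mutate(test, score = predict(model, test))
    pr <- pr_curve(scored)
    tibble(n_features = k,
           recall_at_precision = recall_at_precision(pr, precision),
           pr = list(pr))
  })
}

#' Score candidate pairs with a fitted classifier
#'
#' @param features Feature tibble with `og_a`, `og_b` and the model's
#'   feature columns.
#' @param model A fitted `"ppi_model"`.
#' @return A scored-network tibble (`og_a`, `og_b`, `score` in \[0, 1\]).
#' @export
score_all_pairs <- function(features, model) {
  tibble(og_a = features$og_a, og_b = features$og_b,
         score = predict(model, features))
}
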