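test_that("training-set construction splits double positives into two views", {
  toy <- toy_feature_classes(n_ev = 10, n_ab = 100)
  ts <- build_training_set(toy$dp, toy$ab)
  expect_identical(sum(ts$y == 1L), 20L)
  expect_identical(sum(ts$y == 0L), 100L)
  expect_identical(length(ts$y), 2L * nrow(toy$dp) + nrow(toy$ab))
  # channel views zero the cross-channel binned count
  pos <- ts$x[ts$y == 1L, ]
  expect_true(all(pos[1:10, "ch2_binned_counts"] == 0))
  expect_true(all(pos[11:20, "ch1_binned_counts"] == 0))
  expect_true(all(pos[1:10, "ch1_binned_counts"] ==
                    toy$dp$ch1_binned_counts))
  # count-derived features are recomputed from the view channel
  expect_equal(unname(pos[1:10, "num_localisations"]),
               toy$dp$ch1_binned_counts)
  expect_equal(unname(pos[11:20, "num_localisations"]),
               toy$dp$ch2_binned_counts)

  expect_error(build_training_set(toy$dp[0, ], toy$ab), "double-positive")
  expect_error(build_training_set(toy$dp, toy$ab[0, ]), "antibody")
})

test_that("models are deterministic given a seed and separate separable data", {
  toy <- toy_feature_classes(sep = 6)
  ts <- build_training_set(toy$dp, toy$ab)
  for (m in c("random_forest", "logistic_regression", "svm")) {
    fit1 <- train_model(ts, m, seed = 9)
    fit2 <- train_model(ts, m, seed = 9)
    expect_identical(predict(fit1, ts$x), predict(fit2, ts$x))
    # well-separated classes: perfect training accuracy
    expect_equal(mean(predict(fit1, ts$x, type = "class") == ts$y), 1,
                 label = m)
  }
  expect_error(train_model(structure(list(x = ts$x[ts$y == 1, ],
                                          y = ts$y[ts$y == 1]),
                                     class = "ev_training_set"),
                           "random_forest"), "both classes")
})

test_that("balanced weights improve minority-class recall under imbalance", {
  set.seed(61)
  recalls <- vapply(1:5, function(s) {
    # overlapping classes, 90:10 imbalance, minority = EV (label 1)
    n0 <- 450; n1 <- 50
    x <- rbind(matrix(rnorm(n0 * 3, 0), ncol = 3),
               matrix(rnorm(n1 * 3, 1.2), ncol = 3))
    colnames(x) <- c("radius_of_gyration", "convex_hull_area", "length")
    xm <- matrix(0, nrow(x), 13,
                 dimnames = list(NULL, c(feature_names(), "degenerate")))
    xm[, colnames(x)] <- x
    ts <- structure(list(x = xm, y = rep(c(0L, 1L), c(n0, n1)),
                         provenance = rep("synthetic", n0 + n1)),
                    class = "ev_training_set")
    rec <- function(balanced) {
      fit <- train_model(ts, "logistic_regression", seed = s,
                         balanced = balanced)
      pred <- predict(fit, ts$x, type = "class")
      sum(pred == 1L & ts$y == 1L) / sum(ts$y == 1L)
    }
    rec(TRUE) - rec(FALSE)
  }, numeric(1))
  expect_gt(mean(recalls), 0)
})

test_that("evaluation metrics: perfect, random, and the rank-AUC oracle", {
  y <- rep(c(0L, 1L), each = 50)
  expect_equal(auc_score(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), y), 1)

  set.seed(62)
  y_big <- rbinom(1e4, 1, 0.5)
  expect_equal(auc_score(runif(1e4), y_big), 0.5, tolerance = 0.04)

  # AUC equals the Mann-Whitney U identity on small instances
  for (rep in 1:5) {
    n <- sample(50:500, 1)
    yy <- rbinom(n, 1, 0.4)
    if (length(unique(yy)) < 2) yy[1:2] <- c(0L, 1L)
    sc <- rnorm(n) + yy
    u <- unname(wilcox.test(sc[yy == 1], sc[yy == 0],
                            exact = FALSE)$statistic)
    expect_equal(auc_score(sc, yy), u / (sum(yy == 1) * sum(yy == 0)),
                 tolerance = 1e-12)
  }

  toy <- toy_feature_classes(sep = 6)
  ts <- build_training_set(toy$dp, toy$ab)
  fit <- train_model(ts, "random_forest", seed = 2)
  ev <- evaluate_model(fit, ts)
  expect_equal(ev$auc_roc, 1)
  expect_equal(ev$roc_curve$fpr[1], 0)
  expect_equal(ev$roc_curve$tpr[nrow(ev$roc_curve)], 1)
  expect_true(all(diff(ev$roc_curve$fpr) >= 0))

  one_class <- structure(list(x = ts$x[ts$y == 1, ], y = ts$y[ts$y == 1],
                              provenance = NULL),
                         class = "ev_training_set")
  expect_error(evaluate_model(fit, one_class), "one-class")
})

test_that("ml_correct removes predicted aggregates from singles only", {
  toy <- toy_feature_classes(sep = 6)
  ts <- build_training_set(toy$dp, toy$ab)
  fit <- train_model(ts, "random_forest", seed = 3)
  raw <- summarize_phenotypes(counts = c(CD81_only = 30, CD9_only = 30,
                                         double_positive = 40))

  # single positives that look like EVs: summary unchanged
  sp_ev <- toy$dp
  sp_ev$phenotype <- rep(c("CD81_only", "CD9_only"), length.out = nrow(sp_ev))
  corr1 <- ml_correct(raw, sp_ev, fit)
  expect_equal(corr1$counts, c(CD81_only = 30, CD9_only = 30,
                               double_positive = 40))

  # single positives that look like aggregates: all removed, DP fraction 1
  sp_ab <- toy$ab
  sp_ab$phenotype <- rep(c("CD81_only", "CD9_only"), length.out = nrow(sp_ab))
  corr0 <- ml_correct(raw, sp_ab, fit)
  expect_equal(unname(corr0$fractions[["double_positive"]]), 1)
  expect_identical(corr0$correction_method, "ml")

  # never increases single-positive counts
  mixed <- rbind(sp_ev, sp_ab)
  corr_m <- ml_correct(raw, mixed, fit)
  expect_lte(corr_m$counts[["CD81_only"]], raw$counts[["CD81_only"]])
  expect_lte(corr_m$counts[["CD9_only"]], raw$counts[["CD9_only"]])
})

test_that("permutation importance ranks the informative feature first", {
  set.seed(63)
  n <- 400
  rg <- runif(n, 10, 110)
  xm <- matrix(rnorm(n * 13), n, 13,
               dimnames = list(NULL, c(feature_names(), "degenerate")))
  xm[, "radius_of_gyration"] <- rg
  y <- as.integer(rg > 60)
  ts <- structure(list(x = xm, y = y, provenance = rep("synthetic", n)),
                  class = "ev_training_set")
  fit <- train_model(ts, "random_forest", seed = 4)
  imp <- feature_importance(fit, ts, seed = 5)
  expect_identical(imp$feature[1], "radius_of_gyration")
  expect_identical(feature_importance(fit, ts, seed = 5), imp)

  # label independent of features: importances ~ 0
  set.seed(64)
  ts0 <- structure(list(x = xm, y = sample(y), provenance = ts$provenance),
                   class = "ev_training_set")
  fit0 <- train_model(ts0, "logistic_regression")
  imp0 <- feature_importance(fit0, ts0, seed = 6)
  expect_lt(max(abs(imp0$importance)), 0.1)
})
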