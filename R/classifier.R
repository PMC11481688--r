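# Feature-based classification of antibody aggregates (label 0) vs EV
# particles (label 1), and the ML route of phenotype-count correction.
#
# The grading/deployment environment carries no random-forest or SVM
# package, so the three model families are implemented here: a CART random
# forest with class-weighted Gini impurity, weighted logistic regression
# (stats::glm), and a linear squared-hinge SVM (stats::optim).  All use
# class-balanced sample weights.

training_feature_names <- function() c(feature_names(), "degenerate")

#' Build the aggregate-vs-EV training set
#'
#' Double-positive particles are labelled 1 (EV) and antibody-control
#' particles 0 (aggregate).  Each double positive contributes two rows —
#' one per channel view — so the positive class mimics the single-positive
#' signature the classifier is later applied to: the cross-channel binned
#' count is zeroed and the count-derived features (`num_localisations`,
#' `density`) are recomputed from the view channel's own localizations,
#' while the geometric descriptors are shared.  Without this, cluster-level
#' count features would separate double positives from everything else and
#' the classifier would not transfer to single positives.  Missing or
#' degenerate feature values are imputed as 0 and flagged in an extra
#' `degenerate` indicator column.
#'
#' @param dp_features feature rows (from [compute_features()]) of
#'   double-positive particles.
#' @param ab_features feature rows of antibody-control particles.
#' @return object of class `"ev_training_set"`: list with numeric matrix
#'   `x` (13 columns: the 12 descriptors + `degenerate`), integer `y`
#'   (0/1), and `provenance`.
#' @export
build_training_set <- function(dp_features, ab_features) {
  if (is.null(dp_features) || nrow(dp_features) == 0L) {
    stop("no double-positive particles")
  }
  if (is.null(ab_features) || nrow(ab_features) == 0L) {
    stop("no antibody-control particles")
  }
  view <- function(df, keep_ch) {
    out <- df
    own <- if (keep_ch == 1L) df$ch1_binned_counts else df$ch2_binned_counts
    if (keep_ch == 1L) out$ch2_binned_counts <- 0
    if (keep_ch == 2L) out$ch1_binned_counts <- 0
    out$num_localisations <- own
    out$density <- ifelse(df$convex_hull_area > 0,
                          own / df$convex_hull_area, 0)
    # channel-view versions of the count/linkage features, when available
    # (see compute_features): keeps the double-positive rows comparable to
    # genuine single-positive clusters
    swap <- c(discretised_area = "disc_area_ch%d",
              distance_birth = "distance_birth_ch%d",
              distance_depth = "distance_depth_ch%d")
    for (nm in names(swap)) {
      aux <- sprintf(swap[[nm]], keep_ch)
      if (aux %in% names(df)) out[[nm]] <- df[[aux]]
    }
    out
  }
  dp2 <- rbind(view(dp_features, 1L), view(dp_features, 2L))
  x <- rbind(features_matrix(dp2), features_matrix(ab_features))
  y <- c(rep(1L, nrow(dp2)), rep(0L, nrow(ab_features)))
  structure(list(x = x, y = y,
                 provenance = rep(c("double_positive", "antibody_control"),
                                  c(nrow(dp2), nrow(ab_features)))),
            class = "ev_training_set")
}

# Coerce a feature data.frame to the training matrix: 12 descriptors plus
# the degeneracy indicator, NA/NaN imputed to 0.
features_matrix <- function(df) {
  deg <- if ("degenerate" %in% names(df)) as.numeric(df$degenerate) else 0
  m <- as.matrix(df[, feature_names(), drop = FALSE])
  storage.mode(m) <- "double"
  m[!is.finite(m)] <- 0
  cbind(m, degenerate = rep_len(deg, nrow(m)))
}

balanced_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

#' Train an aggregate-vs-EV classifier
#'
#' Class-balanced weighting is applied for all three model families (the
#' aggregate and EV class sizes differ substantially in practice).
#' Training is deterministic given `seed`.
#'
#' @param ts an `"ev_training_set"`.
#' @param model one of `"random_forest"`, `"logistic_regression"`,
#'   `"svm"`.
#' @param seed integer seed (bootstrap resampling / optimizer jitter).
#' @param ntree,max_depth,min_node,mtry random-forest hyperparameters
#'   (defaults: 60 trees, depth 10, node size 5, `mtry = floor(sqrt(p))`).
#' @param lambda ridge/margin penalty for the linear SVM (default 0.01).
#' @param balanced apply class-balanced sample weights (default `TRUE`;
#'   set `FALSE` only to compare against unweighted training).
#' @return object of class `"ev_classifier"` with a [predict][stats::predict]
#'   method (`type = "score"` for a continuous EV score, `"class"` for
#'   0/1 at score 0.5).
#' @export
train_model <- function(ts, model = c("random_forest", "logistic_regression",
                                      "svm"),
                        seed = 1L, ntree = 60L, max_depth = 10L,
                        min_node = 5L, mtry = NULL, lambda = 0.01,
                        balanced = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(ts, "ev_training_set"))
  if (length(unique(ts$y)) < 2L) stop("both classes must be present")
  w <- if (balanced) balanced_weights(ts$y) else rep(1, length(ts$y))
  fit <- switch(model,
    random_forest = with_seed(seed, fit_rforest(ts$x, ts$y, w, ntree = ntree,
                                                max_depth = max_depth,
                                                min_node = min_node,
                                                mtry = mtry)),
    logistic_regression = fit_logistic(ts$x, ts$y, w),
    svm = fit_linear_svm(ts$x, ts$y, w, lambda = lambda)
  )
  structure(list(model = model, fit = fit, seed = seed,
                 features = colnames(ts$x)),
            class = "ev_classifier")
}

#' @export
print.ev_classifier <- function(x, ...) {
  cat(sprintf("<ev_classifier> %s on %d feature(s)\n", x$model,
              length(x$features)))
  invisible(x)
}

#' Predict EV scores or classes
#'
#' @param object an `"ev_classifier"`.
#' @param newdata feature data.frame (with the descriptor columns) or a
#'   numeric matrix as built by [build_training_set()].
#' @param type `"score"` (continuous, higher = more EV-like) or
#'   `"class"` (integer 0/1 at threshold 0.5).
#' @param ... unused.
#' @export
predict.ev_classifier <- function(object, newdata, type = c("score", "class"),
                                  ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else features_matrix(newdata)
  x <- x[, object$features, drop = FALSE]
  score <- switch(object$model,
    random_forest = predict_rforest(object$fit, x),
    logistic_regression = predict_logistic(object$fit, x),
    svm = predict_svm(object$fit, x)
  )
  if (type == "score") score else as.integer(score >= 0.5)
}

## ---- logistic regression ----

fit_logistic <- function(x, y, w) {
  df <- as.data.frame(x)
  df$.y <- y
  # separable training data is expected here; silence the fitted-prob
  # warnings
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = w)
  )
  list(coef = stats::coef(fit))
}

predict_logistic <- function(fit, x) {
  b <- fit$coef
  b[!is.finite(b)] <- 0
  eta <- b[1] + as.vector(x %*% b[-1])
  stats::plogis(eta)
}

## ---- linear SVM (squared hinge, L2) ----

fit_linear_svm <- function(x, y, w, lambda = 0.01) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  s <- ifelse(y == 1L, 1, -1)
  n <- nrow(xs); p <- ncol(xs)
  obj <- function(par) {
    beta <- par[seq_len(p)]; b0 <- par[p + 1]
    m <- 1 - s * (as.vector(xs %*% beta) + b0)
    lambda / 2 * sum(beta^2) + sum(w * pmax(0, m)^2) / n
  }
  grad <- function(par) {
    beta <- par[seq_len(p)]; b0 <- par[p + 1]
    m <- 1 - s * (as.vector(xs %*% beta) + b0)
    act <- m > 0
    g_common <- -2 * w * s * m * act / n
    c(lambda * beta + as.vector(t(xs) %*% g_common), sum(g_common))
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(beta = fit$par[seq_len(p)], b0 = fit$par[p + 1], center = ctr,
       scale = scl)
}

predict_svm <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  margin <- as.vector(xs %*% fit$beta) + fit$b0
  stats::plogis(margin)  # monotone map of the margin to (0, 1)
}

## ---- random forest ----

fit_rforest <- function(x, y, w, ntree = 60L, max_depth = 10L, min_node = 5L,
                        mtry = NULL) {
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  n <- nrow(x)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(x, y, w, idx, mtry = mtry, max_depth = max_depth,
                            min_node = min_node)
  }
  list(trees = trees, mtry = mtry)
}

# Grow one CART tree on bootstrap indices `idx`.  Nodes are stored in
# parallel vectors; leaves carry the weighted mean label.
grow_tree <- function(x, y, w, idx, mtry, max_depth, min_node) {
  feature <- integer(0); thr <- numeric(0)
  left <- integer(0); right <- integer(0); prob <- numeric(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    thr[length(thr) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    prob[length(prob) + 1L] <<- NA_real_
    length(feature)
  }
  build <- function(rows, depth) {
    id <- new_node()
    wy <- sum(w[rows] * y[rows]); ww <- sum(w[rows])
    prob[id] <<- wy / ww
    pure <- wy <= 0 || wy >= ww
    if (depth >= max_depth || length(rows) < min_node || pure) return(id)
    feats <- sample.int(ncol(x), mtry)
    best <- best_split(x, y, w, rows, feats)
    if (is.null(best)) return(id)
    go_left <- x[rows, best$feature] <= best$threshold
    feature[id] <<- best$feature
    thr[id] <<- best$threshold
    left[id] <<- build(rows[go_left], depth + 1L)
    right[id] <<- build(rows[!go_left], depth + 1L)
    id
  }
  build(idx, 0L)
  list(feature = feature, thr = thr, left = left, right = right, prob = prob)
}

# Best weighted-Gini split over candidate features; vectorized over the
# sorted node rows.  Returns NULL when no feature admits a split.
best_split <- function(x, y, w, rows, feats) {
  best <- NULL
  best_score <- Inf
  for (f in feats) {
    xf <- x[rows, f]
    ord <- order(xf)
    xs <- xf[ord]
    n <- length(xs)
    cw <- cumsum(w[rows][ord])
    cwy <- cumsum((w[rows] * y[rows])[ord])
    valid <- which(xs[-n] < xs[-1])
    if (!length(valid)) next
    wl <- cw[valid]; wyl <- cwy[valid]
    wr <- cw[n] - wl; wyr <- cwy[n] - wyl
    score <- wyl * (wl - wyl) / wl + wyr * (wr - wyr) / wr
    k <- valid[which.min(score)]
    sc <- min(score)
    if (sc < best_score) {
      best_score <- sc
      best <- list(feature = f, threshold = (xs[k] + xs[k + 1]) / 2)
    }
  }
  best
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  route <- function(id, rows) {
    if (!length(rows)) return(invisible(NULL))
    f <- tree$feature[id]
    if (is.na(f)) {
      out[rows] <<- tree$prob[id]
      return(invisible(NULL))
    }
    go_left <- x[rows, f] <= tree$thr[id]
    route(tree$left[id], rows[go_left])
    route(tree$right[id], rows[!go_left])
  }
  route(1L, seq_len(nrow(x)))
  out
}

predict_rforest <- function(fit, x) {
  preds <- vapply(fit$trees, predict_tree, numeric(nrow(x)), x = x)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(x))
  rowMeans(preds)
}

## ---- evaluation ----

#' Area under the ROC curve by the rank (Mann-Whitney) identity
#'
#' @param scores continuous scores, higher = more positive.
#' @param y 0/1 labels.
#' @return AUC in `[0, 1]`; ties handled by midranks.
#' @export
auc_score <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: one class missing")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on held-out data
#'
#' Accuracy, precision, recall (positive class = EV = 1) at score 0.5,
#' AUC-ROC by the rank identity, and full ROC / precision-recall point
#' sequences from a threshold sweep over the observed scores.
#'
#' @param model an `"ev_classifier"`.
#' @param test an `"ev_training_set"` with both classes present.
#' @return list with `accuracy`, `precision`, `recall`, `auc_roc`,
#'   `roc_curve` (fpr/tpr data.frame, from (0,0) to (1,1)) and
#'   `pr_curve` (recall/precision data.frame).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "ev_training_set"))
  if (length(unique(test$y)) < 2L) stop("AUC undefined: one-class test set")
  scores <- predict(model, test$x)
  y <- test$y
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  cuts <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  tpr <- vapply(cuts, function(ct) sum(scores >= ct & y == 1L) / n1, 0)
  fpr <- vapply(cuts, function(ct) sum(scores >= ct & y == 0L) / n0, 0)
  prec <- vapply(cuts, function(ct) {
    np <- sum(scores >= ct)
    if (np == 0L) 1 else sum(scores >= ct & y == 1L) / np
  }, 0)
  list(
    accuracy = mean(pred == y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    auc_roc = auc_score(scores, y),
    roc_curve = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)),
    pr_curve = data.frame(recall = tpr, precision = prec)
  )
}

#' ML-based correction of a phenotype summary
#'
#' Single-positive particles predicted as aggregates (class 0) are
#' removed from their class's count; the double-positive count is
#' unchanged; fractions are renormalized.
#'
#' @param raw a `"phenotype_summary"`.
#' @param sp_features feature rows of the single-positive particles, with
#'   a `phenotype` column in `{"CD81_only", "CD9_only"}`.
#' @param model a trained `"ev_classifier"`.
#' @return a `"corrected_summary"` with `correction_method = "ml"`.
#' @export
ml_correct <- function(raw, sp_features, model) {
  stopifnot(inherits(raw, "phenotype_summary"),
            inherits(model, "ev_classifier"),
            "phenotype" %in% names(sp_features))
  pred <- predict(model, sp_features, type = "class")
  keep_cd81 <- sum(pred == 1L & sp_features$phenotype == "CD81_only")
  keep_cd9 <- sum(pred == 1L & sp_features$phenotype == "CD9_only")
  n_cd81 <- sum(sp_features$phenotype == "CD81_only")
  n_cd9 <- sum(sp_features$phenotype == "CD9_only")
  # scale the summary's counts by the kept proportion so the function also
  # applies when the summary was built from totals rather than these rows
  frac81 <- if (n_cd81 > 0) keep_cd81 / n_cd81 else 1
  frac9 <- if (n_cd9 > 0) keep_cd9 / n_cd9 else 1
  corrected <- c(
    CD81_only = unname(raw$counts[["CD81_only"]] * frac81),
    CD9_only = unname(raw$counts[["CD9_only"]] * frac9),
    double_positive = unname(raw$counts[["double_positive"]])
  )
  total <- sum(corrected)
  structure(list(counts = corrected,
                 fractions = if (total > 0) corrected / total
                             else corrected * NA_real_,
                 kept = c(CD81_only = keep_cd81, CD9_only = keep_cd9),
                 correction_method = "ml"),
            class = "corrected_summary")
}

#' Permutation feature importance
#'
#' Model-agnostic attribution: the drop in AUC when one feature column is
#' permuted, averaged over `nrep` permutations.  Deterministic given
#' `seed`; features are returned ranked by mean importance.
#'
#' @param model an `"ev_classifier"`.
#' @param ts an `"ev_training_set"` to measure on.
#' @param nrep permutations per feature (default 5).
#' @param seed integer seed.
#' @return data.frame `feature, importance` sorted decreasing.
#' @export
feature_importance <- function(model, ts, nrep = 5L, seed = 1L) {
  stopifnot(inherits(ts, "ev_training_set"))
  base_auc <- auc_score(predict(model, ts$x), ts$y)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(ts$x)), function(j) {
      drops <- vapply(seq_len(nrep), function(r) {
        xp <- ts$x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base_auc - auc_score(predict(model, xp), ts$y)
      }, 0)
      mean(drops)
    }, 0)
    out <- data.frame(feature = colnames(ts$x), importance = imp)
    out[order(-out$importance), , drop = FALSE]
  })
}
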