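#' 4:1 train/test split
#'
#' Seeded, unstratified lesion-level random partition with
#' `floor(4N/5)` training rows. When patient `groups` are supplied, whole
#' patients are assigned to one side so no patient spans both sets (sizes
#' are then approximate).
#'
#' @param n_lesions number of rows to split.
#' @param seed integer seed.
#' @param groups optional per-row patient/case ids.
#' @return List with integer row indices `train` and `test`.
#' @export
split_cohort <- function(n_lesions, seed = 1, groups = NULL) {
  if (n_lesions < 5) stop("need at least 5 lesions for a 4:1 split")
  n_train <- floor(4 * n_lesions / 5)
  with_seed(seed, {
    if (is.null(groups)) {
      perm <- sample.int(n_lesions)
      list(train = sort(perm[seq_len(n_train)]),
           test = sort(perm[-seq_len(n_train)]))
    } else {
      stopifnot(length(groups) == n_lesions)
      gs <- sample(unique(groups))
      take <- integer(0)
      for (g in gs) {
        if (length(take) >= n_train) break
        take <- c(take, which(groups == g))
      }
      list(train = sort(take), test = sort(setdiff(seq_len(n_lesions), take)))
    }
  })
}

# Stratified fold assignment: shuffles rows within each class.
fold_assign <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise interpolated average precision,
#' `AP = sum_t (R_t - R_(t-1)) P_t` over descending unique score
#' thresholds.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (1 = positive).
#' @return AP in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index per threshold
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(l)
  sum(diff(c(0, rec)) * prec)
}

#' One Bayesian-optimization trial parameter set
#'
#' @param n_features number of features fed to the booster.
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param weight positive-class weight (searched around
#'   `r = n_negative / n_positive` of the training set).
#' @param bins MI discretization bins for feature selection.
#' @return A `trial_params` list (`booster` is always `"gbtree"`).
#' @export
trial_params <- function(n_features, nrounds, max_depth, eta, weight,
                         bins = 10) {
  stopifnot(n_features >= 1, nrounds >= 1, weight > 0)
  structure(list(n_features = as.integer(n_features), booster = "gbtree",
                 nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, weight = weight, bins = as.integer(bins)),
            class = "trial_params")
}

# Stage 1: repeated-k-fold JMIM, aggregated by selection frequency
# (ties by mean selection rank, then column order). 5 repeats x 5 folds.
stage1_features <- function(train_table, labels, k, bins, seed,
                            repeats = 5, folds = 5) {
  feats <- feature_columns(train_table)
  freq <- stats::setNames(numeric(length(feats)), feats)
  ranksum <- stats::setNames(numeric(length(feats)), feats)
  nruns <- 0L
  for (rep_i in seq_len(repeats)) {
    fa <- fold_assign(labels, folds, seed = seed + 1000L * rep_i)
    for (f in seq_len(folds)) {
      idx <- which(fa != f)
      sel <- jmim_select(train_table[idx, , drop = FALSE], labels[idx],
                         k = k, bins = bins)
      freq[sel$selected] <- freq[sel$selected] + 1
      ranksum[sel$selected] <- ranksum[sel$selected] + seq_along(sel$selected)
      ranksum[setdiff(feats, sel$selected)] <-
        ranksum[setdiff(feats, sel$selected)] + k + 1
      nruns <- nruns + 1L
    }
  }
  meanrank <- ranksum / nruns
  ord <- order(-freq, meanrank, seq_along(feats))
  feats[ord][seq_len(k)]
}

xgb_fit <- function(X, y, params) {
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", booster = params$booster,
                  max_depth = params$max_depth, eta = params$eta,
                  scale_pos_weight = params$weight, nthread = 1),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

#' Nested cross-validation objective of one trial
#'
#' Stage 1 runs JMIM on each training portion of a randomized
#' five-times-repeated 5-fold split of the training rows and aggregates
#' selections by frequency into a top-`k` feature list. Stage 2 runs a
#' stratified 10-fold cross-validation of the gradient-boosted model on
#' those features and returns the mean area under the precision-recall
#' curve over the validation folds. Test rows must never be passed here.
#'
#' @param train_table training feature table.
#' @param labels binary training labels.
#' @param params a [trial_params()].
#' @param seed integer seed for both nested splits.
#' @return List with `objective` (mean AUPRC) and `features` (stage-1 list).
#' @export
trial_objective <- function(train_table, labels, params, seed = 1) {
  feats <- feature_columns(train_table)
  if (params$n_features > length(feats))
    stop("n_features exceeds the available features")
  sel <- stage1_features(train_table, labels, params$n_features, params$bins,
                         seed)
  X <- as.matrix(train_table[, sel, drop = FALSE])
  y <- as.integer(labels)
  fa <- fold_assign(y, 10, seed = seed + 99991L)
  aps <- numeric(0)
  for (f in sort(unique(fa))) {
    tr <- which(fa != f)
    va <- which(fa == f)
    if (length(unique(y[va])) < 2) next
    fit <- xgb_fit(X[tr, , drop = FALSE], y[tr], params)
    sc <- stats::predict(fit, xgboost::xgb.DMatrix(X[va, , drop = FALSE],
                                                   nthread = 1))
    aps <- c(aps, auprc(sc, y[va]))
  }
  list(objective = mean(aps), features = sel)
}

# Draw one random trial from the search space.
random_trial <- function(n_feat_max, r, bins) {
  trial_params(
    n_features = sample(2:min(40, n_feat_max), 1),
    nrounds = sample(5:200, 1),
    max_depth = sample(2:6, 1),
    eta = exp(stats::runif(1, log(0.01), log(0.3))),
    weight = stats::runif(1, r / 2, 2 * r),
    bins = bins)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Perturb a good trial (local move of the sequential optimizer).
mutate_trial <- function(p, n_feat_max, r, bins) {
  trial_params(
    n_features = clamp(p$n_features + sample(-3:3, 1), 2, min(40, n_feat_max)),
    nrounds = clamp(round(p$nrounds * exp(stats::rnorm(1, 0, 0.3))), 5, 200),
    max_depth = clamp(p$max_depth + sample(-1:1, 1), 2, 6),
    eta = clamp(p$eta * exp(stats::rnorm(1, 0, 0.3)), 0.01, 0.3),
    weight = clamp(p$weight * exp(stats::rnorm(1, 0, 0.2)), r / 2, 2 * r),
    bins = bins)
}

#' Sequential model-based optimization of the radiomics pipeline
#'
#' Runs `budget` trials of [trial_objective()] over the search space
#' (features 2-40, rounds 5-200, depth 2-6, log-uniform learning rate
#' 0.01-0.3, class weight in `[r/2, 2r]` around the training
#' negative/positive ratio `r`). The first trials are drawn at random;
#' later trials are sampled around the best quartile of completed trials,
#' with occasional fresh random draws. All trials share the same nested
#' split (common random numbers), and the best trial's parameters and
#' stage-1 feature list are refit on all training rows.
#'
#' @param train_table training feature table.
#' @param labels binary training labels.
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @param bins MI discretization bins.
#' @return List with `best_params`, `model` (a `dlmvoi_model`), and `trace`
#'   (data frame of per-trial parameters and objectives).
#' @export
optimize_model <- function(train_table, labels, budget = 30, seed = 1,
                           bins = 10) {
  if (budget < 1) stop("budget must be >= 1")
  feats <- feature_columns(train_table)
  if (length(feats) == 0) stop("empty feature table")
  y <- as.integer(labels)
  r <- sum(y == 0) / sum(y == 1)
  n_init <- min(budget, 10)

  trials <- vector("list", budget)
  objs <- numeric(budget)
  with_seed(seed + 5L, {
    for (t in seq_len(budget)) {
      p <- if (t <= n_init) {
        random_trial(length(feats), r, bins)
      } else if (stats::runif(1) < 0.25) {
        random_trial(length(feats), r, bins)
      } else {
        done <- order(-objs[seq_len(t - 1)])
        good <- done[seq_len(max(1, floor((t - 1) / 4)))]
        mutate_trial(trials[[sample(good, 1)]], length(feats), r, bins)
      }
      trials[[t]] <- p
      objs[t] <- trial_objective(train_table, y, p, seed = seed)$objective
    }
  })
  best <- which.max(objs)
  bp <- trials[[best]]
  sel <- stage1_features(train_table, y, bp$n_features, bins, seed)
  booster <- xgb_fit(as.matrix(train_table[, sel, drop = FALSE]), y, bp)
  model <- structure(list(features = sel, booster = booster, params = bp,
                          objective = objs[best], class_ratio = r,
                          seed = seed),
                     class = "dlmvoi_model")
  trace <- data.frame(
    trial = seq_len(budget),
    n_features = vapply(trials, `[[`, 0L, "n_features"),
    nrounds = vapply(trials, `[[`, 0L, "nrounds"),
    max_depth = vapply(trials, `[[`, 0L, "max_depth"),
    eta = vapply(trials, `[[`, 0, "eta"),
    weight = vapply(trials, `[[`, 0, "weight"),
    objective = objs)
  list(best_params = bp, model = model, trace = trace)
}

#' Predict clinically-significant-cancer scores
#'
#' @param object a `dlmvoi_model` from [optimize_model()].
#' @param newdata feature table containing the model's selected features.
#' @param ... unused.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict.dlmvoi_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop(sprintf("missing feature columns: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  as.numeric(stats::predict(object$booster,
                            xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' @export
print.dlmvoi_model <- function(x, ...) {
  cat(sprintf(
    "<dlmvoi_model: %d features, %d rounds, depth %d, eta %.3f, w %.2f; CV AUPRC %.3f>\n",
    length(x$features), x$params$nrounds, x$params$max_depth, x$params$eta,
    x$params$weight, x$objective))
  invisible(x)
}
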