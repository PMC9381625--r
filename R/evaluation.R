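#' Area under the empirical ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic via midranks, so
#' tied scores count one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# pROC object with fixed conventions: higher score = positive.
proc_roc <- function(scores, labels) {
  pROC::roc(response = as.integer(labels), predictor = as.numeric(scores),
            levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation interval using the DeLong variance estimate,
#' clipped to `[0, 1]`. A degenerate (zero-variance) score vector collapses
#' to a point interval with a warning.
#'
#' @param scores,labels as in [roc_auc()].
#' @param level confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  a <- roc_auc(scores, labels)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(proc_roc(scores, labels),
                                             conf.level = level,
                                             method = "delong"))),
    error = function(e) NULL)
  if (is.null(ci) || any(!is.finite(ci))) {
    warning("degenerate DeLong variance; returning a point interval")
    return(c(a, a))
  }
  clamp(c(ci[1], ci[3]), 0, 1)
}

#' Paired DeLong comparison of two models
#'
#' Two-sided DeLong test on the correlated AUCs of two score vectors over
#' the same cases.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @param level confidence level for the per-model intervals.
#' @return A `model_comparison`: `auc_a`, `auc_b`, `auc_diff`, `p_value`,
#'   `ci_a`, `ci_b`.
#' @export
compare_models <- function(scores_a, scores_b, labels, level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("inputs must be paired over the same cases")
  ra <- proc_roc(scores_a, labels)
  rb <- proc_roc(scores_b, labels)
  aa <- roc_auc(scores_a, labels)
  ab <- roc_auc(scores_b, labels)
  p <- if (isTRUE(all.equal(scores_a, scores_b))) 1 else {
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    as.numeric(tst$p.value)
  }
  structure(list(auc_a = aa, auc_b = ab, auc_diff = aa - ab,
                 p_value = min(1, p),
                 ci_a = auc_ci(scores_a, labels, level),
                 ci_b = auc_ci(scores_b, labels, level)),
            class = "model_comparison")
}

#' Operating threshold by Youden's J
#'
#' Scans the observed scores as thresholds (predict positive when
#' `score >= t`) and maximizes sensitivity + specificity - 1; ties break
#' to the lowest threshold.
#'
#' @param scores,labels as in [roc_auc()].
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ts <- sort(unique(scores))
  best <- NULL
  for (t in ts) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   j = j)
  }
  best[c("threshold", "sensitivity", "specificity")]
}

#' Evaluate one model's scores on one test set
#'
#' Bundles the empirical ROC points, AUC with DeLong 95% CI, and the
#' Youden-optimal operating point.
#'
#' @param scores,labels as in [roc_auc()].
#' @param model_id identifier stored in the result.
#' @param diameter_mm VOI diameter the model was built at (optional).
#' @return An `eval_result` list.
#' @export
eval_result <- function(scores, labels, model_id = "model",
                        diameter_mm = NA_real_) {
  labels <- as.integer(labels)
  ts <- c(-Inf, sort(unique(scores)))
  roc_points <- data.frame(
    threshold = ts,
    sensitivity = vapply(ts, function(t)
      sum(scores >= t & labels == 1) / sum(labels == 1), 0),
    specificity = vapply(ts, function(t)
      sum(scores < t & labels == 0) / sum(labels == 0), 0))
  yt <- youden_threshold(scores, labels)
  structure(list(model_id = model_id, diameter_mm = diameter_mm,
                 auc = roc_auc(scores, labels),
                 ci = auc_ci(scores, labels),
                 threshold = yt$threshold,
                 sensitivity = yt$sensitivity,
                 specificity = yt$specificity,
                 roc = roc_points,
                 n = length(labels)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result %s%s: AUC %.3f [%.3f-%.3f], sens %.2f / spec %.2f @ %.3f (n=%d)>\n",
              x$model_id,
              if (is.na(x$diameter_mm)) "" else sprintf(" d=%gmm", x$diameter_mm),
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity,
              x$threshold, x$n))
  invisible(x)
}

#' Serialize / restore an evaluation result through JSON
#'
#' @param x an `eval_result`.
#' @return `eval_result_to_json` returns a JSON string;
#'   `eval_result_from_json` rebuilds the `eval_result`.
#' @export
eval_result_to_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname eval_result_to_json
#' @param json JSON string from [eval_result_to_json()].
#' @export
eval_result_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  o$roc <- as.data.frame(o$roc)
  o$roc$threshold[1] <- -Inf
  structure(o, class = "eval_result")
}

#' AUC-versus-diameter sweep experiment
#'
#' For each initial sphere diameter: build all VOIs, extract features,
#' optimize the model on a fixed training split and evaluate on the fixed
#' test split. The lesion-level split is identical across diameters, so
#' rows are directly comparable.
#'
#' @param cohort a `synthetic_cohort`.
#' @param diameters diameters in mm (default [sweep_diameters()]).
#' @param budget optimization trials per diameter.
#' @param seed integer seed (split, nested CV, optimizer).
#' @param params an [extraction_params()].
#' @param bins MI discretization bins.
#' @return A `sweep_report`: list with `results` (one `eval_result` per
#'   diameter), `summary` data frame, and the shared `split`.
#' @export
diameter_sweep_report <- function(cohort, diameters = sweep_diameters(),
                                  budget = 10, seed = 1,
                                  params = extraction_params(), bins = 10) {
  n <- nrow(cohort$manifest)
  split <- split_cohort(n, seed = seed)
  results <- lapply(diameters, function(d) {
    tab <- extract_cohort(cohort, d, params)
    train <- tab[split$train, , drop = FALSE]
    test <- tab[split$test, , drop = FALSE]
    opt <- optimize_model(train, train$label, budget = budget, seed = seed,
                          bins = bins)
    sc <- predict(opt$model, test)
    eval_result(sc, test$label, model_id = sprintf("dlm_d%02d", d),
                diameter_mm = d)
  })
  summary <- data.frame(
    diameter_mm = diameters,
    auc = vapply(results, `[[`, 0, "auc"),
    ci_lo = vapply(results, function(r) r$ci[1], 0),
    ci_hi = vapply(results, function(r) r$ci[2], 0),
    sensitivity = vapply(results, `[[`, 0, "sensitivity"),
    specificity = vapply(results, `[[`, 0, "specificity"))
  structure(list(results = results, summary = summary, split = split),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
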