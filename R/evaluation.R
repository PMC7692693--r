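#' Stratified k-fold assignment
#'
#' Partitions recordings into `k` folds, stratified by label so that
#' per-fold class counts differ by at most one from perfect balance.
#' With the clinical cohort proportions (50 pathological / 45 normal,
#' k = 5) every fold holds exactly 19 recordings.
#'
#' @param labels Character/factor vector of `"normal"`/`"pathological"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; assignment is deterministic per seed.
#' @return Integer vector of fold ids in `1..k`, one per recording, with
#'   attribute `seed`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("make_folds: every class needs at least k = ", k, " members")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  attr(fold, "seed") <- as.integer(seed)
  fold
}

#' Confusion counts
#'
#' Counts with the clinical convention positive = pathological.
#'
#' @param labels True labels (`"normal"`/`"pathological"`).
#' @param predictions Predicted labels, same vocabulary and length.
#' @return Named list `tp`, `fn`, `tn`, `fp` of class `confusion_counts`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) {
    stop("confusion: length mismatch")
  }
  ok <- c("normal", "pathological")
  if (!all(labels %in% ok) || !all(predictions %in% ok)) {
    stop("confusion: labels must be 'normal' or 'pathological'")
  }
  structure(list(tp = sum(labels == "pathological" & predictions == "pathological"),
                 fn = sum(labels == "pathological" & predictions == "normal"),
                 tn = sum(labels == "normal" & predictions == "normal"),
                 fp = sum(labels == "normal" & predictions == "pathological")),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' @param counts A [confusion()] result.
#' @return Named list `accuracy`, `sensitivity`, `specificity`, each in
#'   percent.
#' @export
eval_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn == 0) stop("eval_metrics: no positive cases (sensitivity undefined)")
    if (tn + fp == 0) stop("eval_metrics: no negative cases (specificity undefined)")
    list(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp))
  })
}

#' ROC curve and AUC
#'
#' Rank-based AUC with midrank tie handling: the probability that a
#' random pathological recording scores above a random normal one, ties
#' counting one half (the Mann-Whitney statistic). The ROC points sweep
#' every distinct score threshold.
#'
#' @param scores Numeric scores; larger = more pathological.
#' @param labels `"normal"`/`"pathological"` per score.
#' @return List with `auc` and `roc` (`data.frame` with `fpr`, `tpr`
#'   rising from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (!all(is.finite(scores))) stop("roc_auc: non-finite scores")
  pos <- labels == "pathological"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)                  # midranks
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg,
                      numeric(1L))),
    tpr = c(0, vapply(thr, function(t) sum(scores[pos] >= t) / n_pos,
                      numeric(1L))))
  list(auc = auc, roc = roc)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval for a proportion via beta-distribution quantiles, reported
#' in percent. Boundary conventions: the lower bound of 0 successes is
#' 0 and the upper bound of n successes is 100. For 45/45 successes the
#' 95% lower bound is `0.025^(1/45) = 92.1%`.
#'
#' @param successes,trials Non-negative integer counts, `successes <=
#'   trials`, `trials > 0`.
#' @param level Confidence level (default 0.95).
#' @return List of class `proportion_ci`: `estimate`, `lower`, `upper`
#'   (percent), `level`, `method`.
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials <= 0 || successes < 0 || successes > trials) {
    stop("exact_binomial_ci: need 0 <= successes <= trials, trials > 0")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else {
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  }
  upper <- if (successes == trials) 1 else {
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  }
  structure(list(estimate = 100 * successes / trials,
                 lower = 100 * lower, upper = 100 * upper,
                 level = level, method = "exact binomial (Clopper-Pearson)"),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.1f (%.1f-%.1f) [%d%% %s]\n", x$estimate, x$lower, x$upper,
              round(100 * x$level), x$method))
  invisible(x)
}

#' Cross-validated evaluation of one classifier family
#'
#' Runs k-fold cross-validation: for each fold, a fresh model is trained
#' on the other folds and scored on the held-out fold only. Per-fold
#' accuracy, sensitivity, specificity and AUC are reported with their
#' mean and min-max range; pooled test-fold predictions give the overall
#' ROC, AUC and exact binomial confidence intervals. When `groups` is
#' supplied (the 2D-CNN crop path), all crops of one recording stay in
#' the recording's fold and predictions are aggregated per recording, so
#' no recording ever straddles the train/test boundary.
#'
#' @param config A [model_config()].
#' @param x Inputs of the family's kind: feature matrix rows, list of
#'   padded signals, or list of 40x40 crops.
#' @param labels Per-recording labels (per-crop when `groups` given,
#'   constant within a group).
#' @param folds Fold assignment from [make_folds()], one entry per
#'   recording (per group when `groups` given, constant within a group).
#' @param groups Optional crop-to-recording ids.
#' @param ... Hyperparameter overrides passed to [train_model()].
#' @return An `eval_report`: `per_fold` data.frame, `summary` (mean and
#'   range per metric), `pooled` metrics + CIs, `roc`, `auc`.
#' @export
evaluate_model <- function(config, x, labels, folds, groups = NULL, ...) {
  stopifnot(inherits(config, "model_config"))
  labels <- as.character(labels)
  is_list_input <- is.list(x) && !is.data.frame(x)
  n <- if (is_list_input) length(x) else nrow(x)
  if (length(labels) != n) stop("evaluate_model: labels/input length mismatch")
  if (is.null(groups)) {
    if (length(folds) != n) stop("evaluate_model: folds/input length mismatch")
  } else {
    if (length(groups) != n) stop("evaluate_model: groups/input length mismatch")
    gid <- unique(groups)
    if (length(folds) != length(gid)) {
      stop("evaluate_model: folds must have one entry per group")
    }
    fold_of_group <- stats::setNames(folds, gid)
    folds <- as.integer(fold_of_group[as.character(groups)])
  }
  k <- max(folds)
  per_fold <- NULL
  pooled_scores <- numeric(0)
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    xtr <- if (is_list_input) x[tr] else x[tr, , drop = FALSE]
    xte <- if (is_list_input) x[te] else x[te, , drop = FALSE]
    model <- build_model(config)
    model <- train_model(model, xtr, labels[tr], ...)
    pred <- predict_model(model, xte,
                          groups = if (is.null(groups)) NULL else groups[te])
    if (is.null(groups)) {
      truth <- labels[te]
    } else {
      truth <- vapply(pred$group, function(g) labels[groups == g][1L],
                      character(1L))
    }
    cm <- confusion(truth, pred$label)
    m <- eval_metrics(cm)
    ra <- roc_auc(pred$prob_pathological, truth)
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, n_test = length(truth),
                                 accuracy = m$accuracy,
                                 sensitivity = m$sensitivity,
                                 specificity = m$specificity,
                                 auc = ra$auc))
    pooled_scores <- c(pooled_scores, pred$prob_pathological)
    pooled_truth <- c(pooled_truth, truth)
    pooled_pred <- c(pooled_pred, pred$label)
  }
  cm <- confusion(pooled_truth, pooled_pred)
  pm <- eval_metrics(cm)
  pr <- roc_auc(pooled_scores, pooled_truth)
  summ <- lapply(c(accuracy = "accuracy", sensitivity = "sensitivity",
                   specificity = "specificity", auc = "auc"),
                 function(col) {
                   v <- per_fold[[col]]
                   c(mean = mean(v), min = min(v), max = max(v))
                 })
  pooled <- list(
    metrics = pm,
    confusion = cm,
    accuracy_ci = exact_binomial_ci(cm$tp + cm$tn,
                                    cm$tp + cm$fn + cm$tn + cm$fp),
    sensitivity_ci = exact_binomial_ci(cm$tp, cm$tp + cm$fn),
    specificity_ci = exact_binomial_ci(cm$tn, cm$tn + cm$fp))
  structure(list(family = config$family, per_fold = per_fold,
                 summary = summ, pooled = pooled,
                 roc = pr$roc, auc = pr$auc,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report:%s> %d folds\n", x$family, nrow(x$per_fold)))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-12s %6.1f (%.1f-%.1f)\n", m, s["mean"], s["min"],
                s["max"]))
  }
  cat(sprintf("  pooled AUC %.3f\n", x$auc))
  invisible(x)
}

#' Diagnostic statistics for a human rater
#'
#' Computes the accuracy/sensitivity/specificity row (with exact
#' binomial confidence intervals) and the AUC of a single binary rater
#' against the reference labels, the presentation used for listener
#' studies.
#'
#' @param truth Reference labels (`"normal"`/`"pathological"`).
#' @param rating The rater's binary calls, same vocabulary.
#' @param level CI level (default 0.95).
#' @return List with `accuracy`, `sensitivity`, `specificity` (each a
#'   `proportion_ci`), `auc`, and the `confusion` counts.
#' @export
rater_stats <- function(truth, rating, level = 0.95) {
  cm <- confusion(truth, rating)
  list(accuracy = exact_binomial_ci(cm$tp + cm$tn,
                                    cm$tp + cm$fn + cm$tn + cm$fp, level),
       sensitivity = exact_binomial_ci(cm$tp, cm$tp + cm$fn, level),
       specificity = exact_binomial_ci(cm$tn, cm$tn + cm$fp, level),
       auc = roc_auc(as.numeric(rating == "pathological"), truth)$auc,
       confusion = cm)
}
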