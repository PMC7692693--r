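test_that("stratified folds partition the clinical cohort into 19s", {
  labels <- c(rep("pathological", 50), rep("normal", 45))
  folds <- make_folds(labels, k = 5, seed = 1)
  expect_equal(as.vector(table(folds)), rep(19L, 5L))
  # per-fold class balance within one of perfect stratification
  for (f in 1:5) {
    expect_equal(sum(labels[folds == f] == "pathological"), 10L)
    expect_equal(sum(labels[folds == f] == "normal"), 9L)
  }
  # partition property: union = all, pairwise disjoint is implied by a
  # single assignment vector covering every index
  expect_equal(sort(unlist(lapply(1:5, function(f) which(folds == f)))),
               seq_along(labels))
  expect_identical(make_folds(labels, k = 5, seed = 1), folds)
  expect_false(identical(make_folds(labels, k = 5, seed = 2), folds))
  expect_error(make_folds(c(rep("normal", 20), rep("pathological", 3)), k = 5),
               "at least k")
})

test_that("confusion counts follow the positive = pathological convention", {
  labels <- c(rep("pathological", 50), rep("normal", 45))
  all_normal <- rep("normal", 95)
  cm <- confusion(labels, all_normal)
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 0L, fn = 50L, tn = 45L, fp = 0L))
  perfect <- confusion(labels, labels)
  expect_equal(perfect$fp + perfect$fn, 0L)
  # 10-case worked example, counted by hand
  tr <- c("pathological", "normal", "pathological", "normal", "pathological",
          "normal", "pathological", "normal", "normal", "pathological")
  pr <- c("pathological", "normal", "normal", "pathological", "pathological",
          "normal", "pathological", "normal", "pathological", "normal")
  cm10 <- confusion(tr, pr)
  expect_equal(unclass(cm10)[c("tp", "fn", "tn", "fp")],
               list(tp = 3L, fn = 2L, tn = 3L, fp = 2L))
  expect_error(confusion(tr, pr[1:5]), "length")
  expect_error(confusion(tr, gsub("normal", "healthy", pr)), "label")
})

test_that("metrics arithmetic matches the worked example", {
  cm <- structure(list(tp = 40L, fn = 10L, tn = 40L, fp = 5L),
                  class = "confusion_counts")
  m <- eval_metrics(cm)
  expect_equal(m$accuracy, 100 * 80 / 95, tolerance = 1e-12)   # 84.21%
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 100 * 40 / 45, tolerance = 1e-12) # 88.89%
  # sensitivity depends only on (tp, fn)
  cm2 <- structure(list(tp = 40L, fn = 10L, tn = 7L, fp = 2L),
                   class = "confusion_counts")
  expect_equal(eval_metrics(cm2)$sensitivity, m$sensitivity)
  expect_error(eval_metrics(structure(list(tp = 0L, fn = 0L, tn = 5L, fp = 0L),
                                      class = "confusion_counts")),
               "sensitivity undefined")
})

test_that("accuracy is the prevalence-weighted mix of sensitivity/specificity", {
  set.seed(4)
  for (i in 1:20) {
    cm <- structure(list(tp = sample(1:30, 1), fn = sample(1:30, 1),
                         tn = sample(1:30, 1), fp = sample(1:30, 1)),
                    class = "confusion_counts")
    m <- eval_metrics(cm)
    n_pos <- cm$tp + cm$fn
    n_neg <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * n_pos + m$specificity * n_neg) /
                   (n_pos + n_neg),
                 tolerance = 1e-10)
  }
})

test_that("AUC equals the O(n^2) pairwise oracle, ties counting half", {
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == "pathological"]
    neg <- scores[labels == "normal"]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(8)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    labels <- sample(c("normal", "pathological"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)      # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, pair_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(roc_auc(c(1, 2, 3, 4), c("normal", "normal", "pathological",
                                        "pathological"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("normal", "pathological"), 3))$auc,
               0.5)
  expect_error(roc_auc(1:3, rep("normal", 3)), "both classes")
})

test_that("AUC agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- sample(c("normal", "pathological"), 40, replace = TRUE,
                   prob = c(0.45, 0.55))
  scores <- rnorm(40) + (labels == "pathological")
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("normal", "pathological"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(3)
  labels <- rep(c("normal", "pathological"), each = 15)
  scores <- rnorm(30) + (labels == "pathological") * 1.5
  roc <- roc_auc(scores, labels)$roc
  expect_equal(roc$fpr[1L], 0)
  expect_equal(roc$tpr[1L], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("exact binomial CIs reproduce the published listener-study bounds", {
  # 45/45 correct normals: 100 (92.1-100)
  ci <- exact_binomial_ci(45, 45)
  expect_equal(ci$estimate, 100)
  expect_equal(round(ci$lower, 1), 92.1)
  expect_equal(ci$upper, 100)
  # 40/45: 88.9 (75.9-96.3)
  ci2 <- exact_binomial_ci(40, 45)
  expect_equal(round(ci2$estimate, 1), 88.9)
  expect_equal(round(ci2$lower, 1), 75.9)
  expect_equal(round(ci2$upper, 1), 96.3)
})

test_that("CI closed forms hold at the boundaries", {
  # successes = n: lower = (alpha/2)^(1/n), upper = 100
  for (n in c(10, 45, 90)) {
    ci <- exact_binomial_ci(n, n)
    expect_equal(ci$lower, 100 * 0.025^(1 / n), tolerance = 1e-9)
    expect_equal(ci$upper, 100)
    ci0 <- exact_binomial_ci(0, n)
    expect_equal(ci0$lower, 0)
    expect_equal(ci0$upper, 100 * (1 - 0.025^(1 / n)), tolerance = 1e-9)
  }
  ci <- exact_binomial_ci(7, 10)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  expect_error(exact_binomial_ci(11, 10), "successes")
})

test_that("cross-validated evaluation is leak-free and self-consistent", {
  ftc <- small_cohort_features()
  folds <- make_folds(ftc$labels, k = 5, seed = 3)
  rep1 <- evaluate_model(model_config("svm", seed = 1), ftc$x, ftc$labels,
                         folds)
  # every recording appears in exactly one test fold
  expect_equal(sum(rep1$per_fold$n_test), length(ftc$labels))
  # mean inside min-max range for every metric
  for (m in names(rep1$summary)) {
    s <- rep1$summary[[m]]
    expect_gte(s[["mean"]], s[["min"]])
    expect_lte(s[["mean"]], s[["max"]])
  }
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  # deterministic re-run
  rep2 <- evaluate_model(model_config("svm", seed = 1), ftc$x, ftc$labels,
                         folds)
  expect_equal(rep1$per_fold, rep2$per_fold)
  expect_equal(rep1$auc, rep2$auc)
})

test_that("crop grouping keeps all crops of a recording in one fold", {
  # synthetic crop table: 8 recordings x 4 crops; fold ids per recording
  set.seed(5)
  rec <- sprintf("rec%02d", 1:8)
  labels_rec <- rep(c("normal", "pathological"), 4)
  folds_rec <- make_folds(labels_rec, k = 2, seed = 2)
  groups <- rep(rec, each = 4)
  crops <- lapply(seq_along(groups), function(i) {
    matrix(rnorm(1600, mean = (labels_rec[(i - 1) %/% 4 + 1] ==
                                 "pathological")), 40, 40)
  })
  labels_crop <- rep(labels_rec, each = 4)
  rep1 <- evaluate_model(model_config("cnn2d", seed = 1), crops, labels_crop,
                         folds_rec, groups = groups, epochs = 1,
                         batch_size = 8)
  # each fold tests exactly the recordings assigned to it, aggregated
  expect_equal(sum(rep1$per_fold$n_test), 8L)
  expect_equal(rep1$per_fold$n_test, as.vector(table(folds_rec)))
})

test_that("rater statistics compose CIs and AUC from binary calls", {
  truth <- c(rep("pathological", 50), rep("normal", 45))
  # a rater with 22/50 sensitivity and 45/45 specificity
  rating <- c(rep("pathological", 22), rep("normal", 28), rep("normal", 45))
  rs <- rater_stats(truth, rating)
  expect_equal(rs$sensitivity$estimate, 44)
  expect_equal(rs$specificity$estimate, 100)
  expect_equal(round(rs$specificity$lower, 1), 92.1)
  expect_equal(rs$accuracy$estimate, 100 * 67 / 95, tolerance = 1e-9)
  # AUC of a binary rater = (sens + spec) / 2 on the probability scale
  expect_equal(rs$auc, (0.44 + 1) / 2, tolerance = 1e-12)
})
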