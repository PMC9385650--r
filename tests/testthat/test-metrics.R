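test_that("accuracy handles exact fractions, permutations and empty input", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(c(0, 1, 2, 3), c(0, 1, 2, 0)), 0.75)
  set.seed(1)
  truth <- sample(0:3, 40, replace = TRUE)
  est <- sample(0:3, 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(accuracy(truth, est), accuracy(truth[perm], est[perm]))
  expect_error(accuracy(integer(0), integer(0)), "empty")
})

test_that("ROC points are monotone from (0,0) to (1,1) and handle ties", {
  pts <- roc_points(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(utils::tail(pts$fpr, 1), 1)
  expect_equal(utils::tail(pts$tpr, 1), 1)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))  # perfect separation
  tied <- roc_points(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(tied), 2L)
  expect_equal(tied$fpr, c(0, 1)); expect_equal(tied$tpr, c(0, 1))
  expect_error(roc_points(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("a mixed 6-sample ROC matches exhaustive threshold enumeration", {
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  pts <- roc_points(scores, labels)
  # enumerate every threshold halfway between distinct scores
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  ref <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / sum(labels == 0),
      tpr = sum(pred & labels == 1) / sum(labels == 1))
  }, numeric(2)))
  expect_equal(pts$fpr, unname(ref[, "fpr"]))
  expect_equal(pts$tpr, unname(ref[, "tpr"]))
})

test_that("trapezoidal AUC equals the pairwise rank statistic, including ties", {
  probs <- cbind(c(0.9, 0.8, 0.6, 0.4, 0.4, 0.2, 0.5, 0.1, 0.3, 0.4),
                 c(0.1, 0.2, 0.4, 0.6, 0.6, 0.8, 0.5, 0.9, 0.7, 0.6))
  labels <- c(0, 0, 0, 1, 0, 1, 1, 1, 0, 1)
  got <- auc_ovr(probs, labels, 0)
  ref <- oracle_auc_pairs(probs[, 1], labels == 0)
  expect_equal(got, ref, tolerance = 1e-12)
  # perfect and reversed rankings
  p2 <- cbind(seq(0.9, 0.1, length.out = 6), 1 - seq(0.9, 0.1, length.out = 6))
  expect_equal(auc_ovr(p2, c(0, 0, 0, 1, 1, 1), 0), 1)
  expect_equal(auc_ovr(p2, c(1, 1, 1, 0, 0, 0), 0), 0)
})

test_that("trapezoid equals pairwise concordance on random tied instances", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    pts <- roc_points(scores, labels)
    expect_equal(cascadenet:::trapezoid_auc(pts$fpr, pts$tpr),
                 oracle_auc_pairs(scores, labels), tolerance = 1e-9)
  }
})

test_that("AUC complements under score negation when there are no ties", {
  set.seed(12)
  scores <- runif(30)
  labels <- rep(c(0, 1), 15)
  a1 <- cascadenet:::trapezoid_auc(roc_points(scores, labels)$fpr,
                                   roc_points(scores, labels)$tpr)
  a2 <- cascadenet:::trapezoid_auc(roc_points(-scores, labels)$fpr,
                                   roc_points(-scores, labels)$tpr)
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("macro AUC averages per-class AUCs and flags absent classes", {
  set.seed(13)
  n <- 60
  labels <- sample(0:3, n, replace = TRUE)
  probs <- matrix(runif(n * 4), n, 4)
  probs <- probs / rowSums(probs)
  per <- vapply(0:3, function(k) auc_ovr(probs, labels, k), numeric(1))
  expect_equal(macro_auc(probs, labels), mean(per))
  expect_gte(mean(per), min(per))
  expect_lte(mean(per), max(per))
  expect_error(auc_ovr(probs, labels, 7), "absent")
  labels_no2 <- replace(labels, labels == 2, 0)
  expect_error(macro_auc(probs, labels_no2), "absent")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- round(runif(40), 2)
  labels <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.4, 0.6))
  got <- cascadenet:::trapezoid_auc(roc_points(scores, labels)$fpr,
                                    roc_points(scores, labels)$tpr)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("evaluation reports tie accuracy, confusion and AUCs together", {
  truth <- c(0, 0, 1, 1, 2, 2)
  probs <- rbind(c(0.8, 0.1, 0.1), c(0.5, 0.3, 0.2), c(0.2, 0.7, 0.1),
                 c(0.3, 0.3, 0.4), c(0.1, 0.2, 0.7), c(0.2, 0.1, 0.7))
  rep <- evaluate_predictions(truth, probs)
  expect_equal(rep$accuracy, 5 / 6)
  expect_equal(sum(diag(rep$confusion)) / rep$n_samples, rep$accuracy)
  expect_equal(rep$average_auc, mean(rep$per_class_auc))
  expect_equal(glance(rep)$accuracy, rep$accuracy)
  expect_equal(nrow(tidy(rep)), 3L)
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, js)
  expect_equal(jsonlite::read_json(js)$accuracy, rep$accuracy)
})
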