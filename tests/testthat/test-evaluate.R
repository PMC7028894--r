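test_that("the stratified 70/30 rule reproduces the clinical split counts", {
  man <- dataset_manifest(sprintf("i%03d", 1:212), rep(0:3, clinical_counts))
  sp <- stratified_split(man, split_spec(seed = 1))
  expect_identical(unname(manifest_counts(sp$train)), c(19L, 65L, 43L, 22L))
  expect_identical(unname(manifest_counts(sp$test)), c(8L, 28L, 18L, 9L))
  expect_identical(nrow(sp$train), 149L)
  expect_identical(nrow(sp$test), 63L)
  expect_length(intersect(sp$train$path, sp$test$path), 0L)

  # deterministic given the seed, different under another seed
  sp2 <- stratified_split(man, split_spec(seed = 1))
  expect_identical(sp$train$path, sp2$train$path)
  sp3 <- stratified_split(man, split_spec(seed = 2))
  expect_false(identical(sp$train$path, sp3$train$path))
})

test_that("split arithmetic rounds half-up and protects tiny stages", {
  man10 <- dataset_manifest(sprintf("x%02d", 1:10), rep(0L, 10))
  sp <- stratified_split(man10, split_spec(seed = 3))
  expect_identical(nrow(sp$train), 7L)
  expect_identical(nrow(sp$test), 3L)

  # fraction that would swallow a whole stage: one entry is pushed back
  man4 <- dataset_manifest(c("a", "b", "c", "d"), rep(1L, 4))
  expect_warning(sp4 <- stratified_split(man4,
                                         split_spec(train_fraction = 0.9,
                                                    seed = 1)),
                 "moving one to test")
  expect_identical(nrow(sp4$test), 1L)
})

test_that("balanced splitting first subsamples every stage to the minimum", {
  man <- dataset_manifest(sprintf("i%03d", 1:212), rep(0:3, clinical_counts))
  sp <- stratified_split(man, split_spec(seed = 5, balanced = TRUE))
  cnt <- manifest_counts(sp$train) + manifest_counts(sp$test)
  expect_identical(unname(cnt), rep(27L, 4L))
  expect_identical(unname(manifest_counts(sp$train)), rep(19L, 4L))
})

test_that("binary metrics reproduce the published per-stage arithmetic", {
  # printed sensitivity/specificity of the clinical stage-1 row imply
  # tp=25, fn=3, tn=23, fp=12 on 28 positives / 35 negatives
  cc <- reconstruct_confusion(0.892, 0.657, 28, 35)
  expect_identical(unlist(cc[c("tp", "fn", "tn", "fp")]),
                   c(tp = 25, fn = 3, tn = 23, fp = 12))
  m <- binary_metrics(cc)
  expect_equal(unname(m["tpr"]), 0.893, tolerance = 1e-3)
  expect_equal(unname(m["tnr"]), 0.657, tolerance = 1e-3)
  expect_equal(unname(m["ppv"]), 0.676, tolerance = 1e-3)
  expect_equal(unname(m["f_score"]), 0.769, tolerance = 1e-3)
  expect_equal(unname(m["class_accuracy"]), 48 / 63, tolerance = 1e-12)

  # degenerate and perfect classifiers
  m0 <- binary_metrics(confusion_counts(tp = 0, fn = 5, tn = 5, fp = 0))
  expect_equal(unname(m0[c("tpr", "tnr", "f_score")]), c(0, 1, 0))
  m1 <- binary_metrics(confusion_counts(tp = 7, fn = 0, tn = 9, fp = 0))
  expect_equal(unname(m1[c("tpr", "tnr", "ppv", "f_score",
                           "class_accuracy")]), rep(1, 5))

  expect_error(binary_metrics(confusion_counts(0, 0, 5, 5), stage = 2),
               "stage 2")
})

test_that("rate identities hold on randomly generated confusions", {
  set.seed(19)
  for (i in 1:40) {
    np <- sample(1:40, 1); nn <- sample(1:40, 1)
    tp <- sample(0:np, 1); tn <- sample(0:nn, 1)
    m <- binary_metrics(confusion_counts(tp, np - tp, tn, nn - tn))
    expect_equal(unname(m["tpr"] + m["fnr"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["tnr"] + m["fpr"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["class_accuracy"]), (tp + tn) / (np + nn),
                 tolerance = 1e-12)
    if (m["ppv"] + m["tpr"] > 0 && !attr(m, "ppv_undefined"))
      expect_true(m["f_score"] >= min(m["ppv"], m["tpr"]) - 1e-12 &&
                  m["f_score"] <= max(m["ppv"], m["tpr"]) + 1e-12)
  }
})

test_that("ROC curves have the documented shape in edge cases", {
  # perfectly separating scores pass through (0, 1)
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  # all-tied scores: the single threshold yields the chance diagonal
  rt <- roc_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_identical(nrow(rt), 2L)
  expect_equal(rt$fpr, rt$tpr)           # every point on the diagonal
  expect_equal(auc(rt), 0.5)

  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("reversing score signs complements the ranking", {
  # the mirror symmetry of the ROC under score reversal, checked through
  # its area against brute-force pair counting on small vectors
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(-sc, lb), 1 - auc(sc, lb), tolerance = 1e-12)
    expect_equal(auc(-sc, lb), mw_auc(-sc, lb), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC matches hand-counted orderings and the null", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  # permuted labels: AUC ~ 0.5 within 3 null standard errors
  set.seed(29)
  n1 <- 300; n0 <- 300
  sc <- runif(n1 + n0)
  lb <- sample(rep(c(0, 1), c(n0, n1)))
  se <- sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  expect_lt(abs(auc(sc, lb) - 0.5), 3 * se)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- runif(80)
  lb <- rbinom(80, 1, 0.4)
  expect_equal(auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("model evaluation produces a full per-stage report", {
  cl <- make_cluster_features(counts = c(20L, 20L, 20L, 20L), sep = 6,
                              seed = 37)
  m <- train_ovr(cl$X, cl$labels, family = "LDA")
  rep <- evaluate_model(m, cl$X, cl$labels)
  # perfect predictions: every defined rate is 0/1 as appropriate
  expect_equal(rep$per_stage["average", "class_accuracy"], 1)
  expect_equal(rep$per_stage["average", "tpr"], 1)
  expect_equal(rep$per_stage["average", "fpr"], 0)
  expect_equal(multiclass_accuracy(rep, cl$labels), 1)
  expect_identical(rep$per_stage["average", "n_test"], 80)
})

test_that("a constant majority-stage predictor has TPR 1 / TNR 0 there", {
  truth <- rep(0:3, c(8L, 28L, 18L, 9L))
  pred <- rep(1L, 63)
  scores <- matrix(0, 63, 4); scores[, 2] <- 1
  rep <- suppressWarnings(metrics_from_predictions(pred, scores, truth))
  expect_equal(rep$per_stage["stage1", "tpr"], 1)
  expect_equal(rep$per_stage["stage1", "tnr"], 0)
  expect_equal(rep$per_stage["stage0", "tpr"], 0)
  expect_equal(rep$per_stage["stage1", "class_accuracy"], 28 / 63)
})

test_that("stages absent from the test set are excluded from averages", {
  truth <- rep(c(0L, 1L), c(10L, 10L))
  pred <- truth
  scores <- matrix(0, 20, 4)
  scores[cbind(seq_len(20), truth + 1L)] <- 1
  expect_warning(rep <- metrics_from_predictions(pred, scores, truth),
                 "absent")
  expect_true(is.na(rep$per_stage["stage2", "tpr"]))
  expect_equal(rep$per_stage["average", "class_accuracy"], 1)
})
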