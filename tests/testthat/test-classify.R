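test_that("one-vs-rest training fits four scorers and is seed-deterministic", {
  cl <- make_cluster_features(counts = c(19L, 65L, 43L, 22L), sep = 1.5)
  model <- train_ovr(cl$X, cl$labels, family = "ANN", seed = 7)
  expect_identical(sum(vapply(model$scorers, Negate(is.null), TRUE)), 4L)

  set.seed(101)
  test <- matrix(rnorm(40 * 6), 40, 6)
  p1 <- predict(model, test)
  model2 <- train_ovr(cl$X, cl$labels, family = "ANN", seed = 7)
  p2 <- predict(model2, test)
  expect_identical(p1$stage, p2$stage)
  expect_identical(p1$scores, p2$scores)

  expect_error(train_ovr(cl$X[1:19, ], cl$labels[1:19], family = "ANN"),
               "at least 2 distinct stages")
  expect_error(predict(model, test[, 1:3]), "does not match")
})

test_that("prediction takes the best probability score, ties to low stage", {
  # all four MinDist scorers see the same centroids, so every score is
  # identical and the documented tie-break selects stage 0
  cl <- make_cluster_features(counts = c(8L, 8L, 8L, 8L), sep = 0, seed = 2)
  model <- train_ovr(cl$X, cl$labels, family = "MinDist")
  p <- predict(model, matrix(0, 3, 6))
  expect_true(all(p$stage == which.max(p$scores[1, ]) - 1L))
  same <- abs(p$scores - p$scores[, 1]) < 1e-9
  expect_identical(p$stage[rowSums(same) == 4L],
                   rep(0L, sum(rowSums(same) == 4L)))

  # argmax on a well-separated problem recovers the generating cluster
  cl2 <- make_cluster_features(sep = 6, seed = 3)
  m2 <- train_ovr(cl2$X, cl2$labels, family = "MinDist")
  p2 <- predict(m2, cl2$X)
  expect_identical(p2$stage, cl2$labels)
})

test_that("the perceptron separates well-separated blobs and degenerates safely", {
  set.seed(5)
  n <- 50
  X <- rbind(matrix(rnorm(n * 2, mean = 0), ncol = 2),
             matrix(rnorm(n * 2, mean = 6), ncol = 2))
  y <- rep(c(0, 1), each = n)
  # independent check that the blobs really are linearly separable:
  # project on the center line and compare class extremes
  proj <- X %*% c(1, 1)
  expect_lt(max(proj[y == 0]), min(proj[y == 1]))

  fit <- train_ann_binary(scale(X), y, ann_config(seed = 1))
  pred <- as.integer(predict(fit, scale(X)) > 0.5)
  expect_identical(pred, as.integer(y))  # training accuracy 1.0

  # all-negative labels: fitted scorer stays below 0.5 on its training data
  fit0 <- train_ann_binary(scale(X), rep(0, 2 * n), ann_config(seed = 1))
  expect_true(all(predict(fit0, scale(X)) < 0.5))
})

test_that("perceptron training loss is non-increasing at a small step size", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(60, 0, 0.3) > 0)
  fit <- train_ann_binary(X, y, ann_config(learning_rate = 0.01,
                                           epochs = 300, seed = 2))
  expect_true(all(diff(fit$loss) <= 1e-8))
})

test_that("score transforms return calibrated values in [0, 1]", {
  # MinDist equidistant from both centroids scores exactly 0.5
  X <- rbind(c(-1, 0), c(1, 0), c(-2, 0), c(2, 0))
  y <- c(0, 1, 0, 1)
  sc <- thermostage:::fit_binary_scorer("MinDist", X, y)
  expect_equal(as.numeric(score_scorer(sc, matrix(c(0, 5), 1, 2))), 0.5)

  # KNN score is the fraction of positive neighbors: 4 of 5 -> 0.8
  Xk <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.1, 0.1), c(0.05, 0.05),
              c(9, 9), c(9.1, 9), c(9, 9.1))
  yk <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sck <- thermostage:::fit_binary_scorer("KNN", Xk, yk, params = list(k = 5))
  expect_equal(as.numeric(score_scorer(sck, matrix(c(0.05, 0), 1, 2))), 0.8)

  # every family returns scores inside [0, 1]
  cl <- make_cluster_features(counts = c(15L, 15L, 15L, 15L), sep = 2,
                              seed = 9)
  test <- matrix(rnorm(30 * 6, sd = 3), 30, 6)
  for (fam in classifier_families()) {
    m <- train_ovr(cl$X, cl$labels, family = fam, seed = 4)
    s <- predict(m, test)$scores
    expect_true(all(s >= 0 & s <= 1), info = fam)
  }
})

test_that("with two stages the fusion reduces to the binary decision", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
  labels <- rep(c(0L, 2L), each = 30)
  m <- train_ovr(X, labels, family = "LogReg")
  p <- predict(m, X)
  # fused label must equal the pairwise comparison of the two live scorers
  manual <- ifelse(p$scores[, 1] >= p$scores[, 3], 0L, 2L)
  expect_identical(p$stage, manual)
  expect_true(all(p$stage %in% c(0L, 2L)))
})

test_that("a stage with no positives is flagged and never predicted", {
  cl <- make_cluster_features(counts = c(10L, 10L, 10L, 0L), sep = 5,
                              seed = 13)
  expect_warning(m <- train_ovr(cl$X, cl$labels, family = "LogReg"),
                 "untrainable")
  p <- predict(m, matrix(rnorm(100 * 6, 2), 100, 6))
  expect_false(any(p$stage == 3L))
  expect_true(all(p$scores[, 4] == 0))
})

test_that("the benchmark grid enumerates the full method cross", {
  g <- enumerate_grid(feature_methods(), classifier_families())
  expect_identical(nrow(g), 54L)
  expect_identical(anyDuplicated(paste(g$extractor, g$family)), 0L)
  # the full design with all nine published extractor names
  nine <- c(feature_methods(), "surf", "brisk", "hog_brisk")
  expect_identical(nrow(enumerate_grid(nine, classifier_families())), 81L)
})

test_that("models serialize and reload with identical predictions", {
  cl <- make_cluster_features(counts = c(8L, 8L, 8L, 8L), sep = 3, seed = 15)
  m <- train_ovr(cl$X, cl$labels, family = "DT")
  p <- file.path(tempdir(), "model.rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(predict(m2, cl$X)$stage, predict(m, cl$X)$stage)
})

test_that("strong stage effects drive the reference system to high accuracy", {
  # large-effect generator setting: sub- to super-saturating blob counts
  # with big amplitudes, so HOG texture signatures separate cleanly
  strong <- synth_config(lambda = c(0, 15, 60, 200),
                         amplitude = c(0, 0.2, 0.45, 0.8),
                         blob_radius = c(3, 8))
  imgs <- generate_thermogram_set(c(27L, 93L, 61L, 31L), strong, seed = 17)
  rois <- lapply(imgs, extract_roi)
  X <- feature_matrix(feature_extractor("hog"), rois)
  labels <- vapply(rois, function(r) r$stage, 0L)
  man <- dataset_manifest(sprintf("i%03d", seq_along(rois)), labels)
  for (sd in 1:3) {
    sp <- stratified_split(man, split_spec(seed = sd))
    itr <- match(sp$train$path, man$path)
    ite <- match(sp$test$path, man$path)
    m <- train_ovr(X[itr, ], labels[itr], family = "ANN",
                   params = list(learning_rate = 0.3), seed = sd)
    rep <- evaluate_model(m, X[ite, ], labels[ite])
    # "accuracy" on the published scale: stage-averaged one-vs-rest
    # class accuracy (the Table-style headline metric)
    expect_gte(rep$per_stage["average", "class_accuracy"], 0.9)
    expect_gt(multiclass_accuracy(rep, labels[ite]), 28 / 63)
  }
})
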