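#' Names of the implemented classifier families
#'
#' Minimum distance, k-nearest neighbors, naive Bayes, (ridge-penalized)
#' logistic regression, support vector machine, linear discriminant
#' analysis, decision tree, random forest, and the three-layer artificial
#' neural network.
#'
#' @return character vector of 9 family names.
#' @export
classifier_families <- function()
  c("MinDist", "KNN", "NB", "LogReg", "SVM", "LDA", "DT", "RF", "ANN")

#' Enumerate the feature-method x classifier benchmark grid
#'
#' @param extractors character vector of feature-method names.
#' @param families character vector of classifier-family names.
#' @return data frame with one row per (extractor, family) combination,
#'   ordered extractor-major.
#' @examples
#' nrow(enumerate_grid(feature_methods(), classifier_families()))  # 54
#' @export
enumerate_grid <- function(extractors = feature_methods(),
                           families = classifier_families()) {
  expand.grid(family = families, extractor = extractors,
              stringsAsFactors = FALSE)[, c("extractor", "family")]
}

# default per-family hyperparameters
default_family_params <- function() {
  list(KNN = list(k = 5L),
       SVM = list(cost = 1, kernel = "radial"),
       RF = list(ntree = 100L),
       LogReg = list(lambda = 1e-2),
       ANN = ann_config())
}

# ---- binary scorers ---------------------------------------------------------

# Each fitter returns a `binary_scorer` whose score_scorer() maps raw model
# output to a probability score in [0, 1]:
#   NB / LogReg / RF / ANN / LDA -> native posterior or probability
#   SVM  -> Platt-style logistic calibration (e1071's probability model)
#   KNN  -> fraction of positive neighbors among the k nearest
#   DT   -> leaf class fraction
#   MinDist -> softmin over the distances to the two class centroids
fit_binary_scorer <- function(family, X, y, params = list(), weights = NULL,
                              seed = 17L) {
  defaults <- default_family_params()[[family]]
  if (!is.null(defaults)) {
    params <- utils::modifyList(
      if (inherits(defaults, "ann_config")) unclass(defaults) else defaults,
      params)
  }
  yf <- factor(y, levels = c(0, 1))
  set.seed(seed)
  fit <- switch(family,
    MinDist = {
      mu0 <- colMeans(X[y == 0, , drop = FALSE])
      mu1 <- colMeans(X[y == 1, , drop = FALSE])
      list(mu0 = mu0, mu1 = mu1)
    },
    KNN = list(X = X, y = y, k = params$k),
    NB = e1071::naiveBayes(x = as.data.frame(X), y = yf),
    LogReg = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                            lambda = params$lambda, standardize = FALSE,
                            weights = weights),
    SVM = {
      cw <- if (is.null(weights)) NULL else {
        # translate sample weights to class weights (constant within class)
        c("0" = weights[y == 0][1], "1" = weights[y == 1][1])
      }
      e1071::svm(X, yf, kernel = params$kernel, cost = params$cost,
                 gamma = 1 / ncol(X), probability = TRUE,
                 class.weights = cw)
    },
    LDA = {
      keep <- which(apply(X, 2, function(col)
        sd(col[y == 0]) > 1e-8 || sd(col[y == 1]) > 1e-8))
      list(keep = keep,
           fit = suppressWarnings(MASS::lda(X[, keep, drop = FALSE], yf)))
    },
    DT = {
      df <- as.data.frame(X); df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
                   control = rpart::rpart.control(cp = 0.01, xval = 0))
    },
    RF = randomForest::randomForest(X, yf, ntree = params$ntree),
    ANN = {
      cfg <- do.call(ann_config,
                     params[intersect(names(params),
                                      c("hidden_units", "learning_rate",
                                        "epochs", "seed"))])
      cfg$seed <- seed
      train_ann_binary(X, y, cfg, sample_weights = weights)
    },
    stop("unknown classifier family '", family, "'")
  )
  structure(list(family = family, fit = fit, params = params),
            class = "binary_scorer")
}

#' Probability score of a fitted binary scorer
#'
#' @param scorer a \code{binary_scorer}.
#' @param X feature matrix on the scale the scorer was trained on.
#' @return numeric vector of scores in \code{[0, 1]} (probability of the
#'   positive class).
#' @export
score_scorer <- function(scorer, X) {
  X <- as.matrix(X)
  f <- scorer$fit
  s <- switch(scorer$family,
    MinDist = {
      d0 <- sqrt(rowSums(sweep(X, 2, f$mu0)^2))
      d1 <- sqrt(rowSums(sweep(X, 2, f$mu1)^2))
      tau <- pmax((d0 + d1) / 2, 1e-12)   # scale-free softmin temperature
      .sigmoid((d0 - d1) / tau)
    },
    KNN = {
      pr <- class::knn(f$X, X, factor(f$y, levels = c(0, 1)), k = f$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    NB = predict(f, as.data.frame(X), type = "raw")[, "1"],
    LogReg = as.vector(predict(f, X, type = "response")),
    SVM = {
      pr <- predict(f, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    LDA = {
      post <- predict(f$fit, X[, f$keep, drop = FALSE])$posterior
      if ("1" %in% colnames(post)) post[, "1"] else 1 - post[, "0"]
    },
    DT = predict(f, as.data.frame(X), type = "prob")[, "1"],
    RF = predict(f, X, type = "prob")[, "1"],
    ANN = predict(f, X)
  )
  .clamp(as.numeric(s))
}

# ---- one-vs-rest fusion -----------------------------------------------------

#' Train a one-vs-rest multiclass model
#'
#' For each stage s in 0..3 a binary scorer is fitted on labels
#' \code{y = 1} iff \code{stage == s}; at prediction time the stage with the
#' best probability score wins. Features are z-scaled per dimension with
#' statistics estimated on the training set only. Because stage prevalences
#' are typically unbalanced, each binary fit can weight samples by inverse
#' prevalence (default on; MinDist, KNN and NB have no weighted form and
#' ignore the toggle).
#'
#' @param X numeric feature matrix (rows = samples).
#' @param labels stage labels in 0..3, one per row.
#' @param family one of \code{\link{classifier_families}}.
#' @param params optional named list of family hyperparameters.
#' @param balance_weights use inverse-prevalence sample weights.
#' @param seed seed consumed by every stochastic fit.
#' @return an \code{ovr_model}.
#' @export
train_ovr <- function(X, labels, family = "ANN", params = list(),
                      balance_weights = TRUE, seed = 17L) {
  X <- as.matrix(X)
  labels <- vapply(labels, validate_stage, 0L)
  if (nrow(X) != length(labels)) stop("X rows and labels differ in length")
  if (length(unique(labels)) < 2L)
    stop("one-vs-rest training needs at least 2 distinct stages")
  family <- match.arg(family, classifier_families())

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  scorers <- vector("list", 4L)
  for (s in 0:3) {
    y <- as.integer(labels == s)
    if (sum(y) == 0L) {
      warning("stage ", s, " has no positive training examples; ",
              "its scorer is untrainable and will never be selected")
      next
    }
    w <- if (balance_weights) {
      n <- length(y)
      ifelse(y == 1, n / (2 * sum(y)), n / (2 * sum(1 - y)))
    } else NULL
    scorers[[s + 1L]] <- fit_binary_scorer(family, Xs, y, params,
                                           weights = w, seed = seed + s)
  }
  structure(list(scorers = scorers, family = family, center = ctr,
                 scale = scl, params = params,
                 balance_weights = balance_weights, seed = as.integer(seed)),
            class = "ovr_model")
}

#' Predict stages with a one-vs-rest model
#'
#' Returns the stage whose binary scorer gives the best probability score;
#' ties break toward the lowest stage index. Untrainable scorers report a
#' score of 0 and are never selected while any trainable score exists.
#'
#' @param object an \code{ovr_model}.
#' @param newdata feature matrix with the same columns as in training.
#' @param ... unused.
#' @return list with \code{stage} (integer vector) and \code{scores}
#'   (matrix n x 4, columns stage 0..3).
#' @export
predict.ovr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$center))
    stop("feature length ", ncol(X), " does not match the model (",
         length(object$center), ")")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  scores <- matrix(0, nrow(X), 4L, dimnames = list(NULL, paste0("stage", 0:3)))
  sel <- matrix(-Inf, nrow(X), 4L)
  for (s in 0:3) {
    sc <- object$scorers[[s + 1L]]
    if (is.null(sc)) next
    scores[, s + 1L] <- score_scorer(sc, Xs)
    sel[, s + 1L] <- scores[, s + 1L]
  }
  stage <- max.col(sel, ties.method = "first") - 1L
  list(stage = stage, scores = scores)
}

#' @export
print.ovr_model <- function(x, ...) {
  ok <- vapply(x$scorers, Negate(is.null), TRUE)
  cat(sprintf("<ovr_model> family %s, %d/4 trainable scorers, %d features\n",
              x$family, sum(ok), length(x$center)))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Models are serialized with an embedded format version, the feature
#' method configuration and the training-scale parameters. The format is
#' documented but not guaranteed stable across package versions.
#'
#' @param model an \code{ovr_model} (optionally with an attached extractor).
#' @param path file path.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L,
               package_version = as.character(utils::packageVersion("thermostage")),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  if (is.null(blob$format_version) || blob$format_version != 1L)
    stop("unrecognized model format in '", path, "'")
  blob$model
}
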