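#' Stratified split specification
#'
#' @param train_fraction fraction of each stage assigned to training
#'   (default 0.7, rounded half-up per stage).
#' @param seed seed for the within-stage permutation.
#' @param balanced if \code{TRUE}, every stage is first subsampled down to
#'   the minimum per-stage count (seeded) before splitting, reproducing a
#'   balanced-database experiment.
#' @return a \code{split_spec} list.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 17L, balanced = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 balanced = isTRUE(balanced)),
            class = "split_spec")
}

#' Stratified train/test split of a manifest
#'
#' Within every stage with n entries, \code{round_half_up(train_fraction*n)}
#' entries go to training and the remainder to test, guaranteeing each
#' present stage is represented in training. For the clinical class counts
#' \{27, 93, 61, 31\} at fraction 0.7 this yields train counts
#' \{19, 65, 43, 22\} and test counts \{8, 28, 18, 9\}. Which entries land
#' in training is a seeded within-stage permutation, so the split is
#' deterministic given the seed. If rounding would send a whole stage of
#' two or more entries to training, one entry is moved back to test with a
#' warning.
#'
#' @param manifest a \code{dataset_manifest}.
#' @param spec a \code{\link{split_spec}}.
#' @return list with elements \code{train} and \code{test}, both
#'   \code{dataset_manifest}s.
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  set.seed(spec$seed)
  stages_present <- sort(unique(manifest$stage))
  take <- integer(0)
  if (spec$balanced) {
    m_min <- min(table(manifest$stage))
    idx_bal <- integer(0)
    for (s in stages_present) {
      idx <- which(manifest$stage == s)
      idx_bal <- c(idx_bal, sort(sample(idx, m_min)))
    }
    manifest <- manifest[sort(idx_bal), , drop = FALSE]
  }
  train_idx <- integer(0)
  for (s in stages_present) {
    idx <- which(manifest$stage == s)
    n <- length(idx)
    n_train <- .round_half_up(spec$train_fraction * n)
    if (n_train == n && n >= 2L) {
      warning("stage ", s, ": rounding put all ", n,
              " entries in training; moving one to test")
      n_train <- n - 1L
    }
    train_idx <- c(train_idx, sample(idx)[seq_len(n_train)])
  }
  test_idx <- setdiff(seq_len(nrow(manifest)), train_idx)
  nm <- attr(manifest, "name") %||% "dataset"
  list(train = dataset_manifest(manifest$path[sort(train_idx)],
                                manifest$stage[sort(train_idx)],
                                name = paste0(nm, "_train")),
       test = dataset_manifest(manifest$path[sort(test_idx)],
                               manifest$stage[sort(test_idx)],
                               name = paste0(nm, "_test")))
}

#' Confusion counts for one one-vs-rest stage
#'
#' @param tp,fn,tn,fp non-negative integer counts.
#' @return a \code{confusion_counts} list.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Given a stage's sensitivity, specificity and the positive/negative test
#' counts, recovers the unique integer confusion matrix (rates are rounded
#' to the nearest integer count).
#'
#' @param tpr sensitivity (true positive rate).
#' @param tnr specificity (true negative rate).
#' @param n_pos,n_neg positive and negative test counts.
#' @return a \code{\link{confusion_counts}}.
#' @export
reconstruct_confusion <- function(tpr, tnr, n_pos, n_neg) {
  tp <- round(tpr * n_pos)
  tn <- round(tnr * n_neg)
  confusion_counts(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Binary confusion metrics for one stage
#'
#' Computes TPR (sensitivity), FNR (miss rate), TNR (specificity), FPR
#' (fall-out), PPV (precision), F-score and the one-vs-rest class accuracy
#' \code{(tp + tn) / N}. PPV is defined as 0 (flagged by attribute
#' \code{"ppv_undefined"}) when no positive predictions exist; the F-score
#' is 0 when PPV and TPR are both 0.
#'
#' @param counts a \code{\link{confusion_counts}}.
#' @param stage optional stage id used in error messages.
#' @return named numeric vector with elements \code{tpr, fnr, tnr, fpr,
#'   ppv, f_score, class_accuracy}.
#' @export
binary_metrics <- function(counts, stage = NULL) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  lab <- if (is.null(stage)) "" else paste0(" for stage ", stage)
  if (tp + fn < 1L)
    stop("metrics undefined", lab, ": no positive test examples")
  if (tn + fp < 1L)
    stop("metrics undefined", lab, ": no negative test examples")
  tpr <- tp / (tp + fn); fnr <- fn / (tp + fn)
  tnr <- tn / (tn + fp); fpr <- fp / (tn + fp)
  ppv_undef <- (tp + fp) == 0L
  ppv <- if (ppv_undef) 0 else tp / (tp + fp)
  f <- if (ppv + tpr == 0) 0 else 2 * ppv * tpr / (ppv + tpr)
  out <- c(tpr = tpr, fnr = fnr, tnr = tnr, fpr = fpr, ppv = ppv,
           f_score = f,
           class_accuracy = (tp + tn) / (tp + fn + tn + fp))
  attr(out, "ppv_undefined") <- ppv_undef
  out
}

#' ROC curve from scores and binary labels
#'
#' One operating point per distinct score threshold plus the (0,0) and
#' (1,1) endpoints; both coordinates are monotone non-decreasing.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels in \code{{0, 1}}.
#' @return data frame with columns \code{fpr}, \code{tpr}, \code{threshold}
#'   (\code{Inf} and \code{-Inf} at the endpoints), class \code{roc_curve}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC curve undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied score
  df <- data.frame(fpr = c(0, fp[last] / n_neg),
                   tpr = c(0, tp[last] / n_pos),
                   threshold = c(Inf, s[last]))
  if (df$fpr[nrow(df)] != 1 || df$tpr[nrow(df)] != 1)
    df <- rbind(df, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  class(df) <- c("roc_curve", "data.frame")
  df
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the ROC points; mathematically equal to the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, counting ties one half.
#'
#' @param x a \code{\link{roc_curve}}, or a numeric score vector (in which
#'   case \code{labels} must be given).
#' @param labels binary labels when \code{x} is a score vector.
#' @return AUC in \code{[0, 1]}.
#' @export
auc <- function(x, labels = NULL) {
  curve <- if (inherits(x, "roc_curve")) x else roc_curve(x, labels)
  n <- nrow(curve)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-n]) / 2)
}

#' Evaluate a one-vs-rest model on a test set
#'
#' Fused predictions define per-stage one-vs-rest confusion counts; each
#' stage's ROC and AUC come from that stage's score column against the
#' one-vs-rest test labels. The report mirrors the per-stage summary-table
#' layout: one row per stage (n_test, TPR, FNR, TNR, PPV, FPR, F-score,
#' AUC, class accuracy) plus a final row of unweighted averages over the
#' stages present in the test set. Stages absent from the test set are
#' reported as \code{NA} and excluded from the averages with a warning.
#'
#' @param model an \code{ovr_model}.
#' @param X_test feature matrix for the test images.
#' @param labels_test stage labels for the test images.
#' @return a \code{metrics_report}: list with \code{per_stage} (data frame,
#'   5 rows: stages 0..3 and "average"), \code{confusion} (list of
#'   \code{\link{confusion_counts}}), \code{roc} (list of
#'   \code{\link{roc_curve}}s), \code{predictions} and \code{scores}.
#' @export
evaluate_model <- function(model, X_test, labels_test) {
  if (length(labels_test) == 0L) stop("test set is empty")
  labels_test <- vapply(labels_test, validate_stage, 0L)
  pred <- predict(model, X_test)
  metrics_from_predictions(pred$stage, pred$scores, labels_test)
}

#' Build a metrics report from predictions and scores
#'
#' @param predicted integer predicted stages (0..3).
#' @param scores matrix n x 4 of per-stage probability scores.
#' @param truth integer true stages (0..3).
#' @return a \code{metrics_report}; see \code{\link{evaluate_model}}.
#' @export
metrics_from_predictions <- function(predicted, scores, truth) {
  cols <- c("n_test", "tpr", "fnr", "tnr", "ppv", "fpr", "f_score", "auc",
            "class_accuracy")
  tab <- matrix(NA_real_, 5L, length(cols),
                dimnames = list(c(paste0("stage", 0:3), "average"), cols))
  confusion <- vector("list", 4L)
  roc <- vector("list", 4L)
  for (s in 0:3) {
    pos <- truth == s
    if (!any(pos)) {
      warning("stage ", s, " absent from the test set; ",
              "its row is undefined and excluded from averages")
      next
    }
    cc <- confusion_counts(tp = sum(pos & predicted == s),
                           fn = sum(pos & predicted != s),
                           tn = sum(!pos & predicted != s),
                           fp = sum(!pos & predicted == s))
    m <- binary_metrics(cc, stage = s)
    a <- if (all(pos)) NA_real_ else auc(scores[, s + 1L], as.integer(pos))
    if (!all(pos)) roc[[s + 1L]] <- roc_curve(scores[, s + 1L],
                                              as.integer(pos))
    tab[s + 1L, ] <- c(sum(pos), m["tpr"], m["fnr"], m["tnr"], m["ppv"],
                       m["fpr"], m["f_score"], a, m["class_accuracy"])
    confusion[[s + 1L]] <- cc
  }
  defined <- which(!is.na(tab[1:4, "n_test"]))
  tab["average", ] <- colMeans(tab[defined, , drop = FALSE], na.rm = TRUE)
  tab["average", "n_test"] <- sum(tab[defined, "n_test"])
  structure(list(per_stage = as.data.frame(tab), confusion = confusion,
                 roc = roc, predictions = predicted, scores = scores),
            class = "metrics_report")
}

#' Overall multiclass accuracy of a report
#'
#' Fraction of test images whose fused predicted stage equals the true
#' stage (distinct from the per-stage one-vs-rest class accuracy).
#'
#' @param report a \code{metrics_report}.
#' @param truth integer true stages used to build the report.
#' @return accuracy in \code{[0, 1]}.
#' @export
multiclass_accuracy <- function(report, truth) {
  mean(report$predictions == truth)
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report> per-stage one-vs-rest results\n")
  tab <- x$per_stage
  tab[, -1] <- round(tab[, -1], digits)
  print(tab)
  invisible(x)
}
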