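#' Precision, recall and F-measure from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 * precision * recall / (precision + recall)`. A zero denominator
#' yields 0 with a warning rather than NaN.
#'
#' @param counts Named list or vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `precision`, `recall`, `F`.
#' @export
prf <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]; FN <- counts[["FN"]]
  precision <- if (TP + FP == 0) {
    warning("no positive predictions; precision set to 0")
    0
  } else TP / (TP + FP)
  recall <- if (TP + FN == 0) {
    warning("no positive truths; recall set to 0")
    0
  } else TP / (TP + FN)
  F <- if (precision + recall == 0) {
    warning("precision + recall is 0; F-measure set to 0")
    0
  } else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, F = F)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted +1/-1 labels.
#' @param truth Logical (TRUE = positive).
#' @return Named integer vector TP, FP, TN, FN.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  pos <- predicted == 1L
  c(TP = sum(pos & truth), FP = sum(pos & !truth),
    TN = sum(!pos & !truth), FN = sum(!pos & truth))
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param scores Numeric decision scores.
#' @param positive Logical vector, TRUE for positives.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Balanced fold assignment; with strata, balanced within each stratum.
make_folds <- function(n, k, strata = NULL) {
  stopifnot(k >= 2L, n >= k)
  if (is.null(strata)) {
    sample(rep(seq_len(k), length.out = n))
  } else {
    id <- integer(n)
    for (s in unique(strata)) {
      rows <- which(strata == s)
      id[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
    }
    id
  }
}

#' Random negative selection baseline
#'
#' The conventional alternative to reliable-negative extraction: a uniform
#' sample without replacement from the unlabeled pool.
#'
#' @param u_rows Unlabeled row indices.
#' @param size Number of "negatives" to draw (`size <= length(u_rows)`).
#' @return Integer vector of sampled rows.
#' @export
random_negative_baseline <- function(u_rows, size) {
  if (size > length(u_rows)) stop("size exceeds unlabeled pool")
  if (size == 0L) return(integer())
  sample(u_rows, size)
}

#' Fit the full screening pipeline
#'
#' Feature selection on P vs U, reliable-negative extraction, similarity
#' weighting of the ambiguous remainder and similarity-weighted SVM
#' training. With `negatives = "random"` the extraction and weighting
#' stages are replaced by a size-matched random negative draw (the
#' baseline the method is designed to beat); the match size is the number
#' of reliable negatives the consensus extractor finds on the same data.
#'
#' @param x Feature matrix (all samples).
#' @param p_rows,u_rows Positive and unlabeled row indices.
#' @param config A [pudti_config()].
#' @param negatives `"ndtise"` (default) or `"random"`.
#' @param seed Optional seed set on entry.
#' @return Object of class `pudti_fit`: `model` (`svm_sw`), `selected`
#'   feature indices, `split`, `weights`, `config`.
#' @export
pudti_fit <- function(x, p_rows, u_rows, config = pudti_config(),
                      negatives = c("ndtise", "random"), seed = NULL) {
  negatives <- match.arg(negatives)
  if (!is.null(seed)) set.seed(seed)
  sel <- select_features(x, p_rows, u_rows, k = config$top_k,
                         policy = config$binarize)
  xs <- x[, sel$selected, drop = FALSE]
  split <- ndtise(xs, p_rows, u_rows, config)
  if (negatives == "random") {
    rn <- random_negative_baseline(u_rows, length(split$RN))
    split <- structure(list(P = p_rows, EP = integer(), RN = rn,
                            A = setdiff(u_rows, rn), P_aug = p_rows,
                            c_spy = split$c_spy, c_roc = split$c_roc),
                       class = "sample_split")
    # baseline: no ambiguity modelling; train on P vs random RN only
    split$A <- integer()
  }
  weights <- compute_similarity_weights(xs, split, config)
  model <- svm_sw_fit(xs, split, weights, config)
  out <- list(model = model, selected = sel$selected, split = split,
              weights = weights, config = config)
  class(out) <- "pudti_fit"
  out
}

#' Score new samples with a fitted pipeline
#'
#' @param object A `pudti_fit`.
#' @param newdata Feature matrix in the original (unselected) space.
#' @param ... Unused.
#' @return Data frame with `score` and `label`.
#' @export
predict.pudti_fit <- function(object, newdata, ...) {
  predict(object$model, newdata[, object$selected, drop = FALSE])
}

#' Pairwise cross-validation with positive-unlabeled splits
#'
#' The evaluation protocol: all drug-target pairs are partitioned into
#' `folds` mutually exclusive subsets; in turn each subset is masked and
#' used as the test set. Within the training pairs, `r` percent of the
#' known interactions form the positive set `P`; the remaining known
#' interactions are hidden among the unknown pairs to form the unlabeled
#' set `U`. The whole pipeline is re-run from scratch on each training
#' split and scored on the masked fold, where unlabeled test pairs count
#' as negatives. The experiment is repeated `trials` times and metrics are
#' averaged.
#'
#' @param x Feature matrix, one row per drug-target pair.
#' @param known Logical vector: TRUE for pairs recorded as interacting.
#' @param config A [pudti_config()] (uses `folds`, `trials`, `r` and all
#'   pipeline parameters).
#' @param negatives `"ndtise"` or `"random"` baseline, see [pudti_fit()].
#' @param seed Seed set on entry; the whole report is reproducible from
#'   it.
#' @return List of class `cv_report`: `per_fold` data frame (trial, fold,
#'   precision, recall, F, auc), `summary` (means and sds), `leakage_ok`.
#' @export
pairwise_cv <- function(x, known, config = pudti_config(),
                        negatives = c("ndtise", "random"), seed = NULL) {
  negatives <- match.arg(negatives)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  stopifnot(length(known) == n)
  if (config$folds < 2L) stop("folds must be at least 2")
  if (sum(known) < config$folds) stop("fewer positives than folds")
  rows <- seq_len(n)
  res <- list()
  leakage_ok <- TRUE
  for (trial in seq_len(config$trials)) {
    fold_id <- make_folds(n, config$folds)
    for (f in seq_len(config$folds)) {
      test <- rows[fold_id == f]
      train <- rows[fold_id != f]
      stopifnot(length(intersect(train, test)) == 0L)
      leakage_ok <- leakage_ok && length(intersect(train, test)) == 0L
      kn_train <- train[known[train]]
      if (length(kn_train) == 0L) stop("training fold with no positives")
      nP <- max(1L, round(config$r / 100 * length(kn_train)))
      p_rows <- sample(kn_train, nP)
      u_rows <- setdiff(train, p_rows)
      fit <- pudti_fit(x, p_rows, u_rows, config, negatives = negatives)
      pred <- predict(fit, x[test, , drop = FALSE])
      truth <- known[test]
      if (length(unique(truth)) < 2L) {
        stop("test fold with a single class; enlarge the dataset")
      }
      cc <- confusion_counts(pred$label, truth)
      m <- suppressWarnings(prf(cc))
      res[[length(res) + 1L]] <- data.frame(
        trial = trial, fold = f,
        precision = m[["precision"]], recall = m[["recall"]],
        F = m[["F"]], auc = auc_score(pred$score, truth))
    }
  }
  per_fold <- do.call(rbind, res)
  summary <- data.frame(
    metric = c("precision", "recall", "F", "auc"),
    mean = vapply(c("precision", "recall", "F", "auc"),
                  function(m) mean(per_fold[[m]]), 0),
    sd = vapply(c("precision", "recall", "F", "auc"),
                function(m) stats::sd(per_fold[[m]]), 0))
  out <- list(per_fold = per_fold, summary = summary,
              leakage_ok = leakage_ok)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("pairwise cross-validation report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
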