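#' Pipeline configuration
#'
#' Collects every tunable parameter of the screening pipeline in one
#' validated list. Defaults are the settings used throughout the package's
#' documentation and tests.
#'
#' @param r Percent of known interactions used to form the positive set `P`
#'   in a positive-unlabeled split; the remaining known interactions are
#'   hidden in the unlabeled pool. Default 30.
#' @param top_k Number of features kept by the discriminant-ability filter.
#'   Default 300 (capped at the number of available features downstream).
#' @param t Cluster budget shared between the reliable-negative and
#'   ambiguous k-means partitions. Default 30.
#' @param rocchio_alpha,rocchio_beta Weights of the own-class and
#'   opposing-class centroids in Rocchio prototypes. Defaults 16 and 4.
#' @param balance_alpha Mixing weight between global and local similarity
#'   weights (0 = purely local, 1 = purely global). Default 0.6.
#' @param spy_ratio Fraction of positives sent into the unlabeled pool as
#'   spies. Default 0.15.
#' @param spy_noise_percentile Percentile of spy posteriors used as the
#'   negative-decision threshold. Default 5.
#' @param em_max_iter,em_tol EM iteration cap and convergence tolerance for
#'   the spy classifier. Defaults 50 and 1e-4.
#' @param C1,C2,C3,C4 Slack penalties of the similarity-weighted SVM for
#'   positives, positive-side ambiguous rows, negative-side ambiguous rows
#'   and reliable negatives. All default to 1.
#' @param rbf_gamma RBF kernel width; `NULL` means 1 / (number of features)
#'   at training time.
#' @param svm_tol Dual solver stopping tolerance. Default 1e-6.
#' @param binarize Feature-presence policy for continuous features:
#'   `"median"` (strictly above the column median over P and U) or
#'   `"nonzero"`. Default `"median"`.
#' @param folds,trials Cross-validation folds and repeats. Defaults 5, 10.
#' @param seed Integer seed driving every randomized stage.
#'
#' @return A list of class `pudti_config`.
#' @export
pudti_config <- function(r = 30, top_k = 300, t = 30,
                         rocchio_alpha = 16, rocchio_beta = 4,
                         balance_alpha = 0.6,
                         spy_ratio = 0.15, spy_noise_percentile = 5,
                         em_max_iter = 50, em_tol = 1e-4,
                         C1 = 1, C2 = 1, C3 = 1, C4 = 1,
                         rbf_gamma = NULL, svm_tol = 1e-6,
                         binarize = c("median", "nonzero"),
                         folds = 5, trials = 10, seed = 1L) {
  binarize <- match.arg(binarize)
  cfg <- list(
    r = r, top_k = top_k, t = t,
    rocchio_alpha = rocchio_alpha, rocchio_beta = rocchio_beta,
    balance_alpha = balance_alpha,
    spy_ratio = spy_ratio, spy_noise_percentile = spy_noise_percentile,
    em_max_iter = em_max_iter, em_tol = em_tol,
    C1 = C1, C2 = C2, C3 = C3, C4 = C4,
    rbf_gamma = rbf_gamma, svm_tol = svm_tol,
    binarize = binarize, folds = folds, trials = trials,
    seed = as.integer(seed)
  )
  class(cfg) <- "pudti_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    "r must be in (0, 100]" = cfg$r > 0 && cfg$r <= 100,
    "top_k must be positive" = cfg$top_k >= 1,
    "t must be positive" = cfg$t >= 1,
    "balance_alpha must be in [0, 1]" =
      cfg$balance_alpha >= 0 && cfg$balance_alpha <= 1,
    "rocchio weights must be positive" =
      cfg$rocchio_alpha > 0 && cfg$rocchio_beta > 0,
    "spy_ratio must be in (0, 1)" = cfg$spy_ratio > 0 && cfg$spy_ratio < 1,
    "spy_noise_percentile must be in (0, 100)" =
      cfg$spy_noise_percentile > 0 && cfg$spy_noise_percentile < 100,
    "penalties must be positive" =
      cfg$C1 > 0 && cfg$C2 > 0 && cfg$C3 > 0 && cfg$C4 > 0,
    "folds must be at least 2" = cfg$folds >= 2,
    "trials must be positive" = cfg$trials >= 1
  )
  invisible(cfg)
}

#' @export
print.pudti_config <- function(x, ...) {
  cat("pudti pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(val)) "<auto>" else format(val)))
  }
  invisible(x)
}
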