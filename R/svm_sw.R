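#' Radial basis function kernel
#'
#' @param x,y Numeric matrices (rows = samples); `y = NULL` means `x`
#'   against itself.
#' @param gamma Kernel width.
#' @return Kernel matrix `exp(-gamma * ||x_i - y_j||^2)`.
#' @export
rbf_kernel <- function(x, y = NULL, gamma) {
  x <- as.matrix(x)
  y <- if (is.null(y)) x else as.matrix(y)
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Build the augmented training set of the similarity-weighted SVM
#'
#' Maps the weighted-slack objective onto a per-sample-penalty soft-margin
#' SVM: positives enter once with penalty `C1`, reliable negatives once
#' with penalty `C4`, and every ambiguous sample twice -- once on the
#' positive side with penalty `C2 * W^P(x)` and once on the negative side
#' with penalty `C3 * W^N(x)`. Rows whose penalty falls below 1e-12 are
#' dropped: their slack is unpenalized, so the constraint is vacuous.
#'
#' @param x Feature matrix.
#' @param split A `sample_split` (uses `P_aug`, `RN`, `A`).
#' @param weights Data frame from [compute_similarity_weights()]; must
#'   cover every ambiguous row.
#' @param C1,C2,C3,C4 Penalty factors.
#' @return List: `rows` (row index into `x` per augmented row), `y`
#'   (+1/-1), `c` (per-row penalty).
#' @export
build_augmented_set <- function(x, split, weights,
                                C1 = 1, C2 = 1, C3 = 1, C4 = 1) {
  stopifnot(C1 > 0, C2 > 0, C3 > 0, C4 > 0)
  A <- split$A
  if (length(A) > 0L) {
    miss <- setdiff(A, weights$row)
    if (length(miss) > 0L) {
      stop("missing similarity weights for ", length(miss),
           " ambiguous sample(s)")
    }
    wp <- weights$WP[match(A, weights$row)]
    wn <- weights$WN[match(A, weights$row)]
  } else {
    wp <- wn <- numeric()
  }
  rows <- c(split$P_aug, split$RN, A, A)
  y <- c(rep(1L, length(split$P_aug)), rep(-1L, length(split$RN)),
         rep(1L, length(A)), rep(-1L, length(A)))
  cc <- c(rep(C1, length(split$P_aug)), rep(C4, length(split$RN)),
          C2 * wp, C3 * wn)
  keep <- cc >= 1e-12
  list(rows = rows[keep], y = y[keep], c = cc[keep])
}

#' Train a soft-margin SVM with per-sample slack penalties
#'
#' Solves the dual
#' `min 1/2 a' Q a - e' a  s.t.  y' a = 0, 0 <= a_i <= c_i`
#' (`Q_ij = y_i y_j K(x_i, x_j)`) by sequential minimal optimization with
#' second-order working-set selection, the standard solver family for this
#' problem class. With all `c_i` equal this is the ordinary C-SVM dual.
#'
#' @param x Training matrix (augmented rows).
#' @param y Labels, +1/-1, both classes present.
#' @param c Per-sample penalties (upper box bounds), positive.
#' @param gamma RBF width; default `1 / ncol(x)`.
#' @param tol Stopping tolerance on the maximal KKT violation.
#' @param max_iter Iteration cap.
#' @return Object of class `svm_sw`: support vectors, `coef`
#'   (`alpha_i * y_i`), `b`, `gamma`, `objective` (dual), `alpha`,
#'   `kkt_violation`.
#' @export
svm_sw_train <- function(x, y, c, gamma = NULL, tol = 1e-6,
                         max_iter = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, length(c) == n, all(c > 0),
            all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("training set has a single class")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (is.null(max_iter)) max_iter <- max(1e5L, 100L * n)
  K <- rbf_kernel(x, gamma = gamma)
  Q <- (y %o% y) * K
  alpha <- numeric(n)
  G <- rep(-1, n)  # gradient of 1/2 a'Qa - e'a at a = 0
  tau <- 1e-12
  viol <- Inf
  for (iter in seq_len(max_iter)) {
    yG <- -y * G
    up <- (y == 1 & alpha < c) | (y == -1 & alpha > 0)
    low <- (y == -1 & alpha < c) | (y == 1 & alpha > 0)
    if (!any(up) || !any(low)) break
    m_up <- max(yG[up])
    M_low <- min(yG[low])
    viol <- m_up - M_low
    if (viol < tol) break
    i <- which(up)[which.max(yG[up])]
    # second-order choice of j among violating candidates
    cand <- which(low & yG < m_up - tau)
    if (length(cand) == 0L) break
    bij <- m_up - yG[cand]
    aij <- pmax(K[i, i] + diag(K)[cand] - 2 * K[i, cand], tau)
    j <- cand[which.min(-bij^2 / aij)]

    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (y[i] != y[j]) {
      quad <- max(Q[i, i] + Q[j, j] + 2 * Q[i, j], tau)
      delta <- (-G[i] - G[j]) / quad
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > c[i] - c[j]) {
        if (alpha[i] > c[i]) { alpha[i] <- c[i]; alpha[j] <- c[i] - diff }
      } else {
        if (alpha[j] > c[j]) { alpha[j] <- c[j]; alpha[i] <- c[j] + diff }
      }
    } else {
      quad <- max(Q[i, i] + Q[j, j] - 2 * Q[i, j], tau)
      delta <- (G[i] - G[j]) / quad
      ssum <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (ssum > c[i]) {
        if (alpha[i] > c[i]) { alpha[i] <- c[i]; alpha[j] <- ssum - c[i] }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- ssum }
      }
      if (ssum > c[j]) {
        if (alpha[j] > c[j]) { alpha[j] <- c[j]; alpha[i] <- ssum - c[j] }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- ssum }
      }
    }
    G <- G + Q[, i] * (alpha[i] - ai_old) + Q[, j] * (alpha[j] - aj_old)
    if (iter == max_iter) {
      stop("SVM solver did not converge: KKT violation ",
           format(viol, digits = 4), " after ", max_iter, " iterations")
    }
  }
  # bias from free support vectors; fallback to the violation midpoint
  free <- alpha > 1e-8 & alpha < c - 1e-8
  b <- if (any(free)) {
    mean((-y * G)[free])
  } else {
    yG <- -y * G
    up <- (y == 1 & alpha < c) | (y == -1 & alpha > 0)
    low <- (y == -1 & alpha < c) | (y == 1 & alpha > 0)
    (max(yG[up]) + min(yG[low])) / 2
  }
  objective <- 0.5 * sum(alpha * (G - 1))  # = 1/2 a'Qa - e'a
  sv <- alpha > 1e-12
  model <- list(sv = x[sv, , drop = FALSE], coef = (alpha * y)[sv],
                b = b, gamma = gamma, objective = objective,
                alpha = alpha, y = y, c = c, kkt_violation = viol)
  class(model) <- "svm_sw"
  model
}

#' @export
print.svm_sw <- function(x, ...) {
  cat(sprintf(
    "similarity-weighted SVM: %d support vectors, gamma = %.4g, b = %.4g\n",
    nrow(x$sv), x$gamma, x$b))
  invisible(x)
}

#' Decision scores and labels of a similarity-weighted SVM
#'
#' Score `s(x) = sum_r coef_r K(x_r, x) + b`; the predicted label is +1
#' only when the score is strictly positive, so a sample exactly on the
#' hyperplane is called negative.
#'
#' @param object A fitted `svm_sw` model.
#' @param newdata Numeric matrix of samples to score.
#' @param ... Unused.
#' @return Data frame with `score` and `label` (+1/-1).
#' @export
predict.svm_sw <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- rbf_kernel(newdata, object$sv, gamma = object$gamma)
  score <- as.vector(K %*% object$coef) + object$b
  data.frame(score = score, label = ifelse(score > 0, 1L, -1L))
}

#' Fit the similarity-weighted SVM from a sample split
#'
#' @param x Feature matrix (selected-feature space).
#' @param split A `sample_split`.
#' @param weights Output of [compute_similarity_weights()].
#' @param config A [pudti_config()] providing `C1..C4`, `rbf_gamma`,
#'   `svm_tol`.
#' @return A fitted `svm_sw` model.
#' @export
svm_sw_fit <- function(x, split, weights, config = pudti_config()) {
  aug <- build_augmented_set(x, split, weights, C1 = config$C1,
                             C2 = config$C2, C3 = config$C3,
                             C4 = config$C4)
  svm_sw_train(x[aug$rows, , drop = FALSE], aug$y, aug$c,
               gamma = config$rbf_gamma, tol = config$svm_tol)
}

#' Grid search over penalties and kernel width
#'
#' Exhaustive search maximizing mean cross-validated AUC on the labeled
#' rows (positives vs reliable negatives); ambiguous rows and their
#' weighted duplicates stay in every training fold. Ties prefer the
#' smallest penalties, then the smallest `gamma` (grid rows are visited in
#' ascending lexicographic order and only a strictly better AUC replaces
#' the incumbent).
#'
#' @param x Feature matrix.
#' @param split A `sample_split`.
#' @param weights Output of [compute_similarity_weights()].
#' @param C_grid Numeric vector of candidate values used for each of
#'   `C1..C4` (the four penalties move together unless `expand = TRUE`).
#' @param gamma_grid Candidate RBF widths.
#' @param folds Number of CV folds on the labeled rows.
#' @param config Base configuration.
#' @param expand If `TRUE`, search the full `C1 x C2 x C3 x C4` product
#'   (use short grids).
#' @return List: `best` (named parameters), `auc`, `table` of all
#'   candidates.
#' @export
svm_sw_grid_search <- function(x, split, weights,
                               C_grid = 2^seq(-5, 5, by = 2),
                               gamma_grid = NULL, folds = 3,
                               config = pudti_config(), expand = FALSE) {
  stopifnot(length(C_grid) > 0L)
  if (is.null(gamma_grid)) gamma_grid <- 1 / ncol(x)
  grid <- if (expand) {
    expand.grid(C1 = C_grid, C2 = C_grid, C3 = C_grid, C4 = C_grid,
                gamma = gamma_grid)
  } else {
    expand.grid(C = C_grid, gamma = gamma_grid)
  }
  if (!expand) {
    grid <- data.frame(C1 = grid$C, C2 = grid$C, C3 = grid$C,
                       C4 = grid$C, gamma = grid$gamma)
  }
  grid <- grid[order(grid$C1, grid$C2, grid$C3, grid$C4, grid$gamma), ,
               drop = FALSE]
  lab_rows <- c(split$P_aug, split$RN)
  lab_y <- c(rep(1L, length(split$P_aug)), rep(-1L, length(split$RN)))
  fold_id <- make_folds(length(lab_rows), folds, strata = lab_y)
  best <- NULL
  best_auc <- -Inf
  aucs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$C1 <- grid$C1[g]; cfg$C2 <- grid$C2[g]
    cfg$C3 <- grid$C3[g]; cfg$C4 <- grid$C4[g]
    cfg$rbf_gamma <- grid$gamma[g]
    fold_auc <- vapply(seq_len(folds), function(f) {
      test <- fold_id == f
      sub <- split
      sub$P_aug <- lab_rows[!test & lab_y == 1L]
      sub$RN <- lab_rows[!test & lab_y == -1L]
      if (length(sub$P_aug) == 0L || length(sub$RN) == 0L) return(NA_real_)
      fit <- svm_sw_fit(x, sub, weights, cfg)
      sc <- predict(fit, x[lab_rows[test], , drop = FALSE])$score
      yy <- lab_y[test]
      if (length(unique(yy)) < 2L) return(NA_real_)
      auc_score(sc, yy == 1L)
    }, 0)
    aucs[g] <- mean(fold_auc, na.rm = TRUE)
    if (isTRUE(aucs[g] > best_auc)) {
      best_auc <- aucs[g]
      best <- grid[g, , drop = FALSE]
    }
  }
  list(best = as.list(best), auc = best_auc,
       table = cbind(grid, auc = aucs))
}
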