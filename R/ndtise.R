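#' Spy-based positive-unlabeled classifier
#'
#' Classic spy technique adapted to continuous descriptors: a random
#' fraction of the positives ("spies") is moved into the unlabeled pool, a
#' Gaussian naive Bayes model is fitted with the remaining positives as
#' class +1 and the augmented unlabeled pool as class -1, and EM
#' re-estimates the unlabeled side's class responsibilities. The decision
#' threshold is the `noise_percentile` quantile of the spies' positive
#' posteriors, so that (100 - noise_percentile)% of known positives hidden
#' in U would be retained.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param p_rows,u_rows Row indices of positives and unlabeled samples.
#' @param spy_ratio Fraction of positives used as spies (0 < ratio < 1).
#' @param noise_percentile Spy-posterior percentile for the threshold.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   unlabeled responsibilities.
#' @return List with `labels` (+1/-1 per element of `u_rows`), `posterior`
#'   (P(+1 | x) per element of `u_rows`), `threshold`, `converged`.
#' @export
spy_classify <- function(x, p_rows, u_rows, spy_ratio = 0.15,
                         noise_percentile = 5, max_iter = 50L,
                         tol = 1e-4) {
  nP <- length(p_rows)
  if (nP < 10L) stop("too few positives to spy: |P| = ", nP, " < 10")
  n_spy <- ceiling(spy_ratio * nP)
  if (n_spy >= nP) stop("spy_ratio leaves no positives: ", n_spy,
                        " spies from ", nP, " positives")
  spies <- sample(p_rows, n_spy)
  pos <- setdiff(p_rows, spies)
  unl <- c(u_rows, spies)            # augmented unlabeled pool
  xp <- x[pos, , drop = FALSE]
  xu <- x[unl, , drop = FALSE]

  # responsibilities r = P(class +1 | x) for the unlabeled side;
  # the retained positives stay fixed at 1.
  r <- rep(0, nrow(xu))
  wp_fixed <- nrow(xp)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M-step: weighted Gaussian parameters per class
    w_pos <- wp_fixed + sum(r)
    w_neg <- sum(1 - r)
    mu_pos <- (colSums(xp) + colSums(xu * r)) / w_pos
    var_pos <- (colSums(sweep(xp, 2L, mu_pos)^2) +
                colSums(sweep(xu, 2L, mu_pos)^2 * r)) / w_pos
    if (w_neg <= .Machine$double.eps) {
      mu_neg <- colMeans(xu)
      var_neg <- apply(xu, 2L, stats::var)
    } else {
      mu_neg <- colSums(xu * (1 - r)) / w_neg
      var_neg <- colSums(sweep(xu, 2L, mu_neg)^2 * (1 - r)) / w_neg
    }
    floor_var <- 1e-6
    var_pos <- pmax(var_pos, floor_var)
    var_neg <- pmax(var_neg, floor_var)
    prior_pos <- w_pos / (w_pos + w_neg)

    # E-step on the unlabeled side; keep log-odds to avoid underflow
    llp <- gnb_loglik(xu, mu_pos, var_pos) + log(prior_pos)
    lln <- gnb_loglik(xu, mu_neg, var_neg) + log1p(-prior_pos)
    lo <- llp - lln
    r_new <- stats::plogis(lo)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("spy EM did not converge within ", max_iter,
            " iterations; using last iterate")
  }
  # threshold on the log-odds scale: monotone in the posterior but immune
  # to posteriors underflowing to exactly 0
  spy_lo <- lo[match(spies, unl)]
  th_lo <- stats::quantile(spy_lo, noise_percentile / 100, names = FALSE)
  u_lo <- lo[match(u_rows, unl)]
  labels <- ifelse(u_lo < th_lo, -1L, 1L)
  list(labels = labels, posterior = stats::plogis(u_lo),
       threshold = stats::plogis(th_lo), logodds = u_lo,
       spy_logodds = spy_lo, converged = converged)
}

gnb_loglik <- function(x, mu, v) {
  # sum over features of log N(x | mu, v), diagonal covariance
  z <- sweep(sweep(x, 2L, mu), 2L, sqrt(v), "/")
  -0.5 * rowSums(z^2) - 0.5 * sum(log(2 * pi * v))
}

#' Rocchio prototype classifier for positive-unlabeled data
#'
#' Builds a positive prototype `c+ = alpha * mean(P / |P|) - beta *
#' mean(U / |U|)` over length-normalized samples and the mirrored negative
#' prototype `c-`, then labels each unlabeled sample by its closer
#' prototype under cosine similarity.
#'
#' @param x Numeric feature matrix.
#' @param p_rows,u_rows Row indices of positives and unlabeled samples.
#' @param alpha,beta Own-class and opposing-class centroid weights.
#' @return List with `labels` (+1/-1 per element of `u_rows`),
#'   `proto_pos`, `proto_neg`.
#' @export
rocchio_classify <- function(x, p_rows, u_rows, alpha = 16, beta = 4) {
  stopifnot(length(p_rows) > 0L, length(u_rows) > 0L)
  mean_p <- colMeans(unit_rows(x[p_rows, , drop = FALSE]))
  mean_u <- colMeans(unit_rows(x[u_rows, , drop = FALSE]))
  cpos <- alpha * mean_p - beta * mean_u
  cneg <- alpha * mean_u - beta * mean_p
  xu <- x[u_rows, , drop = FALSE]
  sp <- apply(xu, 1L, cosine_sim, y = cpos)
  sn <- apply(xu, 1L, cosine_sim, y = cneg)
  labels <- ifelse(sp > sn, 1L, -1L)
  list(labels = labels, proto_pos = cpos, proto_neg = cneg)
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1  # zero-norm rows carry no direction; leave as zero
  m / nrm
}

#' Reliable-negative extraction by spy/Rocchio consensus
#'
#' Partitions the unlabeled pool into reliable negatives `RN`, extracted
#' positives `EP` and ambiguous samples `A`. A sample is a reliable
#' negative when both classifiers reject it: its spy log-odds falls below
#' the `spy_noise_percentile` quantile of the spies and the Rocchio vote
#' is -1. An extracted positive must clear the mirrored high bar -- spy
#' log-odds above the `100 - spy_noise_percentile` quantile of the spies
#' (i.e. it looks more positive than nearly all genuine positives planted
#' as spies) with a +1 Rocchio vote -- because unlabeled pools are
#' dominated by negatives and a merely "not negative" consensus would
#' flood the positive class. `EP` is merged into the positive set for all
#' downstream stages.
#'
#' @param x Numeric feature matrix (samples x features), typically after
#'   feature selection.
#' @param p_rows,u_rows Row indices of positives and unlabeled samples.
#' @param config A [pudti_config()]; spy and Rocchio parameters are read
#'   from it.
#' @return List of class `sample_split` with integer row-index vectors
#'   `P` (original positives), `EP`, `RN`, `A`, `P_aug` (`P` plus `EP`),
#'   and the per-sample votes `c_spy`, `c_roc` (aligned with `u_rows`).
#' @export
ndtise <- function(x, p_rows, u_rows, config = pudti_config()) {
  stopifnot(length(p_rows) > 0L, length(u_rows) > 0L,
            length(intersect(p_rows, u_rows)) == 0L)
  spy <- spy_classify(x, p_rows, u_rows,
                      spy_ratio = config$spy_ratio,
                      noise_percentile = config$spy_noise_percentile,
                      max_iter = config$em_max_iter, tol = config$em_tol)
  roc <- rocchio_classify(x, p_rows, u_rows,
                          alpha = config$rocchio_alpha,
                          beta = config$rocchio_beta)
  ep_th <- max(spy$spy_logodds)
  both_neg <- spy$labels == -1L & roc$labels == -1L
  both_pos <- spy$logodds > ep_th & roc$labels == 1L
  RN <- u_rows[both_neg]
  EP <- u_rows[both_pos]
  A <- u_rows[!(both_neg | both_pos)]
  if (length(RN) == 0L) {
    stop("no reliable negatives extracted; relax spy_noise_percentile ",
         "or Rocchio weights")
  }
  stopifnot(length(RN) + length(EP) + length(A) == length(u_rows))
  out <- list(P = p_rows, EP = EP, RN = RN, A = A,
              P_aug = c(p_rows, EP),
              c_spy = spy$labels, c_roc = roc$labels)
  class(out) <- "sample_split"
  out
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf(
    "sample_split: |P| = %d, |EP| = %d, |RN| = %d, |A| = %d\n",
    length(x$P), length(x$EP), length(x$RN), length(x$A)))
  invisible(x)
}
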