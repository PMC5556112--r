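#' Feature-presence binarization thresholds
#'
#' The discriminant filter scores a feature by counting in how many samples
#' it is "present". Binary features (domain indicators) are used as-is; for
#' continuous descriptors presence is defined by a policy fixed once on the
#' pooled P and U samples: strictly above the column median (`"median"`,
#' default) or nonzero (`"nonzero"`).
#'
#' @param x Numeric matrix (samples x features), pooled P and U.
#' @param policy `"median"` or `"nonzero"`.
#' @return Numeric vector of per-feature thresholds; presence means value
#'   strictly greater than the threshold. (Zero for the nonzero policy and
#'   for 0/1 columns; absolute value is compared under `"nonzero"`.)
#' @export
binarize_thresholds <- function(x, policy = c("median", "nonzero")) {
  policy <- match.arg(policy)
  th <- switch(policy,
    median = apply(x, 2L, stats::median),
    nonzero = rep(0, ncol(x)))
  is01 <- apply(x, 2L, function(col) all(col %in% c(0, 1)))
  th[is01] <- 0  # binary columns: present iff 1
  names(th) <- colnames(x)
  attr(th, "policy") <- policy
  th
}

#' Feature presence indicator
#'
#' @param x Numeric matrix or vector of feature values.
#' @param thresholds Output of [binarize_thresholds()].
#' @return Integer 0/1 matrix of the same shape.
#' @export
associate <- function(x, thresholds) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  policy <- attr(thresholds, "policy")
  v <- if (identical(policy, "nonzero")) abs(x) else x
  m <- sweep(v, 2L, as.numeric(thresholds), ">") * 1L
  storage.mode(m) <- "integer"
  m
}

#' Per-set association score
#'
#' Number of samples in a set in which a feature is present.
#'
#' @param assoc 0/1 presence matrix (samples x features).
#' @param rows Row indices of the set.
#' @return Integer vector of per-feature counts.
#' @export
association_score <- function(assoc, rows) {
  if (length(rows) == 0L) stop("association_score: empty sample set")
  colSums(assoc[rows, , drop = FALSE])
}

#' Discriminant-ability score
#'
#' `da(f) = (as_P + as_U) * log(|P|/as_P + |U|/as_U)` with natural log.
#' A zero count is replaced by 0.5 inside its ratio only (continuity
#' correction), so the score stays finite; features present everywhere in
#' both sets score the floor `(|P|+|U|) * log 2`.
#'
#' @param as_P,as_U Per-feature presence counts in P and U.
#' @param nP,nU Set sizes.
#' @return Numeric vector of scores.
#' @export
discriminant_score <- function(as_P, as_U, nP, nU) {
  stopifnot(all(as_P >= 0), all(as_P <= nP), all(as_U >= 0), all(as_U <= nU))
  rP <- nP / ifelse(as_P == 0, 0.5, as_P)
  rU <- nU / ifelse(as_U == 0, 0.5, as_U)
  (as_P + as_U) * log(rP + rU)
}

#' Top-k features by discriminant ability
#'
#' @param scores Numeric score vector.
#' @param k Number of features to keep (`k <= length(scores)`).
#' @return Integer vector of the k highest-scoring feature indices,
#'   descending score, ties broken by ascending index.
#' @export
select_top_k <- function(scores, k = 300L) {
  if (k <= 0L) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds number of features")
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(k)]
}

#' Discriminant feature selection between P and U
#'
#' Runs the full filter: fix the presence policy on the pooled samples,
#' count per-set presences, score every feature and keep the top k.
#'
#' @param x Feature matrix (samples x features).
#' @param p_rows,u_rows Row indices of the positive and unlabeled sets.
#' @param k Number of features to keep; capped at `ncol(x)`.
#' @param policy Binarization policy, see [binarize_thresholds()].
#' @return List with `selected` (indices), `scores`, `thresholds`.
#' @export
select_features <- function(x, p_rows, u_rows, k = 300L,
                            policy = c("median", "nonzero")) {
  policy <- match.arg(policy)
  k <- min(k, ncol(x))
  th <- binarize_thresholds(x[c(p_rows, u_rows), , drop = FALSE], policy)
  assoc <- associate(x, th)
  as_P <- association_score(assoc, p_rows)
  as_U <- association_score(assoc, u_rows)
  scores <- discriminant_score(as_P, as_U, length(p_rows), length(u_rows))
  list(selected = select_top_k(scores, k), scores = scores,
       thresholds = th)
}
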