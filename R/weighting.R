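#' Cosine similarity
#'
#' Standard cosine; a zero-norm vector has no direction and yields 0
#' against anything.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# k-means with k-means++ seeding and restarts; returns stats::kmeans fit.
# Lloyd iterations on top of the seeded centers; best of n_start by total
# within-cluster sum of squares. Caps k at the number of distinct rows.
kmeans_pp <- function(x, k, n_start = 10L, iter_max = 100L) {
  x <- as.matrix(x)
  ux <- unique(x)
  k <- max(1L, min(k, nrow(ux)))
  if (k == 1L) {
    center <- matrix(colMeans(x), 1L)
    return(list(cluster = rep(1L, nrow(x)), centers = center, k = 1L))
  }
  best <- NULL
  for (s in seq_len(n_start)) {
    centers <- ux[kmeanspp_seed(ux, k), , drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  list(cluster = best$cluster, centers = best$centers, k = k)
}

kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = prob)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ])^2))
  }
  idx
}

#' Representative positive and negative prototypes
#'
#' Clusters the reliable negatives into `a = round(t * |RN| / (|A| + |RN|))`
#' modules by k-means and builds one Rocchio prototype pair per module:
#' `n_i = alpha * mean(N_i / |N_i|) - beta * mean(P / |P|)` and the mirrored
#' `p_i`, over length-normalized samples. `A` is the ambiguous remainder of
#' the unlabeled pool, so the reliable-negative and ambiguous partitions
#' together spend about `t` clusters.
#'
#' @param x Feature matrix.
#' @param p_rows Positive rows (typically P plus extracted positives).
#' @param rn_rows Reliable-negative rows.
#' @param a_size Number of ambiguous samples (sets the cluster split).
#' @param t Total cluster budget.
#' @param alpha,beta Rocchio centroid weights.
#' @return List of class `prototype_set`: `pos` and `neg` (a x d matrices,
#'   one prototype per row), `a` (cluster count), `rn_cluster` (cluster id
#'   per element of `rn_rows`).
#' @export
compute_prototypes <- function(x, p_rows, rn_rows, a_size, t = 30,
                               alpha = 16, beta = 4) {
  stopifnot(length(p_rows) > 0L, length(rn_rows) > 0L)
  a <- round(t * length(rn_rows) / (a_size + length(rn_rows)))
  if (a < 1L) {
    warning("prototype cluster count rounded to 0; using 1")
    a <- 1L
  }
  km <- kmeans_pp(x[rn_rows, , drop = FALSE], a)
  a <- km$k
  mean_p <- colMeans(unit_rows(x[p_rows, , drop = FALSE]))
  pos <- matrix(0, a, ncol(x))
  neg <- matrix(0, a, ncol(x))
  for (i in seq_len(a)) {
    rows <- rn_rows[km$cluster == i]
    mean_n <- colMeans(unit_rows(x[rows, , drop = FALSE]))
    neg[i, ] <- alpha * mean_n - beta * mean_p
    pos[i, ] <- alpha * mean_p - beta * mean_n
  }
  out <- list(pos = pos, neg = neg, a = a, rn_cluster = km$cluster)
  class(out) <- "prototype_set"
  out
}

#' Local similarity weights of ambiguous samples
#'
#' Clusters the ambiguous set into `n = round(t * |A| / (|A| + |RN|))`
#' micro-clusters, temporarily tags every sample by which side of the
#' Rocchio decision hyperplane it falls on (cosine to the positive versus
#' the negative class prototype; ties tag negative), and assigns every
#' member of a cluster the cluster's tag fractions:
#' `LocP = |tempos| / |US|`, `LocN = 1 - LocP`.
#'
#' With `tag_rule = "prototype"` the tag instead compares the best cosine
#' over the per-cluster positive prototypes against the best over the
#' negative ones. The hyperplane rule is the default: the max over
#' near-duplicate positive prototypes is optimistically biased, which
#' inflates positive tags on predominantly negative ambiguous sets.
#'
#' @param x Feature matrix.
#' @param a_rows Ambiguous rows.
#' @param prototypes A `prototype_set`.
#' @param t Cluster budget.
#' @param rn_size Number of reliable negatives (sets the cluster split).
#' @param n_clusters Optional explicit cluster count overriding the
#'   formula.
#' @param hyperplane Optional list with `cpos`, `cneg` class prototype
#'   vectors defining the tagging hyperplane; defaults to the mean of the
#'   per-cluster prototypes.
#' @param tag_rule `"hyperplane"` (default) or `"prototype"`.
#' @return List: `LocP`, `LocN` (per element of `a_rows`), `cluster`
#'   (cluster id per sample), `tag` (+1/-1 temporary tag), `n` clusters.
#' @export
local_weights <- function(x, a_rows, prototypes, t = 30, rn_size,
                          n_clusters = NULL, hyperplane = NULL,
                          tag_rule = c("hyperplane", "prototype")) {
  tag_rule <- match.arg(tag_rule)
  stopifnot(length(a_rows) > 0L)
  n <- if (!is.null(n_clusters)) n_clusters else {
    round(t * length(a_rows) / (length(a_rows) + rn_size))
  }
  if (n < 1L) {
    warning("ambiguous cluster count rounded to 0; using 1")
    n <- 1L
  }
  km <- kmeans_pp(x[a_rows, , drop = FALSE], n)
  n <- km$k
  xa <- x[a_rows, , drop = FALSE]
  if (tag_rule == "hyperplane") {
    if (is.null(hyperplane)) {
      hyperplane <- list(cpos = colMeans(prototypes$pos),
                         cneg = colMeans(prototypes$neg))
    }
    sp <- apply(xa, 1L, cosine_sim, y = hyperplane$cpos)
    sn <- apply(xa, 1L, cosine_sim, y = hyperplane$cneg)
    tag <- ifelse(sp > sn, 1L, -1L)
  } else {
    sim_p <- proto_sims(xa, prototypes$pos)
    sim_n <- proto_sims(xa, prototypes$neg)
    tag <- ifelse(apply(sim_p, 1L, max) > apply(sim_n, 1L, max), 1L, -1L)
  }
  LocP <- numeric(length(a_rows))
  for (i in seq_len(n)) {
    members <- km$cluster == i
    LocP[members] <- sum(tag[members] == 1L) / sum(members)
  }
  list(LocP = LocP, LocN = 1 - LocP, cluster = km$cluster, tag = tag,
       n = n)
}

proto_sims <- function(xa, protos) {
  # rows: samples, cols: prototypes
  out <- vapply(seq_len(nrow(protos)),
                function(i) apply(xa, 1L, cosine_sim, y = protos[i, ]),
                numeric(nrow(xa)))
  matrix(out, nrow = nrow(xa))
}

#' Global similarity weights of ambiguous samples
#'
#' `GloP(x) = sum_i sim(x, p_i) / sum_i (sim(x, p_i) + sim(x, n_i))` and
#' the complementary `GloN`. Cosines are clamped at 0 first so both
#' weights stay in \[0, 1\]; if every similarity is 0 the sample is
#' uninformative and gets (0.5, 0.5) with a warning.
#'
#' @param x Feature matrix.
#' @param a_rows Ambiguous rows.
#' @param prototypes A `prototype_set`.
#' @return List: `GloP`, `GloN` per element of `a_rows`.
#' @export
global_weights <- function(x, a_rows, prototypes) {
  xa <- x[a_rows, , drop = FALSE]
  sp <- rowSums(pmax(proto_sims(xa, prototypes$pos), 0))
  sn <- rowSums(pmax(proto_sims(xa, prototypes$neg), 0))
  denom <- sp + sn
  flat <- denom <= 0
  if (any(flat)) {
    warning(sum(flat), " ambiguous sample(s) with no positive similarity ",
            "to any prototype; assigning (0.5, 0.5)")
    sp[flat] <- 0.5
    denom[flat] <- 1
  }
  GloP <- sp / denom
  list(GloP = GloP, GloN = 1 - GloP)
}

#' Combine local and global weights
#'
#' Convex combination `W^P = (1 - alpha) * LocP + alpha * GloP` (and
#' likewise for the negative side), `alpha` balancing global against local
#' similarity.
#'
#' @param LocP,LocN,GloP,GloN Weight vectors in \[0, 1\], pairs summing
#'   to 1.
#' @param alpha Balance parameter in \[0, 1\].
#' @return List: `WP`, `WN`.
#' @export
combine_weights <- function(LocP, LocN, GloP, GloN, alpha = 0.6) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot(all(abs(LocP + LocN - 1) < 1e-9),
            all(abs(GloP + GloN - 1) < 1e-9))
  WP <- (1 - alpha) * LocP + alpha * GloP
  list(WP = WP, WN = 1 - WP)
}

#' Similarity weights for all ambiguous samples
#'
#' Full weighting stage: prototypes from the reliable negatives, local
#' micro-cluster weights, global prototype weights, and their convex
#' combination.
#'
#' @param x Feature matrix.
#' @param split A `sample_split` from [ndtise()].
#' @param config A [pudti_config()].
#' @return Data frame with one row per ambiguous sample: `row` (row index
#'   in `x`), `LocP`, `LocN`, `GloP`, `GloN`, `WP`, `WN`; the
#'   `prototype_set` is attached as attribute `prototypes`.
#' @export
compute_similarity_weights <- function(x, split, config = pudti_config()) {
  protos <- compute_prototypes(x, split$P_aug, split$RN,
                               a_size = length(split$A), t = config$t,
                               alpha = config$rocchio_alpha,
                               beta = config$rocchio_beta)
  if (length(split$A) == 0L) {
    out <- data.frame(row = integer(), LocP = numeric(), LocN = numeric(),
                      GloP = numeric(), GloN = numeric(),
                      WP = numeric(), WN = numeric())
    attr(out, "prototypes") <- protos
    return(out)
  }
  # tagging hyperplane: Rocchio class prototypes of the current positive
  # and reliable-negative sets
  mean_p <- colMeans(unit_rows(x[split$P_aug, , drop = FALSE]))
  mean_n <- colMeans(unit_rows(x[split$RN, , drop = FALSE]))
  hp <- list(cpos = config$rocchio_alpha * mean_p -
               config$rocchio_beta * mean_n,
             cneg = config$rocchio_alpha * mean_n -
               config$rocchio_beta * mean_p)
  loc <- local_weights(x, split$A, protos, t = config$t,
                       rn_size = length(split$RN), hyperplane = hp)
  glo <- global_weights(x, split$A, protos)
  w <- combine_weights(loc$LocP, loc$LocN, glo$GloP, glo$GloN,
                       alpha = config$balance_alpha)
  out <- data.frame(row = split$A, LocP = loc$LocP, LocN = loc$LocN,
                    GloP = glo$GloP, GloN = glo$GloN,
                    WP = w$WP, WN = w$WN)
  attr(out, "prototypes") <- protos
  out
}
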