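#' Synthetic drug-target dataset specification
#'
#' Describes a seeded generator that emulates the structure positive-
#' unlabeled DTI screening faces: interactions are rare, only a fraction
#' of true interactions are recorded, and the unlabeled pool hides the
#' rest; features mix binary (domain-like) and continuous (descriptor-
#' like) coordinates of which only a subset carries class signal.
#'
#' @param n_drugs,n_targets Numbers of drugs and targets; every pair is a
#'   sample.
#' @param n_features Total feature count.
#' @param n_informative Number of class-informative coordinates.
#' @param positive_rate Fraction of pairs that truly interact.
#' @param label_rate Fraction of true interactions revealed as known.
#' @param effect_size Mean shift (continuous) / log-odds shift (binary) of
#'   informative features for true interactions.
#' @param noise_sd Standard deviation of pair-level measurement noise on
#'   continuous coordinates.
#' @param binary_fraction Share of features drawn as Bernoulli.
#' @param affinity If `TRUE` (default), true interactions are the pairs
#'   with the highest latent drug-target affinity, concentrating
#'   interactions on promiscuous drugs and hub targets as real interactomes
#'   do. If `FALSE`, true interactions are drawn uniformly over pairs --
#'   the clean null for experiments that must rule out entity-identity
#'   memorization.
#' @param seed Generator seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200L, n_targets = 50L,
                           n_features = 60L, n_informative = 15L,
                           positive_rate = 0.03, label_rate = 0.3,
                           effect_size = 1.0, noise_sd = 1.0,
                           binary_fraction = 0.3, affinity = TRUE,
                           seed = 11L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_targets = as.integer(n_targets),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               positive_rate = positive_rate, label_rate = label_rate,
               effect_size = effect_size, noise_sd = noise_sd,
               binary_fraction = binary_fraction,
               affinity = isTRUE(affinity), seed = as.integer(seed))
  stopifnot(
    "positive_rate must be in (0, 1)" =
      spec$positive_rate > 0 && spec$positive_rate < 1,
    "label_rate must be in (0, 1]" =
      spec$label_rate > 0 && spec$label_rate <= 1,
    "n_informative must not exceed n_features" =
      spec$n_informative <= spec$n_features,
    "binary_fraction must be in [0, 1]" =
      spec$binary_fraction >= 0 && spec$binary_fraction <= 1,
    spec$n_drugs >= 2L, spec$n_targets >= 2L, spec$n_features >= 2L)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic drug-target dataset with known ground truth
#'
#' Drugs and targets carry latent affinity vectors; the pairs with the
#' highest logistic latent affinity are the true interactions, hit
#' exactly at `positive_rate`. Pair features concatenate per-drug and
#' per-target blocks; informative continuous coordinates are shifted by
#' `effect_size` for true interactions, informative binary coordinates are
#' redrawn pair-level with a log-odds shift of `effect_size`. Only
#' `label_rate` of the true interactions are revealed as known; the hidden
#' remainder is the planted challenge for reliable-negative extraction.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `pairs` (`pair_table` with the revealed labels), `x`
#'   (feature matrix, one row per pair), `truth` (logical, the full
#'   ground-truth interaction status), `known` (logical, revealed),
#'   `hidden_positives` (count), `spec`.
#' @export
generate_dti_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nd <- spec$n_drugs; nt <- spec$n_targets
  n <- nd * nt
  latent_dim <- 6L
  ld <- matrix(stats::rnorm(nd * latent_dim), nd)
  lt <- matrix(stats::rnorm(nt * latent_dim), nt)
  affinity <- stats::plogis(tcrossprod(ld, lt))   # nd x nt
  n_pos <- max(1L, round(spec$positive_rate * n))
  truth_mat <- matrix(FALSE, nd, nt)
  if (spec$affinity) {
    ord <- order(affinity, decreasing = TRUE)
    truth_mat[ord[seq_len(n_pos)]] <- TRUE
  } else {
    truth_mat[sample.int(n, n_pos)] <- TRUE
  }

  p <- spec$n_features
  n_bin <- round(spec$binary_fraction * p)
  is_bin <- c(rep(TRUE, n_bin), rep(FALSE, p - n_bin))
  # interleave so both drug and target blocks carry both kinds
  is_bin <- is_bin[order(seq_len(p) %% 2L, seq_len(p))]
  p_drug <- ceiling(p / 2)
  informative <- seq_len(spec$n_informative)

  # continuous coordinates mimic descriptor magnitudes: nonnegative-ish
  # values around a positive baseline, so directions (cosines) carry
  # information the way they do for real descriptor/domain vectors
  cont_baseline <- 2
  base_block <- function(nrows, cols) {
    m <- matrix(0, nrows, length(cols))
    for (j in seq_along(cols)) {
      m[, j] <- if (is_bin[cols[j]]) stats::rbinom(nrows, 1L, 0.3)
                else stats::rnorm(nrows, mean = cont_baseline)
    }
    m
  }
  drug_feat <- base_block(nd, seq_len(p_drug))
  targ_feat <- base_block(nt, (p_drug + 1L):p)

  di <- rep(seq_len(nd), times = nt)
  ti <- rep(seq_len(nt), each = nd)
  x <- cbind(drug_feat[di, , drop = FALSE], targ_feat[ti, , drop = FALSE])
  truth <- as.vector(truth_mat)

  cont <- which(!is_bin)
  x[, cont] <- x[, cont] +
    matrix(stats::rnorm(n * length(cont), sd = spec$noise_sd), n)
  inf_cont <- intersect(informative, cont)
  x[truth, inf_cont] <- x[truth, inf_cont] + spec$effect_size
  inf_bin <- intersect(informative, which(is_bin))
  if (length(inf_bin) > 0L) {
    p0 <- 0.3
    p1 <- stats::plogis(stats::qlogis(p0) + spec$effect_size)
    for (j in inf_bin) {
      x[, j] <- stats::rbinom(n, 1L, ifelse(truth, p1, p0))
    }
  }
  colnames(x) <- sprintf("f_%04d", seq_len(p))

  pos_idx <- which(truth)
  n_hidden <- floor((1 - spec$label_rate) * length(pos_idx))
  hidden <- if (n_hidden > 0L) sample(pos_idx, n_hidden) else integer()
  known <- truth
  known[hidden] <- FALSE

  drug_ids <- sprintf("D%04d", di)
  target_ids <- sprintf("T%04d", ti)
  pairs <- new_pair_table(
    drug_ids, target_ids,
    factor(ifelse(known, "positive", "unlabeled"),
           levels = c("positive", "unlabeled")))
  rownames(x) <- paste(drug_ids, target_ids, sep = "|")
  list(pairs = pairs, x = x, truth = truth, known = known,
       hidden_positives = n_hidden, spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Emits `pairs.tsv` (revealed labels), `features.csv` and `truth.tsv`
#' (ground truth, for scoring only) in the formats the pipeline reads.
#'
#' @param data Output of [generate_dti_data()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs(data$pairs, file.path(dir, "pairs.tsv"))
  write_feature_table(rownames(data$x), data$x,
                      file.path(dir, "features.csv"))
  utils::write.table(
    data.frame(pair_id = rownames(data$x),
               truth = as.integer(data$truth)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Worked micro-cluster weighting fixture
#'
#' A deterministic 2-D configuration of 34 ambiguous points in four well-
#' separated spatial clusters, with one positive prototype along (1, 0)
#' and one negative prototype along (0, 1). A point is tagged positive
#' exactly when its first coordinate exceeds its second, so the four
#' clusters carry 6/6, 5/12, 7/10 and 0/6 positive tags and the local
#' similarity weights are (1, 0), (5/12, 7/12), (7/10, 3/10) and (0, 1).
#' The reliable-negative size 221 and budget t = 30 make the ambiguous
#' cluster count come out at exactly 4.
#'
#' @return List: `points` (34 x 2), `prototypes` (`prototype_set` with
#'   a = 1), `cluster` (true cluster id per point), `expected` (data frame
#'   of expected LocP/LocN per cluster), `rn_size`, `t`.
#' @export
microcluster_fixture <- function() {
  jit <- function(k) (seq_len(k) - (k + 1) / 2) * 0.03
  m1 <- cbind(5 + jit(6), 0.5 + rev(jit(6)) * 0.5)          # all x > y
  m2_pos <- cbind(3.10 + jit(5) * 0.5, 2.90 + jit(5) * 0.5)  # x > y
  m2_neg <- cbind(2.90 + jit(7) * 0.5, 3.10 + jit(7) * 0.5)  # y > x
  m3_pos <- cbind(6.15 + jit(7) * 0.5, 5.85 + jit(7) * 0.5)
  m3_neg <- cbind(5.85 + jit(3) * 0.5, 6.15 + jit(3) * 0.5)
  m4 <- cbind(0.5 + rev(jit(6)) * 0.5, 5 + jit(6))           # all y > x
  points <- rbind(m1, m2_pos, m2_neg, m3_pos, m3_neg, m4)
  colnames(points) <- c("x1", "x2")
  cluster <- rep(1:4, times = c(6, 12, 10, 6))
  protos <- structure(
    list(pos = matrix(c(1, 0), 1L), neg = matrix(c(0, 1), 1L),
         a = 1L, rn_cluster = integer()),
    class = "prototype_set")
  expected <- data.frame(
    cluster = c("M1", "M2", "M3", "M4"),
    size = c(6L, 12L, 10L, 6L),
    LocP = c(1, 5 / 12, 7 / 10, 0),
    LocN = c(0, 7 / 12, 3 / 10, 1))
  list(points = points, prototypes = protos, cluster = cluster,
       expected = expected, rn_size = 221L, t = 30)
}
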