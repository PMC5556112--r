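#' Domain indicator vector
#'
#' Binary membership of a protein's domain annotations in a fixed,
#' ordered domain vocabulary (e.g. the human PFAM domain set).
#' Annotations outside the vocabulary are ignored with a warning.
#'
#' @param annotations Character vector of domain ids assigned to a protein.
#' @param vocabulary Ordered character vector of unique domain ids.
#' @return Integer 0/1 vector, one entry per vocabulary element.
#' @export
build_domain_vector <- function(annotations, vocabulary) {
  stopifnot(length(vocabulary) > 0L, !anyDuplicated(vocabulary))
  unknown <- setdiff(annotations, vocabulary)
  if (length(unknown) > 0L) {
    warning("domain annotation(s) outside vocabulary ignored: ",
            paste(unknown, collapse = ", "))
  }
  as.integer(vocabulary %in% annotations)
}

# Amino-acid property tables used by pseudo amino acid composition:
# hydrophobicity, hydrophilicity and side-chain mass for the 20 standard
# residues, in alphabetical one-letter order.
paac_properties <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
    H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
    P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
    W = 0.81, Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
    P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3)
  side_chain_mass <- c(
    A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0,
    H = 82.0, I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0,
    P = 42.0, Q = 72.0, R = 101.0, S = 31.0, T = 45.0, V = 43.0,
    W = 130.0, Y = 107.0)
  props <- rbind(hydrophobicity[aa], hydrophilicity[aa],
                 side_chain_mass[aa])
  colnames(props) <- aa
  # standardize each property over the 20 residues (population sd)
  t(apply(props, 1L, function(p) (p - mean(p)) / sqrt(mean((p - mean(p))^2))))
}

#' Pseudo amino acid composition (type I)
#'
#' Chou's type-I pseudo amino acid composition: the 20 residue frequencies
#' followed by `lambda` sequence-order correlation factors computed from
#' standardized hydrophobicity, hydrophilicity and side-chain mass. The
#' full vector is normalized to sum to 1, so the composition block and the
#' correlation block share one scale set by the weight `w`.
#'
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#' @param lambda Number of correlation tiers (default 30); the sequence
#'   must be longer than `lambda`.
#' @param w Weight of the correlation block (default 0.05).
#' @return Numeric vector of length `20 + lambda` summing to 1; names are
#'   the residues followed by `theta1..thetaLambda`.
#' @export
compute_paac <- function(sequence, lambda = 30L, w = 0.05) {
  stopifnot(lambda >= 1L, w > 0)
  res <- strsplit(toupper(sequence), "")[[1L]]
  props <- paac_properties()
  aa <- colnames(props)
  bad <- which(!(res %in% aa))
  if (length(bad) > 0L) {
    stop("non-standard residue '", res[bad[1L]], "' at position ", bad[1L])
  }
  L <- length(res)
  if (L <= lambda) {
    stop("sequence too short for lambda: length ", L, " <= lambda ", lambda)
  }
  idx <- match(res, aa)
  freq <- tabulate(idx, nbins = 20L) / L
  # correlation factor Theta(Ri, Rj): mean squared property difference
  pmat <- props[, idx, drop = FALSE]          # 3 x L
  theta <- vapply(seq_len(lambda), function(k) {
    d <- pmat[, seq_len(L - k), drop = FALSE] -
      pmat[, (k + 1L):L, drop = FALSE]
    mean(colMeans(d^2))
  }, 0)
  denom <- sum(freq) + w * sum(theta)
  out <- c(freq, w * theta) / denom
  names(out) <- c(aa, paste0("theta", seq_len(lambda)))
  out
}

#' Bi-gram features from a position-specific scoring matrix
#'
#' Aggregates consecutive-position products of the transformed PSSM:
#' `B[i, j] = sum_k T[k, i] * T[k + 1, j]`, flattened row-major to a
#' 400-vector. Log-odds scores are squashed to (0, 1) with a logistic
#' transform first, which keeps the bi-gram totals bounded regardless of
#' profile depth.
#'
#' @param pssm L x 20 numeric matrix of log-odds scores (L >= 2).
#' @param transform `"sigmoid"` (default) or `"none"` for raw scores.
#' @return Numeric vector of length 400, names `B_i_j`.
#' @export
compute_bigram_pssm <- function(pssm, transform = c("sigmoid", "none")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(pssm), ncol(pssm) == 20L)
  L <- nrow(pssm)
  if (L < 2L) stop("PSSM must have at least 2 rows, got ", L)
  T <- if (transform == "sigmoid") 1 / (1 + exp(-pssm)) else pssm
  B <- crossprod(T[-L, , drop = FALSE], T[-1L, , drop = FALSE])  # 20 x 20
  out <- as.vector(t(B))  # row-major: i outer, j inner
  names(out) <- paste0("B_", rep(1:20, each = 20L), "_", rep(1:20, 20L))
  out
}

#' Assemble the drug-target interaction feature vector
#'
#' Fixed-order concatenation of the drug descriptor block `G`, the domain
#' indicator block `O`, the pseudo amino acid composition block `A` and
#' the bi-gram PSSM block `B`. At the reference dimensions (1444 drug
#' descriptors, 1331 domains, lambda = 30, 400 bi-grams) the protein part
#' is 1781-dimensional and the full vector 3225-dimensional.
#'
#' @param G Numeric drug descriptor vector.
#' @param O Binary domain vector.
#' @param A Pseudo amino acid composition vector.
#' @param B Bi-gram PSSM vector (length 400).
#' @param expected_lengths Optional named list/vector with any of
#'   `G`, `O`, `A`, `B`; mismatches are an error.
#' @return Numeric vector `c(G, O, A, B)` with an attribute `blocks`
#'   giving the block lengths.
#' @export
assemble_dti_vector <- function(G, O, A, B, expected_lengths = NULL) {
  if (!is.null(expected_lengths)) {
    for (nm in intersect(names(expected_lengths), c("G", "O", "A", "B"))) {
      have <- length(get(nm))
      want <- expected_lengths[[nm]]
      if (have != want) {
        stop("block ", nm, " has length ", have, ", expected ", want)
      }
    }
  }
  if (length(B) != 400L) {
    stop("bi-gram block must have length 400, got ", length(B))
  }
  out <- c(as.numeric(G), as.numeric(O), as.numeric(A), as.numeric(B))
  attr(out, "blocks") <- c(G = length(G), O = length(O),
                           A = length(A), B = length(B))
  out
}

#' Featurize a set of drug-target pairs
#'
#' Convenience wrapper: looks up the drug descriptor and the three protein
#' blocks for every pair and stacks the assembled vectors into a matrix.
#'
#' @param pairs A `pair_table`.
#' @param drug_features Numeric matrix, rownames = drug ids.
#' @param domain_annotations Named list: protein id -> domain ids.
#' @param vocabulary Ordered domain vocabulary.
#' @param sequences Named character vector of protein sequences.
#' @param pssms Named list of L x 20 PSSM matrices.
#' @param lambda,w Pseudo amino acid composition parameters.
#' @return List with `ids` (`drug|target` keys) and `x` (matrix, one row
#'   per pair).
#' @export
featurize_pairs <- function(pairs, drug_features, domain_annotations,
                            vocabulary, sequences, pssms,
                            lambda = 30L, w = 0.05) {
  prot_ids <- unique(pairs$target_id)
  prot_block <- lapply(prot_ids, function(pid) {
    if (!pid %in% names(sequences)) stop("no sequence for target ", pid)
    if (!pid %in% names(pssms)) stop("no PSSM for target ", pid)
    ann <- if (pid %in% names(domain_annotations)) {
      domain_annotations[[pid]]
    } else character()
    c(build_domain_vector(ann, vocabulary),
      compute_paac(sequences[[pid]], lambda = lambda, w = w),
      compute_bigram_pssm(pssms[[pid]]))
  })
  names(prot_block) <- prot_ids
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    did <- pairs$drug_id[i]
    if (!did %in% rownames(drug_features)) {
      stop("no drug descriptor for drug ", did)
    }
    c(drug_features[did, ], prot_block[[pairs$target_id[i]]])
  })
  x <- do.call(rbind, rows)
  ids <- paste(pairs$drug_id, pairs$target_id, sep = "|")
  rownames(x) <- ids
  list(ids = ids, x = x)
}
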