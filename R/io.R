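#' Read a drug-target pair table
#'
#' The canonical pair format is TSV with a header row and columns
#' `drug_id`, `target_id` and optionally `label`. Labels are `1` (known
#' interaction) or `0` (unlabeled pair); a missing label column means every
#' pair is unlabeled. "Negative" is never a valid input label -- negatives
#' are what the pipeline produces.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `drug_id`, `target_id`, `label`
#'   (factor with levels `positive`, `unlabeled`), of class `pair_table`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, blank.lines.skip = TRUE)
  if (nrow(df) == 0L) {
    warning("empty pair file: ", path)
    return(new_pair_table(character(), character(), factor(
      character(), levels = c("positive", "unlabeled"))))
  }
  if (ncol(df) < 2L) stop("pair file needs at least 2 columns: ", path)
  drug <- df[[1L]]
  target <- df[[2L]]
  if (ncol(df) >= 3L) {
    tok <- trimws(df[[3L]])
    bad <- setdiff(unique(tok), c("1", "0"))
    if (length(bad) > 0L) {
      stop("unknown label token(s) in ", path, ": ",
           paste(bad, collapse = ", "), " (expected 1 or 0)")
    }
    label <- ifelse(tok == "1", "positive", "unlabeled")
  } else {
    label <- rep("unlabeled", length(drug))
  }
  new_pair_table(drug, target,
                 factor(label, levels = c("positive", "unlabeled")))
}

new_pair_table <- function(drug_id, target_id, label) {
  key <- paste(drug_id, target_id, sep = "\x1f")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    pairs <- vapply(strsplit(dup, "\x1f", fixed = TRUE),
                    function(p) paste0("(", p[1], ", ", p[2], ")"), "")
    stop("duplicate drug-target pair(s): ", paste(pairs, collapse = "; "))
  }
  out <- data.frame(drug_id = drug_id, target_id = target_id,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Write a pair table
#'
#' Rows are sorted by `drug_id` then `target_id` so that a read/write
#' round trip is byte-stable. Labels serialize as `1` (positive), `0`
#' (unlabeled); a `prediction` column of -1/+1, when present, is kept.
#'
#' @param pairs A `pair_table`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  ord <- order(pairs$drug_id, pairs$target_id, method = "radix")
  out <- pairs[ord, , drop = FALSE]
  out$label <- ifelse(out$label == "positive", 1L, 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, one body row per
#' residue with a position index, the residue, 20 log-odds score columns
#' (used) and a trailing percentage/statistics block (ignored). Scores are
#' returned unchanged, negatives included.
#'
#' @param path Path to an ASCII PSSM file.
#' @return An L x 20 numeric matrix, columns named in the order
#'   A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PSSM file: ", path)
  body <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines, value = TRUE)
  if (length(body) == 0L) stop("no PSSM body rows found in ", path)
  rows <- lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    # index, residue, then at least 20 scores
    if (length(tok) < 22L) {
      stop("malformed PSSM row (fewer than 20 score columns) in ", path,
           ": ", ln)
    }
    sc <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(sc)) stop("non-numeric PSSM scores in ", path, ": ", ln)
    sc
  })
  m <- do.call(rbind, rows)
  colnames(m) <- pssm_residue_order()
  m
}

pssm_residue_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Read a dense feature table
#'
#' CSV or TSV (sniffed from the extension) with a header row; the first
#' column holds sample ids, the rest numeric feature values. Missing values
#' are an error: upstream descriptor generation must impute or drop.
#'
#' @param path Path to a CSV/TSV file.
#' @return A list with `ids` (character), `x` (numeric matrix, rownames =
#'   ids) and `features` (colnames).
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs id column + features: ", path)
  ids <- as.character(df[[1L]])
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values in feature table: ", path)
  rownames(x) <- ids
  list(ids = ids, x = x, features = colnames(x))
}

#' Write a dense feature table as CSV
#'
#' @param ids Sample ids.
#' @param x Numeric matrix, one row per id.
#' @param path Output path (CSV).
#' @export
write_feature_table <- function(ids, x, path) {
  stopifnot(length(ids) == nrow(x))
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f_%04d", seq_len(ncol(x)))
  }
  df <- data.frame(sample_id = ids, x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read domain annotations
#'
#' TSV with columns `protein_id` and `domain_id`, one row per (protein,
#' domain) assignment; proteins absent from the file have no domains.
#'
#' @param path Path to TSV.
#' @return Named list mapping protein id to a character vector of domains.
#' @export
read_domain_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("domain annotation file needs 2 columns: ", path)
  split(as.character(df[[2L]]), df[[1L]])
}

#' Read a domain vocabulary (one domain accession per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique domain ids in file order.
#' @export
read_domain_vocabulary <- function(path) {
  v <- readLines(path, warn = FALSE)
  v <- trimws(v[nzchar(trimws(v))])
  if (anyDuplicated(v)) stop("duplicate ids in domain vocabulary: ", path)
  v
}
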