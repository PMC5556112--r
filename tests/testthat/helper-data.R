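# Shared fixtures built in code.

# Small two-cluster PU dataset: positives near mu_p, unlabeled pool mixing
# hidden positives and negatives near mu_n. Descriptor-like positive
# baseline so cosine geometry is informative.
make_pu_toy <- function(n_pos = 20, n_neg = 60, n_hidden = 10, d = 8,
                        sep = 3, seed = 1) {
  set.seed(seed)
  mu_p <- rep(2, d) + c(rep(sep / sqrt(d), d %/% 2), rep(0, d - d %/% 2))
  mu_n <- rep(2, d)
  xp <- sweep(matrix(rnorm(n_pos * d, sd = 0.5), n_pos), 2, mu_p, "+")
  xh <- sweep(matrix(rnorm(n_hidden * d, sd = 0.5), n_hidden), 2, mu_p, "+")
  xn <- sweep(matrix(rnorm(n_neg * d, sd = 0.5), n_neg), 2, mu_n, "+")
  x <- rbind(xp, xh, xn)
  list(x = x, p_rows = seq_len(n_pos),
       u_rows = (n_pos + 1):(n_pos + n_hidden + n_neg),
       truth = c(rep(TRUE, n_pos + n_hidden), rep(FALSE, n_neg)))
}

# Contaminated-pool study conditions used by the pipeline-level
# experiments: ~27% of the unlabeled pool is hidden positives.
contaminated_spec <- function(seed, effect_size = 2, affinity = TRUE) {
  synthetic_spec(n_drugs = 50L, n_targets = 20L, positive_rate = 0.25,
                 label_rate = 0.2, effect_size = effect_size,
                 affinity = affinity, seed = seed)
}

# Fast pipeline configuration for cross-validation tests.
cv_config <- function(...) {
  pudti_config(svm_tol = 1e-3, trials = 1, folds = 5, ...)
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

pssm_fixture_path <- function() {
  system.file("extdata", "example.pssm", package = "pudti", mustWork = TRUE)
}
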