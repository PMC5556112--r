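test_that("domain vectors are membership indicators over the vocabulary", {
  vocab <- c("PF1", "PF2", "PF3")
  expect_equal(build_domain_vector(character(), vocab), c(0L, 0L, 0L))
  expect_equal(build_domain_vector(vocab, vocab), c(1L, 1L, 1L))
  expect_warning(
    v <- build_domain_vector(c("PF3", "PFX"), vocab), "PFX")
  expect_equal(v, c(0L, 0L, 1L))
})

test_that("pseudo amino acid composition has the reference layout", {
  seq50 <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  a <- compute_paac(seq50, lambda = 30)
  expect_length(a, 50L)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(all(a >= 0))
})

test_that("a homopolymer has zero correlation factors", {
  a <- compute_paac(strrep("A", 40), lambda = 5)
  expect_equal(unname(a[1]), 1)              # all mass on residue A
  expect_equal(unname(a[2:20]), rep(0, 19))
  expect_equal(unname(a[21:25]), rep(0, 5))  # theta = 0 throughout
})

test_that("composition matches an independently computed reference", {
  # frozen from a direct transcription of the published type-I formulas
  ref <- c(rep(0.032417636345, 20),
           0.065369274589, 0.073455172669, 0.067811644331,
           0.083698881891, 0.061312299616)
  a <- compute_paac(strrep("ACDEFGHIKLMNPQRSTVWY", 2), lambda = 5, w = 0.05)
  expect_equal(unname(a), ref, tolerance = 1e-9)
})

test_that("sequence validation names the offending residue and length", {
  expect_error(compute_paac("ACDXACDEFGHIKLMNPQRSTVWY", lambda = 3),
               "position 4")
  expect_error(compute_paac("ACDE", lambda = 10), "too short")
})

test_that("bi-gram features aggregate consecutive-position products", {
  pssm <- matrix(rnorm(10 * 20), 10)
  b <- compute_bigram_pssm(pssm)
  expect_length(b, 400L)
  # hand case in the transformed matrix: unit rows e1 then e2
  t2 <- matrix(0, 2, 20); t2[1, 1] <- 1; t2[2, 2] <- 1
  b2 <- compute_bigram_pssm(t2, transform = "none")
  expect_equal(unname(b2[["B_1_2"]]), 1)
  expect_equal(sum(b2), 1)
  # row-major flattening: B_1_2 sits at position 2
  expect_equal(names(b2)[2], "B_1_2")
})

test_that("bi-gram map is bilinear in the transformed matrix", {
  t0 <- matrix(runif(8 * 20), 8)
  expect_equal(compute_bigram_pssm(matrix(0, 5, 20), transform = "none"),
               compute_bigram_pssm(matrix(0, 5, 20), transform = "none") * 0)
  for (a in c(0.5, 2, -1)) {
    expect_equal(compute_bigram_pssm(a * t0, transform = "none"),
                 a^2 * compute_bigram_pssm(t0, transform = "none"),
                 tolerance = 1e-10)
  }
  expect_error(compute_bigram_pssm(matrix(0, 1, 20)), "at least 2 rows")
})

test_that("assembled vectors have the reference dimensions", {
  G <- numeric(1444)
  O <- numeric(1331)
  A <- numeric(50)
  B <- numeric(400)
  f <- assemble_dti_vector(G, O, A, B)
  expect_length(f, 3225L)
  expect_equal(sum(attr(f, "blocks")[c("O", "A", "B")]), 1781)
  # small layout: 3 + 2 + 21 + 400
  f2 <- assemble_dti_vector(numeric(3), numeric(2), numeric(21),
                            numeric(400))
  expect_length(f2, 426L)
})

test_that("block order is fixed and slices recover the inputs", {
  G <- rnorm(5); O <- c(1, 0, 1); A <- runif(4); B <- rnorm(400)
  f <- assemble_dti_vector(G, O, A, B)
  expect_equal(f[1:5], G)
  expect_equal(f[6:8], O)
  expect_equal(f[9:12], A)
  expect_error(
    assemble_dti_vector(G, O, A, B, expected_lengths = list(G = 9)),
    "length 5, expected 9")
  expect_error(assemble_dti_vector(G, O, A, numeric(10)), "400")
})

test_that("featurize_pairs stitches the blocks per pair", {
  pairs <- read_pairs(write_tsv_lines(c("drug_id\ttarget_id\tlabel",
                                        "D1\tT1\t1", "D2\tT1\t0")))
  drugs <- matrix(1:6, 2, dimnames = list(c("D1", "D2"), NULL))
  seqs <- c(T1 = strrep("ACDEFGHIKLMNPQRSTVWY", 2))
  pssms <- list(T1 = matrix(rnorm(80), 4))
  out <- featurize_pairs(pairs, drugs, list(T1 = c("PF2")),
                         c("PF1", "PF2"), seqs, pssms, lambda = 5)
  expect_equal(dim(out$x), c(2L, 3 + 2 + 25 + 400))
  expect_equal(unname(out$x[1, 1:3]), c(1, 3, 5))
  expect_equal(unname(out$x[1, 4:5]), c(0, 1))
  expect_error(
    featurize_pairs(pairs, drugs, list(), c("PF1"),
                    c(T2 = "ACD"), pssms, lambda = 5),
    "no sequence")
})
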