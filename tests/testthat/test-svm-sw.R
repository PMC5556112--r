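toy_split <- function(p, rn, a = integer()) {
  structure(list(P = p, EP = integer(), RN = rn, A = a,
                 P_aug = p, c_spy = NULL, c_roc = NULL),
            class = "sample_split")
}

test_that("the augmented set carries the per-role penalties", {
  x <- matrix(rnorm(7 * 2), 7)
  w <- data.frame(row = 6:7, WP = c(0.25, 1), WN = c(0.75, 0))
  aug <- build_augmented_set(x, toy_split(1:2, 3:5, 6:7), w,
                             C1 = 2, C2 = 4, C3 = 8, C4 = 16)
  # 2 P + 3 RN + 2 ambiguous-positive + 1 ambiguous-negative (one zero
  # penalty row dropped)
  expect_equal(length(aug$rows), 8L)
  expect_equal(aug$c[1:2], c(2, 2))
  expect_equal(aug$c[3:5], c(16, 16, 16))
  expect_equal(aug$c[6:7], c(4 * 0.25, 4 * 1))
  expect_equal(aug$c[8], 8 * 0.75)
  expect_equal(aug$y, c(1L, 1L, -1L, -1L, -1L, 1L, 1L, -1L))
  # empty ambiguous set degenerates to a two-class set
  aug0 <- build_augmented_set(x, toy_split(1:2, 3:5), w[0, ],
                              C1 = 3, C4 = 5)
  expect_equal(aug0$c, c(3, 3, 5, 5, 5))
  expect_error(
    build_augmented_set(x, toy_split(1:2, 3:5, 6:7), w[1, , drop = FALSE]),
    "missing similarity weights")
})

test_that("the dual solver matches a generic QP reference", {
  skip_if_not_installed("kernlab")
  for (s in 1:8) {
    set.seed(s)
    n <- sample(12:50, 1)
    x <- matrix(rnorm(n * 4), n)
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1L, 1L)
    cc <- runif(n, 0.1, 4)
    g <- runif(1, 0.1, 1.5)
    fit <- svm_sw_train(x, y, cc, gamma = g, tol = 1e-8)
    K <- rbf_kernel(x, gamma = g)
    Q <- (y %o% y) * K
    sol <- kernlab::ipop(rep(-1, n), Q, matrix(as.numeric(y), 1), 0,
                         rep(0, n), cc, 0, sigf = 9, maxiter = 400)
    a2 <- kernlab::primal(sol)
    obj2 <- drop(0.5 * t(a2) %*% Q %*% a2 - sum(a2))
    expect_lt(abs(fit$objective - obj2), 1e-5)
    s2 <- as.vector(K %*% (a2 * y))
    free <- a2 > 1e-6 & a2 < cc - 1e-6
    b2 <- if (any(free)) mean((y - s2)[free]) else fit$b
    expect_lt(max(abs(predict(fit, x)$score - (s2 + b2))), 1e-4)
  }
})

test_that("a fully weighted duplicate behaves like a plain positive", {
  set.seed(14)
  x <- rbind(matrix(rnorm(10 * 2, mean = 2), 10),
             matrix(rnorm(10 * 2, mean = -2), 10))
  x <- rbind(x, x[1, ])                    # row 21 duplicates positive 1
  w <- data.frame(row = 21, WP = 1, WN = 0)
  m_amb <- svm_sw_fit(x, toy_split(1:10, 11:20, 21), w,
                      pudti_config(C1 = 1, C2 = 1, C3 = 1, C4 = 1))
  x2 <- x[c(1:20, 1), ]
  m_pos <- svm_sw_train(x2, c(rep(1L, 10), rep(-1L, 10), 1L),
                        rep(1, 21), gamma = 1 / 2)
  grid <- as.matrix(expand.grid(seq(-3, 3, 1.5), seq(-3, 3, 1.5)))
  expect_equal(predict(m_amb, grid)$score, predict(m_pos, grid)$score,
               tolerance = 1e-4)
})

test_that("one-sided ambiguous weights merge into the negative class", {
  set.seed(15)
  x <- rbind(matrix(rnorm(8 * 2, mean = 2), 8),
             matrix(rnorm(8 * 2, mean = -2), 8),
             matrix(rnorm(4 * 2, mean = -2), 4))
  w <- data.frame(row = 17:20, WP = 0, WN = 1)
  m_amb <- svm_sw_fit(x, toy_split(1:8, 9:16, 17:20), w,
                      pudti_config(C3 = 0.7))
  m_neg <- svm_sw_train(x, c(rep(1L, 8), rep(-1L, 12)),
                        c(rep(1, 16), rep(0.7, 4)), gamma = 1 / 2)
  grid <- as.matrix(expand.grid(seq(-3, 3, 1.5), seq(-3, 3, 1.5)))
  expect_equal(predict(m_amb, grid)$score, predict(m_neg, grid)$score,
               tolerance = 1e-4)
})

test_that("prediction is strict: the hyperplane itself is negative", {
  model <- structure(list(sv = matrix(c(1, 0, 0, 1), 2), coef = c(1, -1),
                          b = 0, gamma = 1), class = "svm_sw")
  # symmetric point: kernel terms cancel exactly, score 0
  p <- predict(model, matrix(c(0.5, 0.5), 1))
  expect_equal(p$score, 0)
  expect_equal(p$label, -1L)
  # hand kernel sum on an off-axis point
  z <- matrix(c(0.9, 0.1), 1)
  s_hand <- exp(-sum((z - c(1, 0))^2)) - exp(-sum((z - c(0, 1))^2))
  expect_equal(predict(model, z)$score, s_hand)
})

test_that("single-class input and bad penalties are rejected", {
  x <- matrix(rnorm(10), 5)
  expect_error(svm_sw_train(x, rep(1L, 5), rep(1, 5)), "single class")
  expect_error(svm_sw_train(x, c(1L, 1L, 1L, -1L, -1L), rep(0, 5)))
})

test_that("with no ambiguity and C1 = C4 the model is a plain C-SVM", {
  skip_if_not_installed("e1071")
  set.seed(31)
  x <- rbind(matrix(rnorm(15 * 3, mean = 1), 15),
             matrix(rnorm(15 * 3, mean = -1), 15))
  y <- c(rep(1L, 15), rep(-1L, 15))
  C <- 2
  fit <- svm_sw_train(x, y, rep(C, 30), gamma = 0.4, tol = 1e-8)
  ref <- e1071::svm(x, factor(y), scale = FALSE, kernel = "radial",
                    gamma = 0.4, cost = C, tolerance = 1e-8)
  sc_ref <- attr(predict(ref, x, decision.values = TRUE),
                 "decision.values")[, 1]
  if (colnames(attr(predict(ref, x, decision.values = TRUE),
                    "decision.values")) == "-1/1") sc_ref <- -sc_ref
  expect_lt(max(abs(predict(fit, x)$score - sc_ref)), 1e-3)
})

test_that("raising an ambiguous sample's positive penalty never lowers
          its score", {
  set.seed(41)
  x <- rbind(matrix(rnorm(8 * 2, mean = 1.5), 8),
             matrix(rnorm(8 * 2, mean = -1.5), 8),
             matrix(rnorm(1 * 2, sd = 0.2), 1))
  sp <- toy_split(1:8, 9:16, 17)
  last <- NULL
  scores <- vapply(c(0.1, 0.5, 1, 2, 4), function(C2) {
    w <- data.frame(row = 17, WP = 1, WN = 0.)
    m <- svm_sw_fit(x, sp, w, pudti_config(C2 = C2))
    predict(m, x[17, , drop = FALSE])$score
  }, 0)
  expect_true(all(diff(scores) > -1e-8))
})

test_that("grid search is exhaustive, deterministic and tie-stable", {
  set.seed(51)
  d <- make_pu_toy(n_pos = 15, n_neg = 30, n_hidden = 5, seed = 51)
  sp <- toy_split(d$p_rows, d$u_rows[6:35], integer())
  w <- data.frame(row = integer(), WP = numeric(), WN = numeric())
  set.seed(1)
  g1 <- svm_sw_grid_search(d$x, sp, w, C_grid = 1, gamma_grid = 0.2,
                           folds = 2)
  expect_equal(g1$best$C1, 1)
  expect_equal(g1$best$gamma, 0.2)
  set.seed(2)
  g2 <- svm_sw_grid_search(d$x, sp, w, C_grid = c(0.5, 2),
                           gamma_grid = 0.2, folds = 2)
  set.seed(2)
  g3 <- svm_sw_grid_search(d$x, sp, w, C_grid = c(0.5, 2),
                           gamma_grid = 0.2, folds = 2)
  expect_identical(g2$best, g3$best)
  expect_equal(nrow(g2$table), 2L)
})
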