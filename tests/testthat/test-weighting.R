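test_that("cosine similarity matches hand values and handles zeros", {
  v <- rnorm(6)
  expect_equal(cosine_sim(v, v), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 2), c(2, 1)), 0.8)
  expect_equal(cosine_sim(c(0, 0), c(3, 4)), 0)
})

test_that("prototype counts follow the cluster-budget split", {
  set.seed(21)
  x <- matrix(rnorm(120 * 4, mean = 2), 120)
  p_rows <- 1:20
  rn_rows <- 21:60    # |RN| = 40
  pr <- compute_prototypes(x, p_rows, rn_rows, a_size = 60, t = 30)
  expect_equal(pr$a, 12)  # 30 * 40 / (60 + 40)
  expect_equal(dim(pr$pos), c(12L, 4L))
  expect_equal(dim(pr$neg), c(12L, 4L))
  expect_length(pr$rn_cluster, 40L)
})

test_that("a single-cluster prototype pair is the closed-form Rocchio", {
  x <- rbind(c(2, 1), c(2.2, 0.9), c(1.8, 1.1),   # positives
             c(1, 2), c(0.9, 2.2), c(1.1, 1.8))   # reliable negatives
  set.seed(1)
  pr <- compute_prototypes(x, 1:3, 4:6, a_size = 0, t = 1,
                           alpha = 16, beta = 4)
  expect_equal(pr$a, 1L)
  unit <- function(m) m / sqrt(rowSums(m^2))
  mp <- colMeans(unit(x[1:3, ])); mn <- colMeans(unit(x[4:6, ]))
  expect_equal(unname(pr$neg[1, ]), unname(16 * mn - 4 * mp),
               tolerance = 1e-12)
  expect_equal(unname(pr$pos[1, ]), unname(16 * mp - 4 * mn),
               tolerance = 1e-12)
})

test_that("identical seeds give identical prototypes", {
  set.seed(33)
  x <- matrix(rnorm(200 * 3, mean = 2), 200)
  set.seed(8); a <- compute_prototypes(x, 1:40, 41:140, a_size = 60)
  set.seed(8); b <- compute_prototypes(x, 1:40, 41:140, a_size = 60)
  expect_identical(a$pos, b$pos)
  expect_identical(a$neg, b$neg)
})

test_that("the worked micro-cluster example reproduces exactly", {
  fx <- microcluster_fixture()
  set.seed(1)
  lw <- local_weights(fx$points, seq_len(nrow(fx$points)), fx$prototypes,
                      t = fx$t, rn_size = fx$rn_size)
  expect_equal(lw$n, 4L)
  got <- unique(data.frame(cluster = fx$cluster, LocP = lw$LocP,
                           LocN = lw$LocN))
  got <- got[order(got$cluster), ]
  expect_equal(got$LocP, fx$expected$LocP)
  expect_equal(got$LocN, fx$expected$LocN)
  # every member of a spatial cluster shares the same local weight
  expect_equal(nrow(got), 4L)
})

test_that("moving one mixed-cluster point across the boundary recounts", {
  fx <- microcluster_fixture()
  pts <- fx$points
  i <- which(fx$cluster == 2)[1]           # a positive-tagged M2 member
  stopifnot(pts[i, 1] > pts[i, 2])
  pts[i, ] <- rev(pts[i, ])                # reflect across x1 = x2
  set.seed(1)
  lw <- local_weights(pts, seq_len(nrow(pts)), fx$prototypes,
                      t = fx$t, rn_size = fx$rn_size)
  expect_equal(sort(unique(round(lw$LocP[fx$cluster == 2], 10))), 4 / 12)
})

test_that("local weights are cluster-shared tag fractions in 2-D", {
  # one tight cluster: 3 points leaning positive, 1 leaning negative
  pts <- rbind(c(0.9, 0.1), c(0.88, 0.12), c(0.92, 0.08), c(0.1, 0.9))
  protos <- structure(list(pos = matrix(c(1, 0), 1), neg = matrix(c(0, 1), 1),
                           a = 1L, rn_cluster = integer()),
                      class = "prototype_set")
  set.seed(2)
  lw <- local_weights(pts, 1:4, protos, n_clusters = 1, rn_size = 1)
  expect_equal(lw$LocP, rep(3 / 4, 4))
  expect_equal(lw$LocN, rep(1 / 4, 4))
})

test_that("global weights normalize summed clamped cosines", {
  protos <- structure(list(pos = matrix(c(1, 0), 1), neg = matrix(c(0, 1), 1),
                           a = 1L, rn_cluster = integer()),
                      class = "prototype_set")
  x <- rbind(c(1, 1), c(0.9, 0.3))
  gw <- global_weights(x, 1:2, protos)
  expect_equal(gw$GloP[1], 0.5)            # equal similarities
  expect_equal(gw$GloP[2], 0.75)           # 0.9 / (0.9 + 0.3)
  expect_equal(gw$GloP + gw$GloN, c(1, 1))
  # two prototype pairs, hand-summed
  protos2 <- structure(list(pos = rbind(c(1, 0), c(0.6, 0.8)),
                            neg = rbind(c(0, 1), c(0.8, 0.6)),
                            a = 2L, rn_cluster = integer()),
                       class = "prototype_set")
  xx <- matrix(c(3, 4), 1)
  sims_p <- c(cosine_sim(c(3, 4), c(1, 0)), cosine_sim(c(3, 4), c(0.6, 0.8)))
  sims_n <- c(cosine_sim(c(3, 4), c(0, 1)), cosine_sim(c(3, 4), c(0.8, 0.6)))
  gw2 <- global_weights(xx, 1, protos2)
  expect_equal(gw2$GloP, sum(sims_p) / sum(c(sims_p, sims_n)))
  # a sample with no positive similarity to anything gets (0.5, 0.5)
  expect_warning(gw3 <- global_weights(matrix(c(-1, -1), 1), 1, protos),
                 "no positive similarity")
  expect_equal(gw3$GloP, 0.5)
})

test_that("combined weights are the stated convex combination", {
  expect_equal(combine_weights(0.3, 0.7, 0.9, 0.1, alpha = 0)$WP, 0.3)
  expect_equal(combine_weights(0.3, 0.7, 0.9, 0.1, alpha = 1)$WP, 0.9)
  w <- combine_weights(5 / 12, 7 / 12, 0.75, 0.25, alpha = 0.6)
  expect_equal(w$WP, 0.4 * 5 / 12 + 0.6 * 0.75, tolerance = 1e-12)
  expect_equal(w$WP + w$WN, 1)
  expect_error(combine_weights(0.5, 0.5, 0.5, 0.5, alpha = 1.2), "alpha")
  # monotone in each argument
  expect_gt(combine_weights(0.5, 0.5, 0.8, 0.2, 0.6)$WP,
            combine_weights(0.5, 0.5, 0.6, 0.4, 0.6)$WP)
  expect_gt(combine_weights(0.7, 0.3, 0.5, 0.5, 0.6)$WP,
            combine_weights(0.5, 0.5, 0.5, 0.5, 0.6)$WP)
})

test_that("all weight pairs sum to one on a full synthetic run", {
  d <- generate_dti_data(contaminated_spec(seed = 19))
  p <- which(d$known); u <- which(!d$known)
  cfg <- pudti_config()
  sel <- select_features(d$x, p, u, k = cfg$top_k)
  xs <- d$x[, sel$selected, drop = FALSE]
  set.seed(19)
  sp <- ndtise(xs, p, u, cfg)
  w <- suppressWarnings(compute_similarity_weights(xs, sp, cfg))
  expect_equal(nrow(w), length(sp$A))
  expect_true(all(abs(w$LocP + w$LocN - 1) < 1e-9))
  expect_true(all(abs(w$GloP + w$GloN - 1) < 1e-9))
  expect_true(all(abs(w$WP + w$WN - 1) < 1e-9))
  expect_true(all(w$WP >= 0 & w$WP <= 1))
})

test_that("same-cluster samples share local but not global weights", {
  d <- generate_dti_data(contaminated_spec(seed = 23))
  p <- which(d$known); u <- which(!d$known)
  cfg <- pudti_config()
  sel <- select_features(d$x, p, u, k = cfg$top_k)
  xs <- d$x[, sel$selected, drop = FALSE]
  set.seed(23)
  sp <- ndtise(xs, p, u, cfg)
  protos <- compute_prototypes(xs, sp$P_aug, sp$RN, length(sp$A),
                               t = cfg$t)
  lw <- local_weights(xs, sp$A, protos, t = cfg$t,
                      rn_size = length(sp$RN))
  gw <- global_weights(xs, sp$A, protos)
  cl <- lw$cluster[1]
  members <- which(lw$cluster == cl)
  expect_length(unique(lw$LocP[members]), 1L)
  if (length(members) > 2) {
    expect_gt(length(unique(round(gw$GloP[members], 12))), 1L)
  }
})
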