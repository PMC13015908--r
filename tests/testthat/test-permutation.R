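test_that("TFCE of trivial series matches closed forms", {
  p <- tfce_params(E = 1, H = 2, dh = 0.001)
  expect_equal(tfce_transform(rep(0, 12), p), rep(0, 12))
  # constant series of height 1, length 10: integral of 10 * h^2 over (0,1)
  sc <- tfce_transform(rep(1, 10), p)
  expect_equal(sc, rep(sc[1], 10))
  expect_lt(abs(sc[1] - 10 / 3) / (10 / 3), 0.01)
})

test_that("splitting a supra-threshold run decreases flanking scores", {
  x <- rep(1, 11)
  y <- x; y[6] <- 0
  p <- tfce_params(dh = 0.01)
  sx <- tfce_transform(x, p); sy <- tfce_transform(y, p)
  expect_true(all(sy[c(1:5, 7:11)] < sx[c(1:5, 7:11)]))
})

test_that("TFCE scales as c^(H+1) under amplitude scaling", {
  set.seed(3)
  x <- abs(rnorm(20))
  for (H in c(0, 1, 2)) {
    cst <- 3.7
    p1 <- tfce_params(E = 1, H = H, dh = 0.005)
    p2 <- tfce_params(E = 1, H = H, dh = 0.005 * cst)
    expect_equal(tfce_transform(cst * x, p2),
                 cst^(H + 1) * tfce_transform(x, p1), tolerance = 1e-10)
  }
  expect_error(tfce_params(dh = 0), "dh")
  expect_error(tfce_transform(c(1, NA, 2)), "finite")
})

test_that("two-sided enhancement treats each sign separately", {
  x <- c(1, 1, -1, -1, -1)
  p2 <- tfce_params(dh = 0.01, tail = "two")
  s <- tfce_transform(x, p2)
  expect_true(all(s[1:2] > 0) && all(s[3:5] < 0))
  expect_equal(abs(s[3:5]),
               tfce_transform(pmax(-x, 0), tfce_params(dh = 0.01))[3:5])
})

test_that("fwe p-values use the add-one estimator with a hard floor", {
  nullmax <- 1:999
  res <- fwe_pvalues(c(2000, 500, 0), nullmax)
  expect_equal(res$p_fwe[1], 1 / 1000)       # exceeds every null value
  expect_equal(res$p_fwe[2], (1 + 500) / 1000, tolerance = 1e-12)
  expect_equal(res$p_fwe[3], 1)
  expect_true(all(diff(res$p_fwe[order(res$score)]) <= 0) ||
                all(diff(res$p_fwe[order(-res$score)]) <= 0))
  # observed at the null median sits near p = 0.5
  expect_equal(fwe_pvalues(500, nullmax)$p_fwe, 0.5, tolerance = 0.01)
})

test_that("exhaustive sign-flip enumeration agrees with Monte-Carlo", {
  set.seed(5)
  X <- matrix(rnorm(8 * 10, mean = 0.4), 8, 10)
  p_ex <- tfce_params(dh = 0.05, seed = 6)
  ex <- permutation_null(X, "within", p_ex, exhaustive = TRUE)
  expect_equal(length(ex$null_max), 2^8)
  mc <- permutation_null(X, "within",
                         tfce_params(dh = 0.05, n_permutations = 4000,
                                     seed = 7))
  p_from <- function(nul) {
    (1 + sum(nul$null_max >= max(abs(nul$observed_scores)))) /
      (length(nul$null_max) + 1)
  }
  expect_lt(abs(p_from(ex) - p_from(mc)), 0.02)
  expect_error(permutation_null(X[1, , drop = FALSE], "within"),
               "at least 2")
  expect_error(tfce_params(n_permutations = 0), "n_permutations")
})

test_that("permutation machinery is deterministic given the seed", {
  set.seed(8)
  X <- matrix(rnorm(12 * 15), 12, 15)
  a <- permutation_null(X, "within", tfce_params(n_permutations = 200,
                                                 seed = 9))
  b <- permutation_null(X, "within", tfce_params(n_permutations = 200,
                                                 seed = 9))
  expect_identical(a$null_max, b$null_max)
})

test_that("between-group permutation detects a planted group difference", {
  set.seed(10)
  X <- rbind(matrix(rnorm(12 * 15), 12, 15),
             cbind(matrix(rnorm(12 * 5, 1.6), 12, 5),
                   matrix(rnorm(12 * 10), 12, 10)))
  groups <- rep(c("ctrl", "stim"), each = 12)
  res <- tfce_permutation_test(X, "between",
                               tfce_params(n_permutations = 500, seed = 11,
                                           tail = "two"), groups = groups)
  expect_lt(min(res$p_fwe[1:5]), 0.05)
  expect_gt(min(res$p_fwe[8:15]), 0.2)
})

test_that("cluster-mass variant finds planted clusters and not noise", {
  set.seed(12)
  X <- cbind(matrix(rnorm(25 * 3, 1.0), 25, 3), matrix(rnorm(25 * 12), 25, 12))
  res <- cluster_mass_variant(X, "within",
                              tfce_params(n_permutations = 500, seed = 13))
  expect_gt(nrow(res$clusters), 0)
  hit <- any(res$clusters$from <= 3 & res$clusters$p_fwe < 0.05)
  expect_true(hit)
  # pure noise: typically nothing survives
  X0 <- matrix(rnorm(25 * 15), 25, 15)
  res0 <- cluster_mass_variant(X0, "within",
                               tfce_params(n_permutations = 300, seed = 14))
  if (nrow(res0$clusters)) expect_gt(min(res0$clusters$p_fwe), 0.05)
})

test_that("TFCE and cluster-mass concur on strong effects", {
  set.seed(15)
  X <- cbind(matrix(rnorm(25 * 4, 1.2), 25, 4), matrix(rnorm(25 * 11), 25, 11))
  p <- tfce_params(n_permutations = 400, seed = 16)
  tf <- tfce_permutation_test(X, "within", p)
  cm <- cluster_mass_variant(X, "within", p)
  tf_sig <- which(tf$p_fwe < 0.05)
  cm_sig <- unlist(lapply(seq_len(nrow(cm$clusters)), function(k) {
    if (cm$clusters$p_fwe[k] < 0.05) cm$clusters$from[k]:cm$clusters$to[k]
  }))
  expect_gt(length(intersect(tf_sig, cm_sig)), 0)
})
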