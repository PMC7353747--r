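test_that("gini matches the pairwise-sum oracle and printed cases", {
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(rep(2.5, 8)), 0)
  set.seed(20)
  for (r in 1:10) {
    x <- rpois(sample(5:50, 1), 4) + runif(1)
    expect_equal(gini(x), oracle_gini(x), tolerance = 1e-9)
  }
  x <- rpois(30, 3)
  x[1] <- 5
  expect_equal(gini(x * 17.3), gini(x), tolerance = 1e-12)  # scale-invariant
  expect_equal(gini(sample(x)), gini(x), tolerance = 1e-12) # permutation
  expect_error(gini(rep(0, 4)), "all-zero")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("gini RMSE compares per-gene distribution shapes", {
  a <- matrix(rpois(200, 5), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  a[a == 0] <- 1
  expect_equal(gini_rmse(a, a), 0)
  b <- a
  b[, 2] <- c(rep(0, 49), 50)   # one gene with extreme concentration
  dg <- abs(gini(a[, 2]) - gini(b[, 2]))
  expect_equal(gini_rmse(a[, 2, drop = FALSE], b[, 2, drop = FALSE]), dg)
  # 3-gene toy against a hand computation
  hand <- sqrt(mean((sapply(1:3, function(j) gini(a[, j])) -
                       sapply(1:3, function(j) gini(b[, j])))^2))
  expect_equal(gini_rmse(a[, 1:3], b[, 1:3]), hand, tolerance = 1e-12)
  expect_error(gini_rmse(a, b, genes = character(0)), "overlapping")
})

test_that("efficient-factor normalization equalizes means", {
  sc <- c(1, 3, 5, 7); fish <- c(10, 20, 30, 50)
  out <- efficient_factor_normalize(sc, fish)
  expect_equal(mean(out), mean(fish))
  expect_equal(out, sc * mean(fish) / mean(sc))
  expect_equal(efficient_factor_normalize(fish, fish), fish)
  expect_error(efficient_factor_normalize(c(0, 0), fish), "positive")
})

test_that("FF distance agrees with the brute-force quadrant scan", {
  set.seed(31)
  for (r in 1:5) {
    n1 <- sample(10:50, 1); n2 <- sample(10:50, 1)
    a <- cbind(rnorm(n1), rnorm(n1))
    b <- cbind(rnorm(n2, 0.5), rnorm(n2))
    expect_equal(ff_distance(a, b), oracle_ff(a, b), tolerance = 1e-12)
  }
  a <- cbind(rnorm(40), rnorm(40))
  expect_equal(ff_distance(a, a), 0)
  # permuting the coordinates of one sample breaks the joint structure
  set.seed(5)
  z <- cbind(rnorm(60), 0)
  z[, 2] <- z[, 1] + rnorm(60, sd = 0.1)
  zperm <- cbind(sample(z[, 1]), sample(z[, 2]))
  expect_gt(ff_distance(z, zperm), 0.2)
  # symmetric in its arguments
  b <- cbind(rnorm(30), rnorm(30))
  expect_equal(ff_distance(a, b), ff_distance(b, a), tolerance = 1e-12)
})

test_that("CMD matches direct arithmetic", {
  R1 <- diag(2)
  R2 <- matrix(1, 2, 2)
  expect_equal(cmd(R1, R2), 1 - 2 / (sqrt(2) * 2), tolerance = 1e-12)
  expect_equal(cmd(R1, R2), 1 - 1 / sqrt(2), tolerance = 1e-12)
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  R <- cor(X)
  expect_equal(cmd(R, R), 0, tolerance = 1e-12)
  R3 <- cor(matrix(rnorm(200), 50, 4))
  expect_equal(cmd(R, R3), cmd(R3, R), tolerance = 1e-12)
  expect_equal(cmd(R, R3),
               1 - sum(diag(R %*% R3)) / (norm(R, "F") * norm(R3, "F")),
               tolerance = 1e-12)
  expect_error(cmd(R, matrix(0, 4, 4)), "zero-norm")
  expect_error(cmd(R, matrix(rnorm(16), 4, 4)), "symmetric")
})

test_that("MAE rescales to the reference library size", {
  ref <- tiny_counts(5, 6, seed = 17, lambda = 5)
  expect_equal(mae(ref, ref), rep(0, 5), ignore_attr = TRUE)
  # an exactly halved matrix is perfect after rescaling
  even <- count_matrix(2 * ref$counts)
  half <- count_matrix(ref$counts)
  expect_equal(mae(even, half), rep(0, 5), ignore_attr = TRUE)
  set.seed(2)
  test <- count_matrix(matrix(rpois(30, 4) + 1, 5, 6))
  expect_equal(mae(ref, test),
               oracle_mae(ref$counts, test$counts, ref$library_sizes,
                          test$counts |> rowSums()),
               tolerance = 1e-9, ignore_attr = TRUE)
  bad <- ref$counts; bad[2, ] <- 0
  expect_error(mae(ref, bad), "library size")
})

test_that("structure correlations apply the 10% filters", {
  set.seed(23)
  ref <- matrix(rpois(600, 3), 30, 20)
  ref[, 1] <- c(rep(0, 28), 1, 1)   # 2/30 cells < 10%: excluded
  test <- ref + matrix(rpois(600, 1), 30, 20)
  r <- structure_correlations(ref, test, "gene")
  included <- colMeans(ref > 0) >= 0.1
  expect_length(r, sum(included))
  j <- which(included)[1]
  expect_equal(unname(r[1]), cor(ref[, j], test[, j]))
  expect_equal(unname(structure_correlations(ref, ref, "gene")),
               rep(1, sum(included)))
  rc <- structure_correlations(ref, test, "cell")
  expect_length(rc, sum(rowMeans(ref > 0) >= 0.1))
  expect_error(structure_correlations(ref * 0, ref, "gene"), "filter")
})

test_that("ACC, ARI and Jaccard match their definitions", {
  expect_equal(acc(c("a", "a", "b", "b"), c("a", "b", "b", "b")), 0.75)
  expect_equal(acc(1:5, 1:5), 1)
  expect_equal(acc(rep("a", 4), rep("b", 4)), 0)
  expect_error(acc(1:3, 1:4), "mismatch")

  expect_equal(ari(1:6, 1:6), 1)           # all singletons, identical
  expect_equal(ari(rep(1, 6), rep(2, 6)), 1)  # both trivial: identical
  expect_equal(ari(1:6, rep(1, 6)), 0)     # singletons vs one cluster
  set.seed(11)
  for (r in 1:8) {
    n <- sample(8:30, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(ari(a[perm], b[perm]), ari(a, b), tolerance = 1e-12)
  }
  if (requireNamespace("mclust", quietly = TRUE)) {
    a <- sample(1:3, 40, replace = TRUE); b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }

  labs <- c("a", "a", "a", "a", "b", "b")
  cls <- c("a", "a", "b", "b", "a", "a")
  # |c| = 4, |d| = 4, overlap 2 -> 2/6
  expect_equal(jaccard(labs, cls, "a"), 2 / 6)
  expect_equal(jaccard(labs, labs, "a"), 1)
  expect_equal(jaccard(labs, rep("b", 6), "a"), 0)
  expect_error(jaccard(labs, cls, "z"), "absent")
})

test_that("pseudotime order accuracy counts correctly ordered pairs", {
  lev <- c(1, 2, 3, 3, 4, 5)
  lin <- cbind(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(pseudotime_order_accuracy(lev, lev, lin), 1)
  expect_equal(pseudotime_order_accuracy(-lev, lev, lin), 0)
  set.seed(3)
  pt <- rnorm(6)
  # brute-force pair enumeration
  correct <- 0; elig <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    if (lev[i] != lev[j] && any(lin[i, ] & lin[j, ])) {
      elig <- elig + 1
      hi <- if (lev[i] > lev[j]) i else j
      lo <- if (lev[i] > lev[j]) j else i
      if (pt[hi] > pt[lo]) correct <- correct + 1
    }
  }
  expect_equal(pseudotime_order_accuracy(pt, lev, lin), correct / elig)
  expect_error(pseudotime_order_accuracy(1:3, c(1, 1, 1), diag(3) > 0),
               "eligible")
})

test_that("the evaluation report summarizes recovery in both directions", {
  set.seed(40)
  sim <- simulate_counts(sim_config(n_cells = 120, n_genes = 40, seed = 41))
  ds <- downsample_reads(sim$counts, 0.5, seed = 42)
  rep <- evaluate_imputation(sim$counts, ds$observed, sim$counts$counts)
  expect_named(rep, c("metric", "observed", "imputed"))
  # the "imputed" column here is the reference itself: perfect scores
  expect_equal(rep$imputed[rep$metric == "mae_mean"], 0)
  expect_equal(rep$imputed[rep$metric == "gene_correlation_mean"], 1)
  expect_gt(rep$observed[rep$metric == "mae_mean"], 0)
})
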