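random_config <- function(seed, L = 8) {
  set.seed(seed)
  matrix(rnorm(L * 3), L, 3)
}

similarity_copy <- function(m, seed) {
  set.seed(seed)
  qr_R <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_R)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  scale <- runif(1, 0.5, 3)
  shift <- rnorm(3, 0, 5)
  sweep(scale * m %*% R, 2, shift, "+")
}

test_that("procrustes_distance: similarity invariance, symmetry, oracle", {
  a <- random_config(1)
  b <- similarity_copy(a, 2)
  expect_lt(procrustes_distance(a, b), 1e-10)
  c2 <- random_config(3)
  expect_equal(procrustes_distance(a, c2), procrustes_distance(c2, a),
               tolerance = 1e-12)
  expect_gt(procrustes_distance(a, c2), 0)
  expect_error(procrustes_distance(a, random_config(4, L = 5)),
               "landmark counts differ")
  expect_error(procrustes_distance(matrix(1, 4, 3), matrix(2, 4, 3)),
               "degenerate")

  skip_if_not_installed("vegan")
  # pairwise closed-form oracle via vegan's orthogonal Procrustes
  for (i in 1:6) {
    x <- random_config(10 + i); y <- random_config(20 + i)
    cx <- scale(x, scale = FALSE); cx <- cx / sqrt(sum(cx^2))
    cy <- scale(y, scale = FALSE); cy <- cy / sqrt(sum(cy^2))
    vp <- vegan::procrustes(cx, cy, scale = FALSE, symmetric = FALSE)
    expect_equal(procrustes_distance(x, y), sqrt(sum((vp$X - vp$Yrot)^2)),
                 tolerance = 1e-6)
  }
})

test_that("generalized Procrustes aligns and is idempotent", {
  base <- random_config(5)
  lm <- landmark_set(lapply(1:4, function(i) {
    similarity_copy(base + matrix(rnorm(24, 0, 0.01), 8, 3), 100 + i)
  }))
  res <- procrustes_superimpose(lm)
  expect_true(res$aligned$aligned)
  expect_length(res$centroid_size, 4)
  # all aligned shapes are close to the consensus
  for (m in res$aligned$coords)
    expect_lt(sqrt(sum((m - res$mean_shape)^2)), 0.1)
  # idempotence: aligning aligned data barely moves coordinates
  res2 <- procrustes_superimpose(res$aligned)
  for (i in 1:4)
    expect_lt(max(abs(res2$aligned$coords[[i]] - res$aligned$coords[[i]])),
              1e-8)
  expect_error(procrustes_superimpose(landmark_set(list(base))), "at least 2")
})

test_that("flatten_and_normalize shapes, commutation and guards", {
  base <- random_config(6, L = 5)
  lm <- landmark_set(list(s1 = base, s2 = similarity_copy(base, 7)))
  expect_error(flatten_and_normalize(lm), "superimposed")
  al <- procrustes_superimpose(lm)$aligned
  M <- flatten_and_normalize(al)
  expect_equal(dim(M), c(2, 15))
  v <- runif(15, 0.5, 2)
  M1 <- flatten_and_normalize(al, v)
  M2 <- normalize_by_sd(flatten_and_normalize(al), v)
  expect_equal(unclass(M1), unclass(M2), tolerance = 1e-12)
  expect_true(attr(M1, "normalized"))
})

test_that("mds_embed recovers exactly embeddable configurations", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  res <- mds_embed(D, dim = 2, seed = 1)
  expect_lt(res$stress, 1e-6)
  expect_equal(as.matrix(dist(res$points)), D, tolerance = 1e-4,
               ignore_attr = TRUE)
  # stress is monotone non-increasing in target dimension
  res9 <- mds_embed(D, dim = 9, seed = 1)
  expect_lte(res9$stress, res$stress + 1e-9)
  expect_error(mds_embed(D + upper.tri(D) * 0.5, 2, 1), "symmetric")
})

test_that("majorization never increases stress; permutation invariance", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    P <- matrix(rnorm(n * 4), n, 4)
    D <- as.matrix(dist(P))
    res <- mds_embed(D, dim = 2, seed = i, n_starts = 1, max_iter = 80)
    expect_true(all(diff(res$stress_trace) <= 1e-9))
  }
  P <- matrix(rnorm(8 * 3), 8, 3)
  D <- as.matrix(dist(P))
  perm <- sample(8)
  s1 <- mds_embed(D, 2, seed = 4)$stress
  s2 <- mds_embed(D[perm, perm], 2, seed = 4)$stress
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("separated landmark clusters stay separated in the 2-D map", {
  set.seed(10)
  base1 <- random_config(11); base2 <- random_config(12) * 2
  specs <- c(lapply(1:5, function(i) base1 + matrix(rnorm(24, 0, .02), 8, 3)),
             lapply(1:5, function(i) base2 + matrix(rnorm(24, 0, .02), 8, 3)))
  al <- procrustes_superimpose(landmark_set(specs))$aligned
  M <- flatten_and_normalize(al)
  D <- as.matrix(dist(unclass(M)))
  pts <- mds_embed(D, 2, seed = 2)$points
  lab <- rep(1:2, each = 5)
  # silhouette-style check: mean within-cluster map distance is smaller
  # than mean between-cluster distance
  dm <- as.matrix(dist(pts))
  within <- mean(dm[lab[row(dm)] == lab[col(dm)] & row(dm) != col(dm)])
  between <- mean(dm[lab[row(dm)] != lab[col(dm)]])
  expect_gt(between, within)
})
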