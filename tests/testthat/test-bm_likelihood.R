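test_that("build_sigma arithmetic and the unit-rate identity", {
  rho <- rbind(c(1, 0.5), c(0.5, 1))
  expect_equal(build_sigma(c(1, 1), rho), rho)       # r = 1 gives Sigma = rho
  expect_equal(build_sigma(c(2, 3), rho), rbind(c(4, 3), c(3, 9)))
  expect_error(build_sigma(c(1, 1), rbind(c(2, 0), c(0, 1))), "unit diagonal")
})

test_that("sigma_from_factor round-trips with build_sigma", {
  expect_equal(sigma_from_factor(diag(2)), diag(2))
  L <- rbind(c(1, 0.5), c(0, 1))
  expect_equal(sigma_from_factor(L), rbind(c(1.25, 0.5), c(0.5, 1)))
  expect_error(sigma_from_factor(rbind(c(1, 0), c(0, 0))), "singular")

  set.seed(4)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    r <- runif(k, 0.5, 2)
    rho <- ridge_shrink(stats::cov2cor(crossprod(matrix(rnorm(4 * k * k), ncol = k))),
                        0.1)
    S <- build_sigma(r, rho)
    # upper-triangular factor with S = U U^T via the reverse-permuted Cholesky
    J <- diag(k)[k:1, ]
    Lu <- J %*% t(chol(J %*% S %*% J)) %*% J
    expect_true(all(abs(Lu[lower.tri(Lu)]) < 1e-12))
    expect_equal(sigma_from_factor(Lu), S, tolerance = 1e-10)
    # recovered parameters
    expect_equal(sqrt(diag(sigma_from_factor(Lu))), r, tolerance = 1e-8)
    # positive definiteness of random factors
    ev <- eigen(sigma_from_factor(Lu), only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("apply_intraspecific increments only own-taxon blocks", {
  V <- diag(4)
  verr <- rbind(c(0.2, 0.1), c(0.1, 0.3))
  expect_equal(apply_intraspecific(V, matrix(0, 2, 2)), V)
  V1 <- apply_intraspecific(diag(2), verr)           # n = 1
  expect_equal(V1, diag(2) + verr)
  V2 <- apply_intraspecific(V, verr)
  expect_equal(V2[1:2, 1:2], diag(2) + verr)
  expect_equal(V2[1:2, 3:4], matrix(0, 2, 2))        # off blocks untouched
  expect_error(apply_intraspecific(diag(3), verr), "dimension mismatch")
})

test_that("normalize_by_sd scales columns and flags the matrix", {
  M <- character_matrix(cbind(c(2, 4)), taxa = c("A", "B"), characters = "c1")
  Ms <- normalize_by_sd(M, 4)
  expect_equal(unname(unclass(Ms)[, 1]), c(1, 2))
  expect_true(attr(Ms, "normalized"))
  expect_equal(unclass(normalize_by_sd(M, 1)), unclass(M),
               ignore_attr = TRUE)
  expect_error(normalize_by_sd(M, 0), "zero variance")
})

test_that("normalized data with verr = rho matches the unnormalized model", {
  # the two parameterizations differ by a constant Jacobian in tree & rates
  for (i in 1:8) {
    tr <- random_fbd_tree(400 + i, lo = 3, hi = 7)
    k <- 2
    rho <- rbind(c(1, 0.4), c(0.4, 1))
    sds <- runif(k, 0.5, 2)
    M <- simulate_bm(tr, bm_params(corr = rho, c_m = 1, y0 = rep(0, k)),
                     seed = i)
    Ms <- normalize_by_sd(M, sds^2)
    diffs <- vapply(1:4, function(j) {
      set.seed(i * 10 + j)
      cm <- exp(rnorm(1, 0, 0.4))
      r <- runif(k, 0.5, 2)
      pA <- bm_params(r = r / sds, corr = rho, c_m = cm, y0 = rep(0, k),
                      v_err = rho)
      pB <- bm_params(r = r, corr = rho, c_m = cm, y0 = rep(0, k),
                      v_err = diag(sds) %*% rho %*% diag(sds))
      dense_loglik(Ms, tr, pA) - dense_loglik(M, tr, pB)
    }, 0)
    expect_lt(max(diffs) - min(diffs), 1e-8)
    expect_equal(mean(diffs), nrow(M) * sum(log(sds)), tolerance = 1e-8)
  }
})

test_that("dense_loglik reproduces closed-form special cases", {
  # single taxon, unit path, sigma = 1, observation at the root value
  phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2), edge.length = 1,
                        tip.label = "A", Nnode = 1L), class = "phylo")
  tr1 <- time_tree(phy)
  M1 <- character_matrix(matrix(0.0, 1, 1, dimnames = list("A", "c1")))
  expect_equal(dense_loglik(M1, tr1, bm_params(corr = diag(1), y0 = 0)),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # star tree: independent normal densities
  star <- parse_tree("(A:1.5,B:1.5,C:1.5);")
  x <- c(0.3, -1, 2)
  M <- character_matrix(matrix(x, 3, dimnames = list(c("A", "B", "C"), "c1")))
  cm <- 0.8
  expect_equal(dense_loglik(M, star, bm_params(corr = diag(1), c_m = cm, y0 = 0.1)),
               sum(dnorm(x, 0.1, sqrt(cm * 1.5), log = TRUE)),
               tolerance = 1e-12)
})

test_that("dense_loglik equals an independently coded Kronecker oracle", {
  for (i in 1:12) {
    tr <- random_fbd_tree(50 + i, lo = 2, hi = 6)
    k <- sample(1:3, 1)
    p <- random_bm_params(i, k, with_verr = i %% 2 == 0)
    M <- simulate_bm(tr, bm_params(L = diag(k), c_m = 1, y0 = rep(0, k)),
                     seed = i)
    d <- tryCatch(dense_loglik(M, tr, p),
                  tedmorph_singular_error = function(e) NULL)
    if (is.null(d)) next
    expect_equal(d, oracle_mvn_loglik(M, tr, p), tolerance = 1e-8)
  }
})

test_that("both pruning algorithms agree with the dense oracle", {
  checked <- 0
  for (i in 1:60) {
    tr <- random_fbd_tree(2024 + i, lo = 2, hi = 8)
    k <- sample(1:4, 1)
    p <- random_bm_params(i + 300, k, with_verr = i %% 3 == 0)
    M <- simulate_bm(tr, bm_params(L = diag(k), c_m = 1, y0 = rep(0, k)),
                     seed = i + 5000)
    d <- tryCatch(dense_loglik(M, tr, p), error = function(e) NULL)
    if (is.null(d)) next                 # exactly observed root state
    f <- pruning_loglik(M, tr, p, algorithm = "felsenstein")
    g <- pruning_loglik(M, tr, p, algorithm = "general")
    expect_equal(f, d, tolerance = 1e-8)
    expect_equal(g, d, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("perfectly correlated duplicate characters raise singular errors", {
  tr <- fixture_tree3()
  rho <- matrix(1, 2, 2)
  M <- character_matrix(cbind(c(1, 2, 3), c(1, 2, 3)),
                        taxa = c("A", "B", "C"), characters = c("a", "b"))
  p <- bm_params(corr = rho, y0 = c(0, 0))
  expect_error(pruning_loglik(M, tr, p), class = "tedmorph_singular_error")
  expect_error(pruning_loglik(M, tr, p, algorithm = "general"),
               class = "tedmorph_singular_error")
  expect_error(dense_loglik(M, tr, p), class = "tedmorph_singular_error")
})

test_that("ml_root_values matches trivial cases and the GLS oracle", {
  star <- parse_tree("(A:2,B:2,C:2);")
  M <- character_matrix(cbind(c(1, 2, 6), c(0, 3, 3)),
                        taxa = c("A", "B", "C"), characters = c("a", "b"))
  p <- bm_params(corr = diag(2), y0 = "ML")
  expect_equal(unname(ml_root_values(M, star, p)), c(3, 2))

  for (i in 1:8) {
    tr <- random_fbd_tree(777 + i, lo = 3, hi = 7)
    if (min(diag(phylo_vcv(tr))) == 0) next   # root state observed exactly
    k <- 2
    p <- random_bm_params(i, k, y0 = "ML")
    p$y0 <- "ML"
    M <- simulate_bm(tr, bm_params(L = diag(k), c_m = 1, y0 = rep(0, k)),
                     seed = i + 40)
    labs <- taxa_labels(tr)
    Tm <- phylo_vcv(tr, p$c_m)
    Ti <- solve(Tm)
    one <- rep(1, nrow(Tm))
    gls <- as.vector((t(one) %*% Ti %*% unclass(M)[labs, ]) /
                       as.numeric(t(one) %*% Ti %*% one))
    expect_equal(unname(ml_root_values(M, tr, p)), gls, tolerance = 1e-8)
    # profile property: ML root values maximize the likelihood
    base <- dense_loglik(M, tr, p)
    y0hat <- ml_root_values(M, tr, p)
    set.seed(i)
    for (j in 1:10) {
      p2 <- p
      p2$y0 <- y0hat + rnorm(k, 0, 0.3)
      expect_lte(dense_loglik(M, tr, p2), base + 1e-10)
    }
  }
})

test_that("likelihood obeys the Gaussian scaling identity", {
  for (i in 1:6) {
    tr <- random_fbd_tree(600 + i, lo = 3, hi = 7)
    k <- 2
    # skip trees whose root state is observed exactly (a sampled ancestor at
    # the root): the delta factor does not scale like a density
    if (min(diag(phylo_vcv(tr))) == 0) next
    rho <- rbind(c(1, 0.3), c(0.3, 1))
    y0 <- c(0.5, -0.5)
    M <- simulate_bm(tr, bm_params(corr = rho, c_m = 1, y0 = y0), seed = i)
    a <- 2.7
    p1 <- bm_params(corr = rho, c_m = 1, y0 = y0)
    p2 <- bm_params(corr = rho, c_m = a, y0 = y0)
    Ma <- character_matrix(
      sweep(sweep(unclass(M), 2, y0), 2, rep(sqrt(a), k), "*") +
        matrix(y0, nrow(M), k, byrow = TRUE),
      taxa = rownames(M))
    n <- nrow(M)
    expect_equal(pruning_loglik(Ma, tr, p2) - pruning_loglik(M, tr, p1),
                 -(n * k / 2) * log(a), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to taxon reordering", {
  tr <- random_fbd_tree(222, lo = 4, hi = 8)
  k <- 3
  p <- random_bm_params(5, k)
  M <- simulate_bm(tr, bm_params(L = diag(k), c_m = 1, y0 = rep(0, k)),
                   seed = 77)
  perm <- sample(nrow(M))
  M2 <- character_matrix(unclass(M)[perm, ], taxa = rownames(M)[perm])
  expect_equal(pruning_loglik(M2, tr, p), pruning_loglik(M, tr, p),
               tolerance = 1e-10)
})
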