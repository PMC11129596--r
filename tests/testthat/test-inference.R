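test_that("hpd_interval equals the exhaustive shortest-window oracle", {
  expect_equal(diff(hpd_interval(1:100, 0.95)), 94)
  expect_equal(hpd_interval(rep(3.2, 50), 0.95), c(3.2, 3.2))
  set.seed(1)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    x <- switch(i %% 3 + 1, rnorm(n), rexp(n), rt(n, 3))
    lv <- runif(1, 0.5, 0.99)
    expect_identical(hpd_interval(x, lv), oracle_hpd(x, lv))
  }
  # symmetric unimodal: interval brackets the median
  set.seed(2)
  x <- rnorm(2000)
  h <- hpd_interval(x, 0.95)
  expect_lt(h[1], median(x)); expect_gt(h[2], median(x))
  expect_error(hpd_interval(numeric(0)), "empty")
})

test_that("ess behaves like an effective sample size", {
  set.seed(3)
  x <- rnorm(1000)
  e <- ess(x)
  expect_gt(e, 800); expect_lt(e, 1200)
  expect_equal(ess(rep(3.7, 100)), 1)    # repeated value: no information
  # strongly autocorrelated AR(1): far below N, and never above N
  z <- as.numeric(arima.sim(list(ar = 0.95), 1000))
  expect_lt(ess(z), 300)
  for (i in 1:5) expect_lte(ess(rnorm(200)), 200)
  expect_error(ess(1:5), "at least 10")
})

test_that("log_posterior is the sum of its separately computed factors", {
  set.seed(4)
  for (i in 1:15) {
    tr <- random_fbd_tree(6000 + i, lo = 3, hi = 8)
    k <- 2
    bm <- random_bm_params(i, k)
    ep <- episode_params(exp(rnorm(1, 0, .2)), runif(1, 0, .4),
                         runif(1, .2, .8), 1, origin_time = tr$origin_time)
    M <- simulate_bm(tr, bm_params(corr = diag(k), y0 = rep(0, k)), seed = i)
    pri <- prior_spec(c_m = prior_lognormal(0, 1),
                      lambda = prior_lognormal(0, .5), mu = prior_fixed(ep$mu),
                      psi = prior_fixed(ep$psi), p_extant = prior_fixed(1),
                      origin_time = prior_fixed(tr$origin_time))
    # the posterior's likelihood factor diffuses the trait process from the
    # origin, so the oracle must use the same root edge
    pl <- tryCatch(pruning_loglik(M, tr, bm,
                                  root_edge_time = tr$origin_time -
                                    root_age(tr)),
                   tedmorph_singular_error = function(e) -Inf)
    lp <- fbd_log_density(tr, ep) + dlnorm(bm$c_m, 0, 1, log = TRUE) +
      dlnorm(ep$lambda, 0, .5, log = TRUE)
    got <- log_posterior(list(tree = tr, bm = bm, episode = ep), M, pri)
    expect_equal(got, pl + lp, tolerance = 1e-10)
    # empty data: prior only
    expect_equal(log_posterior(list(tree = tr, bm = bm, episode = ep),
                               NULL, pri), lp, tolerance = 1e-10)
  }
  # -Inf propagates from any factor
  tr <- parse_tree("((A:1.0,F:0.5):1.0,C:2.0);")
  tr$origin_time <- 3
  ep0 <- episode_params(1, 0.1, 0, origin_time = 3)   # fossils need psi > 0
  bm <- bm_params(corr = diag(1), y0 = 0)
  M <- character_matrix(matrix(0, 3, 1, dimnames = list(c("A", "F", "C"), "c")))
  expect_identical(log_posterior(list(tree = tr, bm = bm, episode = ep0),
                                 M, prior_spec(origin_time = prior_fixed(3))),
                   -Inf)
})

test_that("run_chain is deterministic and reports sane acceptance", {
  tr <- random_fbd_tree(111, lo = 4, hi = 9)
  k <- 2
  bm <- bm_params(corr = diag(k), c_m = 1, y0 = rep(0, k))
  M <- simulate_bm(tr, bm, seed = 2)
  ep <- episode_params(1, 0.3, 0.6, origin_time = tr$origin_time)
  pri <- prior_spec(c_m = prior_lognormal(0, 0.5),
                    lambda = prior_fixed(1), mu = prior_fixed(0.3),
                    psi = prior_fixed(0.6), p_extant = prior_fixed(1),
                    origin_time = prior_fixed(tr$origin_time))
  t1 <- run_chain(M, tr, pri, chain_length = 2000, sample_every = 10,
                  seed = 42, init_bm = bm, init_episode = ep,
                  debug_check_every = 500)
  t2 <- run_chain(M, tr, pri, chain_length = 2000, sample_every = 10,
                  seed = 42, init_bm = bm, init_episode = ep)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$trees, t2$trees)
  acc <- t1$config$acceptance$c_m
  expect_gt(acc, 0); expect_lt(acc, 1)
  expect_true(all(c("sa_count", "root_age", "c_m") %in% names(t1$samples)))
  # chain mean of the lone free scalar stabilizes near its conditional mass
  s <- trace_burnin(t1)$samples$c_m
  expect_true(is.finite(mean(s)) && sd(s) > 0)
})

test_that("prior-only chains recover the prior of c_m", {
  tr <- random_fbd_tree(313, lo = 4, hi = 8)
  ep <- episode_params(1, 0.3, 0.6, origin_time = tr$origin_time)
  pri <- prior_spec(c_m = prior_lognormal(-0.3, 0.6),
                    lambda = prior_fixed(1), mu = prior_fixed(0.3),
                    psi = prior_fixed(0.6), p_extant = prior_fixed(1),
                    origin_time = prior_fixed(tr$origin_time))
  tm <- run_chain(NULL, tr, pri, chain_length = 60000, sample_every = 20,
                  seed = 8, init_episode = ep, store_trees = FALSE)
  s <- trace_burnin(tm)$samples$c_m
  mom <- tedmorph:::prior_moments(prior_lognormal(-0.3, 0.6))
  e <- ess(s)
  se_mean <- sqrt(mom$var / e)
  expect_lt(abs(mean(s) - mom$mean), 3 * se_mean)
  # 95% quantiles within Monte-Carlo error of the prior quantiles
  qs <- quantile(s, c(0.025, 0.975))
  qt <- qlnorm(c(0.025, 0.975), -0.3, 0.6)
  expect_lt(abs(qs[1] - qt[1]) / qt[1], 0.2)
  expect_lt(abs(qs[2] - qt[2]) / qt[2], 0.2)
})

test_that("constraints and fixed extant topologies are enforced", {
  tr <- random_fbd_tree(515, lo = 6, hi = 12,
                        ep = episode_params(1.4, 0.2, 0.5, origin_time = 2))
  k <- 2
  bm <- bm_params(corr = diag(k), c_m = 1, y0 = rep(0, k))
  M <- simulate_bm(tr, bm, seed = 3)
  ep <- episode_params(1.4, 0.2, 0.5, origin_time = tr$origin_time)
  pri <- prior_spec(c_m = prior_lognormal(0, 0.5), lambda = prior_fixed(1.4),
                    mu = prior_fixed(0.2), psi = prior_fixed(0.5),
                    p_extant = prior_fixed(1),
                    origin_time = prior_fixed(tr$origin_time))
  tm <- run_chain(M, tr, pri, chain_length = 3000, sample_every = 20,
                  seed = 11, init_bm = bm, init_episode = ep,
                  fix_extant_topology = TRUE)
  ext <- names(tip_ages(tr))[tip_ages(tr) == 0]
  sig0 <- extant_signature(prune_taxa(tr, setdiff(names(tip_ages(tr)), ext)))
  for (s in tm$trees) {
    tt <- parse_tree(s)
    ptt <- prune_taxa(tt, setdiff(names(tip_ages(tt)), ext))
    expect_identical(extant_signature(ptt), sig0)
  }
})

test_that("coverage_study handles the empty and miscalibrated cases", {
  expect_equal(nrow(coverage_study(0, seed = 1)), 0)
  # a deliberately wrong, over-tight prior must undercover
  bad <- coverage_study(
    8, seed = 99,
    chain_config = list(chain_length = 4000, sample_every = 10, burnin = 0.1),
    infer_priors = NULL)
  wrong <- prior_spec(c_m = prior_lognormal(log(25), 0.05))
  # reuse simulation priors but infer under the wrong c_m prior
  mis <- coverage_study(
    8, seed = 99,
    chain_config = list(chain_length = 4000, sample_every = 10, burnin = 0.1),
    infer_priors = wrong)
  tabw <- attr(mis, "replicates")
  expect_lt(sum(tabw$c_m_cover, na.rm = TRUE), 3)
  expect_true(all(c("parameter", "coverage", "n_used") %in% names(bad)))
})

test_that("accuracy improves with more characters under the true model", {
  tr <- random_fbd_tree(717, lo = 8, hi = 16,
                        ep = episode_params(1.4, 0.2, 0.5, origin_time = 2))
  base <- list(tree = tr, rho_true = 0, rho_assumed = 0, w = 1,
               fossil_subset = "all",
               rate_prior = prior_lognormal(0, 0.1), y0 = 0,
               lambda = 1.4, mu = 0.2, psi = 0.5,
               origin_time = tr$origin_time)
  cfg <- list(chain_length = 3000, sample_every = 10, burnin = 0.1)
  s1 <- accuracy_study(c(base, n_chars = 1), n_reps = 4, seed = 21,
                       chain_config = cfg)
  s8 <- accuracy_study(c(base, n_chars = 8), n_reps = 4, seed = 21,
                       chain_config = cfg)
  expect_lte(mean(s8$node_abs_err), mean(s1$node_abs_err) * 1.15)
  expect_lte(mean(s8$node_hpd_width), mean(s1$node_hpd_width) * 1.15)
  expect_true(all(is.finite(s1$root_pct_err)))
})

test_that("mcc_tree summarizes posterior tree samples from a chain", {
  tr <- random_fbd_tree(919, lo = 4, hi = 7)
  ep <- episode_params(1, 0.3, 0.6, origin_time = tr$origin_time)
  pri <- prior_spec(lambda = prior_fixed(1), mu = prior_fixed(0.3),
                    psi = prior_fixed(0.6), p_extant = prior_fixed(1),
                    origin_time = prior_fixed(tr$origin_time))
  tm <- run_chain(NULL, tr, pri, chain_length = 4000, sample_every = 40,
                  seed = 5, init_episode = ep)
  trees <- lapply(tm$trees, parse_tree)
  res <- mcc_tree(trees, burnin_fraction = 0.1)
  expect_s3_class(res$tree, "time_tree")
  expect_true(all(res$clade_support$support > 0 &
                    res$clade_support$support <= 1))
})
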