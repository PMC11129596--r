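#' Well-calibrated coverage study
#'
#' Simulation-based calibration of the restricted integrative model. For
#' each replicate: draw the focal evolutionary rate `c_m`, the
#' tree-process rates, the factor elements of the among-character
#' covariance and the root values from their priors; simulate an FBD tree
#' and correlated Brownian characters at its tips; run MCMC under the
#' identical model (the focal `c_m` sampled under its simulation prior,
#' nuisance parameters conditioned on their drawn true values, the tree
#' co-estimated); and record whether each credibility interval contains
#' the truth. A correct implementation yields coverage near the nominal
#' level; replicates whose focal-parameter ESS falls below `ess_min` are
#' excluded and reported.
#'
#' @param n_reps Number of replicates.
#' @param sim_config List of simulation settings; see
#'   [coverage_sim_config()] for the defaults (the reduced study-I-like
#'   world: FBD trees of around ten samples, four correlated characters,
#'   strict clock).
#' @param chain_config List with `chain_length`, `sample_every`, `burnin`.
#' @param seed Integer master seed; all per-replicate seeds derive from it.
#' @param infer_priors Optional [prior_spec] used in *inference* instead of
#'   the simulation priors (for miscalibration controls); calibration holds
#'   only when it is `NULL`, i.e. priors match.
#' @param level Credibility level of the HPD intervals.
#' @param ess_min Convergence threshold on the focal-parameter ESS.
#' @return A data frame with one row per monitored parameter (`c_m`,
#'   `root_age`): replicates used, excluded, coverage count and proportion,
#'   mean bias. The per-replicate table is attached as attribute
#'   `"replicates"`.
#' @export
coverage_study <- function(n_reps, sim_config = coverage_sim_config(),
                           chain_config = list(chain_length = 40000,
                                               sample_every = 20,
                                               burnin = 0.1),
                           seed, infer_priors = NULL, level = 0.95,
                           ess_min = 200) {
  if (n_reps == 0) {
    out <- data.frame(parameter = character(0), n_used = integer(0),
                      n_excluded = integer(0), coverage = integer(0),
                      proportion = numeric(0), mean_bias = numeric(0))
    return(out)
  }
  set.seed(as.integer(seed))
  rs <- matrix(sample.int(.Machine$integer.max - 1, 3 * n_reps), ncol = 3)
  cfg <- sim_config
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rs[r, 1])
    c_m_true <- prior_draw(cfg$priors$c_m)
    lambda <- prior_draw(cfg$priors$lambda)
    mu <- prior_draw(cfg$priors$mu)
    psi <- prior_draw(cfg$priors$psi)
    p_ext <- prior_draw(cfg$priors$p_extant)
    Ltrue <- draw_L(cfg$k, cfg$L_diag, cfg$L_offdiag)
    y0true <- prior_draw(cfg$y0, cfg$k)
    ep <- episode_params(lambda, mu, psi, p_ext,
                         origin_time = cfg$origin_time)
    # redraw the tree until it carries between 2 and max_taxa samples;
    # the event is a function of the observed tip configuration, which the
    # MCMC conditions on, so calibration is unaffected
    tr <- NULL
    for (attempt in seq_len(100)) {
      cand <- tryCatch(
        simulate_fbd(ep, seed = (rs[r, 2] + attempt) %% 2147483646L,
                     max_tries = 200),
        error = function(e) NULL)
      if (!is.null(cand) && n_taxa(cand) >= 2 && n_taxa(cand) <= cfg$max_taxa) {
        tr <- cand
        break
      }
    }
    if (is.null(tr)) {
      reps[[r]] <- data.frame(rep = r, status = "skipped_tree",
                              c_m_true = c_m_true, root_true = NA,
                              ess = NA, c_m_cover = NA, root_cover = NA,
                              c_m_bias = NA, root_bias = NA)
      next
    }
    bm_true <- bm_params(L = Ltrue, c_m = c_m_true, y0 = y0true)
    M <- simulate_bm(tr, bm_true, seed = rs[r, 3],
                     root_edge_time = tr$origin_time - root_age(tr))
    pri <- prior_spec(c_m = cfg$priors$c_m,
                      lambda = prior_fixed(lambda), mu = prior_fixed(mu),
                      psi = prior_fixed(psi), p_extant = prior_fixed(p_ext),
                      origin_time = prior_fixed(cfg$origin_time),
                      tree_model = "fbd")
    if (!is.null(infer_priors)) pri <- infer_priors
    # weight the sampled-ancestor, exchange and rate-height moves up: the
    # slow posterior component is the fossil-attachment configuration
    mv <- default_moves()
    mv$weight[mv$move %in% c("sa_toggle", "exchange", "rate_height",
                             "fossil_reattach")] <- 8
    trace <- run_chain(M, tr, pri, moves = mv,
                       chain_length = chain_config$chain_length,
                       sample_every = chain_config$sample_every,
                       seed = rs[r, 1],
                       init_bm = bm_true, init_episode = ep,
                       store_trees = FALSE)
    trace <- trace_burnin(trace, chain_config$burnin %||% 0.1)
    s <- trace$samples
    e <- ess(s$c_m)
    if (e < ess_min) {
      # one extension attempt with a three-fold longer chain
      trace <- run_chain(M, tr, pri, moves = mv,
                         chain_length = 3 * chain_config$chain_length,
                         sample_every = 3 * chain_config$sample_every,
                         seed = (rs[r, 1] + 1) %% 2147483646L,
                         init_bm = bm_true, init_episode = ep,
                         store_trees = FALSE)
      trace <- trace_burnin(trace, chain_config$burnin %||% 0.1)
      s <- trace$samples
      e <- ess(s$c_m)
    }
    h_cm <- hpd_interval(s$c_m, level)
    h_root <- hpd_interval(s$root_age, level)
    reps[[r]] <- data.frame(
      rep = r,
      status = if (e >= ess_min) "ok" else "low_ess",
      c_m_true = c_m_true, root_true = root_age(tr), ess = e,
      c_m_cover = h_cm[1] <= c_m_true && c_m_true <= h_cm[2],
      root_cover = h_root[1] <= root_age(tr) && root_age(tr) <= h_root[2],
      c_m_bias = mean(s$c_m) - c_m_true,
      root_bias = mean(s$root_age) - root_age(tr))
  }
  tab <- do.call(rbind, reps)
  used <- tab$status == "ok"
  out <- data.frame(
    parameter = c("c_m", "root_age"),
    n_used = sum(used),
    n_excluded = sum(!used),
    coverage = c(sum(tab$c_m_cover[used]), sum(tab$root_cover[used])),
    proportion = c(mean(tab$c_m_cover[used]), mean(tab$root_cover[used])),
    mean_bias = c(mean(tab$c_m_bias[used]), mean(tab$root_bias[used])))
  attr(out, "replicates") <- tab
  out
}

#' Default simulation configuration for the coverage study
#'
#' The stated desk-scale world for calibration: FBD trees started from a
#' single lineage 2 time units before present (speciation around 1,
#' moderate extinction and fossilization, complete extant sampling), four
#' correlated characters whose covariance factor has log-normal diagonal
#' and truncated-normal off-diagonal elements, root values standard
#' normal, and a log-normal prior on the focal rate `c_m`.
#'
#' @param k Number of characters.
#' @return A list consumed by [coverage_study()].
#' @export
coverage_sim_config <- function(k = 4) {
  list(
    k = k,
    priors = prior_spec(
      c_m = prior_lognormal(0, 0.5),
      lambda = prior_lognormal(log(1), 0.15),
      mu = prior_lognormal(log(0.3), 0.3),
      psi = prior_lognormal(log(0.7), 0.3),
      p_extant = prior_fixed(1),
      origin_time = prior_fixed(2)),
    L_diag = prior_lognormal(0, 0.1),
    L_offdiag = prior_truncnormal(0.5, 0.5, -1, 1),
    y0 = prior_normal(0, 1),
    origin_time = 2,
    max_taxa = 16)
}

draw_L <- function(k, diag_prior, offdiag_prior) {
  L <- matrix(0, k, k)
  diag(L) <- prior_draw(diag_prior, k)
  if (k > 1) L[upper.tri(L)] <- prior_draw(offdiag_prior, k * (k - 1) / 2)
  L
}

#' Accuracy and precision of divergence-time estimates
#'
#' Desk-scale replication of the accuracy experiments: repeated simulation
#' and inference under configurable data features (character count, true
#' vs. assumed correlation, white-noise admixture `w`, fossil subsets by
#' age), with the extant subtopology fixed to the simulated truth and
#' fossil lineages pruned before node ages are compared. Accuracy is the
#' absolute difference between true and posterior-mean node ages (reported
#' for the root as a percentage of the true value); precision is the width
#' of the HPD interval.
#'
#' @param scenario A list: `tree` (fixed [time_tree] with fossils),
#'   `n_chars`, `rho_true`, `rho_assumed`, `w` (Brownian weight, 1 = pure
#'   BM), `fossil_subset` (`"all"`, `"oldest"`, `"youngest"`, `"none"`),
#'   `rate_prior` (log-normal prior shared by simulation and inference),
#'   `y0` (root values), `origin_time`.
#' @param n_reps Replicates.
#' @param seed Integer seed.
#' @param chain_config As in [coverage_study()].
#' @param level HPD level.
#' @return Data frame with one row per replicate: root-age error (absolute
#'   and percent), mean internal-node error, root HPD width, mean node HPD
#'   width, ESS of the rate.
#' @export
accuracy_study <- function(scenario, n_reps, seed,
                           chain_config = list(chain_length = 6000,
                                               sample_every = 10,
                                               burnin = 0.1),
                           level = 0.95) {
  set.seed(as.integer(seed))
  rs <- matrix(sample.int(.Machine$integer.max - 1, 3 * n_reps), ncol = 3)
  sc <- scenario
  k <- sc$n_chars
  rho_t <- matrix(sc$rho_true, k, k); diag(rho_t) <- 1
  rho_a <- matrix(sc$rho_assumed, k, k); diag(rho_a) <- 1
  tr_full <- sc$tree
  tr_used <- subset_fossils(tr_full, sc$fossil_subset %||% "all")
  y0 <- rep_len(sc$y0 %||% 0, k)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rate <- prior_draw(sc$rate_prior)
    bm_t <- bm_params(corr = rho_t, c_m = rate, y0 = y0)
    x0 <- sc$origin_time %||% (root_age(tr_used) * 1.2)
    M_BM <- simulate_bm(tr_used, bm_t, seed = rs[r, 1],
                        root_edge_time = x0 - root_age(tr_used))
    w <- sc$w %||% 1
    if (w < 1) {
      tipvar <- mean(diag(phylo_vcv(tr_used, rate)))
      M_WN <- simulate_wn(rownames(M_BM), k, mean = y0, variance = tipvar,
                          corr = rho_t, seed = rs[r, 2])
      M <- blend(M_WN, M_BM, w)
    } else M <- M_BM
    pri <- prior_spec(c_m = sc$rate_prior,
                      lambda = prior_fixed(sc$lambda %||% 1),
                      mu = prior_fixed(sc$mu %||% 0.3),
                      psi = prior_fixed(sc$psi %||% 0.5),
                      p_extant = prior_fixed(1),
                      origin_time = prior_fixed(sc$origin_time %||%
                                                  (root_age(tr_used) * 1.2)))
    bm_a <- bm_params(corr = rho_a, c_m = rate, y0 = y0)
    trace <- run_chain(M, tr_used, pri,
                       chain_length = chain_config$chain_length,
                       sample_every = chain_config$sample_every,
                       seed = rs[r, 3], init_bm = bm_a,
                       init_episode = episode_params(
                         sc$lambda %||% 1, sc$mu %||% 0.3, sc$psi %||% 0.5,
                         1, origin_time = sc$origin_time %||%
                           (root_age(tr_used) * 1.2)),
                       fix_extant_topology = TRUE, store_trees = TRUE)
    trace <- trace_burnin(trace, chain_config$burnin %||% 0.1)
    met <- node_age_metrics(trace, tr_used, level)
    out[[r]] <- data.frame(rep = r, rate_true = rate,
                           root_true = root_age(tr_used),
                           root_abs_err = met$root_abs_err,
                           root_pct_err = met$root_pct_err,
                           node_abs_err = met$node_abs_err,
                           root_hpd_width = met$root_hpd_width,
                           node_hpd_width = met$node_hpd_width,
                           ess_rate = ess(trace$samples$c_m))
  }
  do.call(rbind, out)
}

# keep the oldest/youngest half of fossil tips (sampled ancestors are kept
# with "all"); "none" removes every fossil sample that can be removed
subset_fossils <- function(tree, which = c("all", "oldest", "youngest", "none")) {
  which <- match.arg(which)
  if (which == "all") return(tree)
  ages <- tip_ages(tree)
  fossil <- names(ages)[ages > 0]
  if (length(fossil) == 0) return(tree)
  drop <- switch(which,
    none = fossil,
    oldest = fossil[order(ages[fossil])][seq_len(floor(length(fossil) / 2))],
    youngest = fossil[order(-ages[fossil])][seq_len(floor(length(fossil) / 2))])
  # note: "oldest" KEEPS the oldest half (drops the youngest half)
  if (length(drop) == 0) return(tree)
  prune_taxa(tree, drop)
}

# posterior node-age metrics on fossil-pruned trees, clades keyed by
# extant descendant sets (valid under a fixed extant subtopology)
node_age_metrics <- function(trace, true_tree, level = 0.95) {
  ext <- names(tip_ages(true_tree))[tip_ages(true_tree) == 0]
  truth <- prune_taxa(true_tree, setdiff(names(tip_ages(true_tree)), ext))
  tkeys <- clade_age_table(truth)
  root_key <- tkeys$key[which.max(tkeys$age)]
  ages_by_key <- lapply(tkeys$key, function(k2) numeric(0))
  names(ages_by_key) <- tkeys$key
  for (i in seq_along(trace$trees)) {
    tt <- parse_tree(trace$trees[i])
    ptt <- prune_taxa(tt, setdiff(names(tip_ages(tt)), ext))
    ka <- clade_age_table(ptt)
    m <- match(names(ages_by_key), ka$key)
    for (j in seq_along(m)) if (!is.na(m[j]))
      ages_by_key[[j]] <- c(ages_by_key[[j]], ka$age[m[j]])
  }
  post_mean <- vapply(ages_by_key, mean, 0)
  widths <- vapply(ages_by_key, function(a)
    diff(hpd_interval(a, level)), 0)
  err <- abs(post_mean - tkeys$age)
  is_root <- tkeys$key == root_key
  list(root_abs_err = err[is_root],
       root_pct_err = 100 * err[is_root] / tkeys$age[is_root],
       node_abs_err = mean(err[!is_root]),
       root_hpd_width = widths[is_root],
       node_hpd_width = mean(widths[!is_root]))
}

clade_age_table <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  sets <- clade_tip_sets(phy)
  int <- (ntip + 1L):(ntip + phy$Nnode)
  data.frame(
    key = vapply(int, function(u)
      paste(sort(phy$tip.label[sets[[u]]]), collapse = "|"), ""),
    age = tree$ages[int], stringsAsFactors = FALSE)
}
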