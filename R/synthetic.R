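#' Simulate correlated Brownian characters on a time tree
#'
#' Draws tip values from the generative direction of the phylogenetic
#' Brownian model: the root starts at `y0`, each branch adds a multivariate
#' normal increment with covariance `c_m * b * length * Sigma`, and each
#' observation (tips and sampled ancestors, which observe internal states
#' through their zero-length attachment) optionally adds intraspecific
#' noise with covariance `v_err`. The joint tip distribution is
#' `MVN(y0 (x) 1, Sigma (x) T + I (x) v_err)`.
#'
#' @param tree A [time_tree].
#' @param params A [bm_params] with numeric `y0` (the root state must be
#'   given to simulate).
#' @param seed Integer seed.
#' @param root_edge_time Extra diffusion time before the root (see
#'   [pruning_loglik()]); the root state is drawn from
#'   `N(y0, root_edge_time * c_m * Sigma)`.
#' @return A [character_matrix] (taxa in canonical order).
#' @export
simulate_bm <- function(tree, params, seed, root_edge_time = 0) {
  if (identical(params$y0, "ML"))
    stop("numeric root values y0 are required for simulation")
  set.seed(as.integer(seed))
  k <- params$k
  CS <- tryCatch(chol(params$Sigma), error = function(e) NULL)
  if (is.null(CS)) stop_singular()
  phy <- tree$phy
  nnode <- length(tree$ages)
  state <- matrix(NA_real_, nnode, k)
  root <- n_taxa(tree) + 1L
  state[root, ] <- params$y0 +
    if (root_edge_time > 0)
      sqrt(root_edge_time * params$c_m) * drop(stats::rnorm(k) %*% CS) else 0
  eo <- ape::reorder.phylo(phy, "cladewise")
  wl <- (tree$ages[eo$edge[, 1]] - tree$ages[eo$edge[, 2]]) *
    tree$rates[eo$edge[, 2]] * params$c_m
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    state[ch, ] <- state[p, ] +
      if (wl[i] > 0) sqrt(wl[i]) * drop(stats::rnorm(k) %*% CS) else 0
  }
  labs <- taxa_labels(tree)
  X <- state[match(labs, phy$tip.label), , drop = FALSE]
  if (any(params$v_err != 0)) {
    CE <- suppressWarnings(chol(params$v_err, pivot = TRUE))
    CE <- CE[, order(attr(CE, "pivot")), drop = FALSE]
    X <- X + matrix(stats::rnorm(nrow(X) * k), nrow(X), k) %*% CE
  }
  character_matrix(X, taxa = labs,
                   characters = paste0("c", seq_len(k)))
}

#' Simulate white-noise (tree-free) characters
#'
#' Each taxon's row is an independent draw from
#' `MVN(mean, diag(sqrt(variance)) corr diag(sqrt(variance)))`; the tree
#' topology plays no role.
#'
#' @param labels Taxon labels.
#' @param k Number of characters.
#' @param mean Numeric mean vector (recycled to length `k`).
#' @param variance Positive per-character variances (recycled).
#' @param corr Correlation matrix (default identity).
#' @param seed Integer seed.
#' @return A [character_matrix].
#' @export
simulate_wn <- function(labels, k, mean = 0, variance = 1, corr = diag(k),
                        seed) {
  set.seed(as.integer(seed))
  mean <- rep_len(mean, k)
  variance <- rep_len(variance, k)
  if (any(variance <= 0)) stop("white-noise variances must be > 0")
  Sg <- diag(sqrt(variance), k) %*% as.matrix(corr) %*% diag(sqrt(variance), k)
  C <- chol((Sg + t(Sg)) / 2)
  n <- length(labels)
  X <- matrix(stats::rnorm(n * k), n, k) %*% C +
    matrix(mean, n, k, byrow = TRUE)
  character_matrix(X, taxa = labels, characters = paste0("c", seq_len(k)))
}

#' Mix white-noise and Brownian character matrices
#'
#' Elementwise convex combination `M = (1 - w) * M_WN + w * M_BM`; `w = 1`
#' returns the purely phylogenetic matrix (perfect model fit), `w = 0` the
#' purely tree-free one.
#'
#' @param M_WN,M_BM [character_matrix] objects of identical shape and taxon
#'   order.
#' @param w Mixture weight in `[0, 1]`.
#' @return A [character_matrix].
#' @export
blend <- function(M_WN, M_BM, w) {
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1)
    stop("`w` must be a single weight in [0, 1]")
  if (!identical(dim(M_WN), dim(M_BM)) ||
      !identical(rownames(M_WN), rownames(M_BM)))
    stop("shape/taxon mismatch between the two matrices")
  character_matrix((1 - w) * unclass(M_WN) + w * unclass(M_BM),
                   taxa = rownames(M_BM), characters = colnames(M_BM))
}

#' Simulate within-species replicate measurements
#'
#' For every species (row of `species_means`), draws `m` individuals from
#' `MVN(mean, diag(sigma) corr diag(sigma))` — the generative direction of
#' the intraspecific tip-error model.
#'
#' @param species_means A [character_matrix] of species mean values.
#' @param sigma Non-negative per-character intraspecific SDs (recycled).
#' @param corr Correlation matrix (default identity).
#' @param m Number of individuals per species, `>= 2`.
#' @param seed Integer seed.
#' @return Named list of [replicate_table] objects, one per species.
#' @export
simulate_individuals <- function(species_means, sigma, corr = NULL, m, seed) {
  if (m < 2) stop("`m` must be at least 2")
  set.seed(as.integer(seed))
  k <- ncol(species_means)
  sigma <- rep_len(as.numeric(sigma), k)
  if (any(sigma < 0)) stop("`sigma` must be >= 0")
  if (is.null(corr)) corr <- diag(k)
  Sg <- diag(sigma, k) %*% as.matrix(corr) %*% diag(sigma, k)
  C <- suppressWarnings(chol((Sg + t(Sg)) / 2, pivot = TRUE))
  C <- C[, order(attr(C, "pivot")), drop = FALSE]
  out <- lapply(rownames(species_means), function(spp) {
    vals <- matrix(stats::rnorm(m * k), m, k) %*% C +
      matrix(unclass(species_means)[spp, ], m, k, byrow = TRUE)
    replicate_table(vals, species = spp, characters = colnames(species_means))
  })
  stats::setNames(out, rownames(species_means))
}
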