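#' Joint log-posterior of the restricted integrative model
#'
#' Sums the continuous-morphology pruning log-likelihood, the tree prior
#' (FBD or BDSS), the log-priors of the sampled scalar parameters, and the
#' relaxed-clock prior over branch rates when one is specified. Any
#' `-Inf` factor (including a singular among-character covariance, which is
#' treated as a rejected state rather than an error) makes the posterior
#' `-Inf`.
#'
#' @param state A list with elements `tree` (a [time_tree]), `bm` (a
#'   [bm_params]) and `episode` (an [episode_params]).
#' @param data A [character_matrix], or `NULL` for a prior-only evaluation.
#' @param priors A [prior_spec].
#' @return Scalar log-posterior (unnormalized).
#' @export
log_posterior <- function(state, data, priors) {
  ll <- 0
  if (!is.null(data) && nrow(data) > 0 && ncol(data) > 0) {
    x0 <- state$episode$origin_time
    if (!is.finite(x0)) x0 <- state$tree$origin_time %||% root_age(state$tree)
    ll <- tryCatch(
      pruning_loglik(data, state$tree, state$bm,
                     root_edge_time = max(x0 - root_age(state$tree), 0)),
      tedmorph_singular_error = function(e) -Inf)
  }
  if (!is.finite(ll)) return(-Inf)
  lp_tree <- if (priors$tree_model == "bdss")
    bdss_log_density(state$tree, state$episode)
  else fbd_log_density(state$tree, state$episode)
  lp <- lp_tree
  for (nm in c("c_m", "lambda", "mu", "psi", "p_extant")) {
    pr <- priors[[nm]]
    if (!is_fixed_prior(pr)) {
      val <- switch(nm, c_m = state$bm$c_m, state$episode[[nm]])
      lp <- lp + prior_logdens(pr, val)
    }
  }
  if (!is.null(priors$branch_rates)) {
    nr <- state$tree$rates[-(n_taxa(state$tree) + 1L)]
    lp <- lp + sum(prior_logdens(priors$branch_rates, nr))
  }
  if (inherits(priors$y0, "tm_prior") && !identical(state$bm$y0, "ML"))
    lp <- lp + sum(prior_logdens(priors$y0, state$bm$y0))
  if (!is.null(priors$L_diag) && !is.null(state$bm$L)) {
    L <- state$bm$L
    lp <- lp + sum(prior_logdens(priors$L_diag, diag(L)))
    if (ncol(L) > 1)
      lp <- lp + sum(prior_logdens(priors$L_offdiag, L[upper.tri(L)]))
  }
  ll + lp
}

# ---------------------------------------------------------------------
# internal mutable chain state

mcmc_init_state <- function(tree, M, bm, episode, priors) {
  st <- new.env(parent = emptyenv())
  phy <- tree$phy
  st$ntip <- length(phy$tip.label)
  st$nnode <- st$ntip + phy$Nnode
  st$root <- st$ntip + 1L
  st$parent <- parent_vec(phy)
  st$children <- unname(lapply(seq_len(st$nnode), function(i)
    phy$edge[phy$edge[, 1] == i, 2]))
  st$ages <- tree$ages
  st$rates <- tree$rates
  st$sa <- tree$sa
  st$tip.label <- phy$tip.label
  st$origin <- if (!is.null(episode$origin_time) && is.finite(episode$origin_time))
    episode$origin_time else tree$origin_time
  if (is.null(st$origin) || !is.finite(st$origin))
    stop("an origin time is required (episode_params or tree)")
  st$episode <- list(lambda = episode$lambda, mu = episode$mu,
                     psi = episode$psi, p_extant = episode$p_extant)
  st$tree_model <- priors$tree_model
  if (!is.null(M)) {
    labs <- taxa_labels(tree)
    st$Xt <- t(unclass(M)[labs, , drop = FALSE])
    st$labs <- labs
    st$k <- nrow(st$Xt)
  } else {
    st$Xt <- NULL
    st$labs <- taxa_labels(tree)
  }
  st$c_m <- bm$c_m
  st$L <- bm$L
  st$Sigma <- bm$Sigma
  st$verr <- bm$v_err
  st$y0 <- if (identical(bm$y0, "ML")) NULL else bm$y0
  refresh_topology_cache(st)
  st
}

refresh_topology_cache <- function(st) {
  nnode <- st$nnode
  keep <- rep(TRUE, nnode)
  sa_tips <- which(st$sa)
  keep[sa_tips] <- FALSE
  # iterative preorder, reversed
  stk <- integer(nnode); out <- integer(nnode)
  stk[1] <- st$root; top <- 1L; cnt <- 0L
  while (top > 0L) {
    u <- stk[top]; top <- top - 1L
    cnt <- cnt + 1L; out[cnt] <- u
    for (ch in st$children[[u]]) if (keep[ch]) {
      top <- top + 1L; stk[top] <- ch
    }
  }
  st$porder <- rev(out[seq_len(cnt)])
  obs <- integer(nnode)
  if (!is.null(st$labs))
    obs[seq_len(st$ntip)] <- match(st$tip.label, st$labs)
  for (f in sa_tips) {
    obs[st$parent[f]] <- obs[f]
    obs[f] <- 0L
  }
  st$obs <- obs
  # tree-prior classification cache (changes only with topology / flags)
  sa_attach <- st$parent[sa_tips]
  int <- (st$ntip + 1L):st$nnode
  deg <- lengths(st$children[int])
  st$cls_bif <- int[deg >= 2 & !(int %in% sa_attach)]
  ta <- st$ages[seq_len(st$ntip)]
  st$cls_fossil <- which(ta > 0 & !st$sa)
  st$cls_extant <- sum(ta == 0 & !st$sa)
  st$cls_nsa <- length(sa_tips)
  invisible(st)
}

state_loglik <- function(st) {
  if (is.null(st$Xt)) return(0)
  idx <- seq_len(st$nnode)[-st$root]
  wlen <- numeric(st$nnode)
  wlen[idx] <- (st$ages[st$parent[idx]] - st$ages[idx]) * st$rates[idx] * st$c_m
  res <- prune_felsenstein_cpp(st$parent, st$porder, wlen, st$obs, st$Xt,
                               st$Sigma, st$verr,
                               if (is.null(st$y0)) numeric(0) else st$y0,
                               max(st$origin - st$ages[st$root], 0) * st$c_m)
  if (res$status != 0L) return(-Inf)
  res$loglik
}

state_lp_tree <- function(st) {
  cls <- list(n_extant = st$cls_extant,
              n_fossil = length(st$cls_fossil),
              n_sa = st$cls_nsa,
              fossil_ages = st$ages[st$cls_fossil],
              bif_ages = st$ages[st$cls_bif],
              root_age = st$ages[st$root])
  ll <- fbd_log_density_parts(cls, st$origin, st$episode)
  if (st$tree_model == "bdss") ll <- ll - length(cls$bif_ages) * log(2)
  ll
}

# O(1) tree-prior update when a single bifurcation age moves
lp_tree_age_delta <- function(st, old_age, new_age) {
  cn <- fbd_constants(st$episode)
  fbd_log_q(new_age, cn) - fbd_log_q(old_age, cn)
}

state_lp_scalar <- function(st, priors) {
  out <- c(c_m = 0, lambda = 0, mu = 0, psi = 0, p_extant = 0, L = 0, y0 = 0)
  for (nm in c("c_m", "lambda", "mu", "psi", "p_extant")) {
    pr <- priors[[nm]]
    if (!is_fixed_prior(pr))
      out[nm] <- prior_logdens(pr, if (nm == "c_m") st$c_m else st$episode[[nm]])
  }
  if (!is.null(priors$L_diag) && !is.null(st$L)) {
    out["L"] <- sum(prior_logdens(priors$L_diag, diag(st$L)))
    if (ncol(st$L) > 1)
      out["L"] <- out["L"] +
        sum(prior_logdens(priors$L_offdiag, st$L[upper.tri(st$L)]))
  }
  if (inherits(priors$y0, "tm_prior") && !is.null(st$y0))
    out["y0"] <- sum(prior_logdens(priors$y0, st$y0))
  out
}

state_lp_rates <- function(st, priors) {
  if (is.null(priors$branch_rates)) return(0)
  sum(prior_logdens(priors$branch_rates,
                    st$rates[seq_len(st$nnode)[-st$root]]))
}

state_newick <- function(st) {
  build <- function(u) {
    kids <- st$children[[u]]
    len <- if (st$parent[u] > 0)
      sprintf(":%.12g", st$ages[st$parent[u]] - st$ages[u]) else ""
    if (length(kids) == 0) return(paste0(st$tip.label[u], len))
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")", len)
  }
  paste0(build(st$root), ";")
}

state_to_time_tree <- function(st) {
  ids <- seq_len(st$nnode)[-st$root]
  edge <- cbind(st$parent[ids], ids)
  phy <- structure(list(edge = edge,
                        edge.length = st$ages[edge[, 1]] - st$ages[edge[, 2]],
                        tip.label = st$tip.label,
                        Nnode = st$nnode - st$ntip),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  tt <- time_tree(phy, ages = st$ages, rates = st$rates, sa = st$sa)
  tt$origin_time <- st$origin
  tt
}

# descendant-tip keys of all internal nodes, restricted to a tip subset
topology_signature <- function(st, tips) {
  nnode <- st$nnode
  sets <- vector("list", nnode)
  for (i in seq_len(st$ntip)) sets[[i]] <- if (i %in% tips) i else integer(0)
  for (u in st$porder) {
    # children lists include sa pendant tips, whose sets are initialized
    for (ch in st$children[[u]])
      sets[[u]] <- c(sets[[u]], sets[[ch]])
  }
  keys <- vapply((st$ntip + 1L):nnode, function(u)
    paste(sort(sets[[u]]), collapse = ","), "")
  sort(unique(keys[nzchar(keys)]))
}

check_constraints_ok <- function(st, cinfo) {
  if (is.null(cinfo)) return(TRUE)
  for (cc in cinfo) {
    sig <- topology_signature(st, cc$tips)
    if (cc$fixed) {
      if (!identical(sig, cc$sig)) return(FALSE)
    } else {
      if (!(cc$key %in% sig)) return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------
# proposal moves; each returns TRUE (accepted) / FALSE and leaves the
# state caches (ll, lp_tree, lp_scalar, lp_rates) consistent

accept_mh <- function(st, delta, extra = 0) {
  is.finite(delta) && log(stats::runif(1)) < delta + extra
}

move_scaler <- function(st, priors, target, tune) {
  old <- if (target == "c_m") st$c_m else st$episode[[target]]
  if (old <= 0) return(FALSE)
  f <- exp(stats::runif(1, -tune, tune))
  new <- old * f
  lp_old <- st$lp_scalar[target]
  lp_new <- prior_logdens(priors[[target]], new)
  if (!is.finite(lp_new)) return(FALSE)
  if (target == "c_m") {
    st$c_m <- new
    ll_new <- state_loglik(st)
    d <- (ll_new - st$ll) + (lp_new - lp_old)
    if (accept_mh(st, d, log(f))) {
      st$ll <- ll_new; st$lp_scalar[target] <- lp_new
      return(TRUE)
    }
    st$c_m <- old
    return(FALSE)
  }
  st$episode[[target]] <- new
  lpt_new <- state_lp_tree(st)
  d <- (lpt_new - st$lp_tree) + (lp_new - lp_old)
  if (accept_mh(st, d, log(f))) {
    st$lp_tree <- lpt_new; st$lp_scalar[target] <- lp_new
    return(TRUE)
  }
  st$episode[[target]] <- old
  FALSE
}

move_p_extant <- function(st, priors, tune) {
  old <- st$episode$p_extant
  new <- old + stats::runif(1, -tune, tune)
  for (i in 1:10) {                      # reflect into (0, 1]
    if (new > 1) new <- 2 - new
    else if (new < 0) new <- -new
    else break
  }
  if (new <= 0 || new > 1) return(FALSE)
  lp_new <- prior_logdens(priors$p_extant, new)
  if (!is.finite(lp_new)) return(FALSE)
  st$episode$p_extant <- new
  lpt_new <- state_lp_tree(st)
  d <- (lpt_new - st$lp_tree) + (lp_new - st$lp_scalar["p_extant"])
  if (accept_mh(st, d)) {
    st$lp_tree <- lpt_new; st$lp_scalar["p_extant"] <- lp_new
    return(TRUE)
  }
  st$episode$p_extant <- old
  FALSE
}

move_L <- function(st, priors, tune) {
  k <- nrow(st$L)
  i <- sample.int(k, 1); j <- if (i == k) i else sample(i:k, 1)
  oldL <- st$L; oldS <- st$Sigma
  hr <- 0
  if (i == j) {
    f <- exp(stats::runif(1, -tune, tune))
    st$L[i, i] <- st$L[i, i] * f
    hr <- log(f)
  } else {
    st$L[i, j] <- st$L[i, j] + stats::rnorm(1, 0, tune)
  }
  st$Sigma <- tcrossprod(st$L)
  lp_new <- sum(prior_logdens(priors$L_diag, diag(st$L))) +
    if (k > 1) sum(prior_logdens(priors$L_offdiag, st$L[upper.tri(st$L)])) else 0
  if (!is.finite(lp_new)) { st$L <- oldL; st$Sigma <- oldS; return(FALSE) }
  ll_new <- state_loglik(st)
  d <- (ll_new - st$ll) + (lp_new - st$lp_scalar["L"])
  if (accept_mh(st, d, hr)) {
    st$ll <- ll_new; st$lp_scalar["L"] <- lp_new
    return(TRUE)
  }
  st$L <- oldL; st$Sigma <- oldS
  FALSE
}

move_y0 <- function(st, priors, tune) {
  k <- length(st$y0)
  i <- sample.int(k, 1)
  old <- st$y0[i]
  st$y0[i] <- old + stats::rnorm(1, 0, tune)
  lp_new <- sum(prior_logdens(priors$y0, st$y0))
  ll_new <- state_loglik(st)
  d <- (ll_new - st$ll) + (lp_new - st$lp_scalar["y0"])
  if (accept_mh(st, d)) {
    st$ll <- ll_new; st$lp_scalar["y0"] <- lp_new
    return(TRUE)
  }
  st$y0[i] <- old
  FALSE
}

move_branch_rate <- function(st, priors, tune) {
  cand <- seq_len(st$nnode)[-st$root]
  u <- cand[sample.int(length(cand), 1)]
  old <- st$rates[u]
  f <- exp(stats::runif(1, -tune, tune))
  st$rates[u] <- old * f
  lp_new <- state_lp_rates(st, priors)
  ll_new <- state_loglik(st)
  d <- (ll_new - st$ll) + (lp_new - st$lp_rates)
  if (accept_mh(st, d, log(f))) {
    st$ll <- ll_new; st$lp_rates <- lp_new
    return(TRUE)
  }
  st$rates[u] <- old
  FALSE
}

internal_age_candidates <- function(st) {
  int <- (st$ntip + 1L):st$nnode
  sa_attach <- st$parent[which(st$sa)]
  setdiff(int[int != st$root], sa_attach)
}

move_node_age <- function(st) {
  cand <- internal_age_candidates(st)
  if (length(cand) == 0) return(FALSE)
  u <- cand[sample.int(length(cand), 1)]
  lo <- max(st$ages[st$children[[u]]])
  hi <- st$ages[st$parent[u]]
  if (hi <= lo) return(FALSE)
  old <- st$ages[u]
  st$ages[u] <- stats::runif(1, lo, hi)
  ll_new <- state_loglik(st)
  lpt_new <- st$lp_tree + lp_tree_age_delta(st, old, st$ages[u])
  if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree))) {
    st$ll <- ll_new; st$lp_tree <- lpt_new
    return(TRUE)
  }
  st$ages[u] <- old
  FALSE
}

move_root_age <- function(st, tune) {
  r <- st$root
  if (r %in% st$parent[which(st$sa)]) return(FALSE)   # root age pinned
  if (length(st$children[[r]]) < 2) return(FALSE)     # degenerate origin root
  maxch <- max(st$ages[st$children[[r]]])
  x <- st$ages[r] - maxch
  if (x <= 0) return(FALSE)
  f <- exp(stats::runif(1, -tune, tune))
  xnew <- x * f
  if (maxch + xnew >= st$origin) return(FALSE)
  old <- st$ages[r]
  st$ages[r] <- maxch + xnew
  ll_new <- state_loglik(st)
  lpt_new <- state_lp_tree(st)
  if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree), log(f))) {
    st$ll <- ll_new; st$lp_tree <- lpt_new
    return(TRUE)
  }
  st$ages[r] <- old
  FALSE
}

# multiplier on all internal-node ages that are not pinned by a sampled
# ancestor; tips keep their (observed) ages, so validity is re-checked
move_tree_scale <- function(st, tune) {
  int <- (st$ntip + 1L):st$nnode
  pinned <- st$parent[which(st$sa)]
  scalable <- setdiff(int, pinned)
  if (length(scalable) == 0) return(FALSE)
  f <- exp(stats::runif(1, -tune, tune))
  old <- st$ages[scalable]
  st$ages[scalable] <- old * f
  idx <- seq_len(st$nnode)[-st$root]
  ok <- all(st$ages[st$parent[idx]] - st$ages[idx] >= 0) &&
    st$ages[st$root] < st$origin
  if (ok) {
    ll_new <- state_loglik(st)
    lpt_new <- state_lp_tree(st)
    if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree),
                  length(scalable) * log(f))) {
      st$ll <- ll_new; st$lp_tree <- lpt_new
      return(TRUE)
    }
  }
  st$ages[scalable] <- old
  FALSE
}

# joint multiplier along the rate-height ridge: scales c_m up while
# scaling unpinned internal ages down by the same factor (and vice versa);
# Jacobian is (1 - m) log f for the m scaled ages
move_rate_height <- function(st, priors, tune) {
  int <- (st$ntip + 1L):st$nnode
  pinned <- st$parent[which(st$sa)]
  scalable <- setdiff(int, pinned)
  if (length(scalable) == 0) return(FALSE)
  f <- exp(stats::runif(1, -tune, tune))
  old_cm <- st$c_m
  old_ages <- st$ages[scalable]
  st$c_m <- old_cm * f
  st$ages[scalable] <- old_ages / f
  idx <- seq_len(st$nnode)[-st$root]
  ok <- all(st$ages[st$parent[idx]] - st$ages[idx] >= 0) &&
    st$ages[st$root] < st$origin
  lp_new <- prior_logdens(priors$c_m, st$c_m)
  if (ok && is.finite(lp_new)) {
    ll_new <- state_loglik(st)
    lpt_new <- state_lp_tree(st)
    d <- (ll_new - st$ll) + (lpt_new - st$lp_tree) +
      (lp_new - st$lp_scalar["c_m"])
    if (accept_mh(st, d, (1 - length(scalable)) * log(f))) {
      st$ll <- ll_new; st$lp_tree <- lpt_new
      st$lp_scalar["c_m"] <- lp_new
      return(TRUE)
    }
  }
  st$c_m <- old_cm
  st$ages[scalable] <- old_ages
  FALSE
}

exchange_candidates <- function(st) {
  out <- list()
  is_sa_tip <- function(x) x <= st$ntip && st$sa[x]
  for (u in (st$ntip + 1L):st$nnode) {
    g <- st$parent[u]
    if (g == 0L) next
    sibs <- st$children[[g]]
    sibs <- sibs[sibs != u]
    for (s in sibs) {
      if (is_sa_tip(s)) next
      if (st$ages[s] >= st$ages[u]) next
      for (cc in st$children[[u]]) {
        if (is_sa_tip(cc)) next
        out[[length(out) + 1L]] <- c(u, g, cc, s)
      }
    }
  }
  out
}

apply_exchange <- function(st, mv) {
  u <- mv[1]; g <- mv[2]; cc <- mv[3]; s <- mv[4]
  ku <- st$children[[u]]; ku[ku == cc] <- s
  kg <- st$children[[g]]; kg[kg == s] <- cc
  st$children[[u]] <- ku
  st$children[[g]] <- kg
  st$parent[cc] <- g
  st$parent[s] <- u
}

move_exchange <- function(st, cinfo) {
  cand <- exchange_candidates(st)
  nf <- length(cand)
  if (nf == 0) return(FALSE)
  mv <- cand[[sample.int(nf, 1)]]
  apply_exchange(st, mv)
  refresh_topology_cache(st)
  if (!check_constraints_ok(st, cinfo)) {
    apply_exchange(st, mv[c(1, 2, 4, 3)])
    refresh_topology_cache(st)
    return(FALSE)
  }
  nr <- length(exchange_candidates(st))
  ll_new <- state_loglik(st)
  # FBD/BDSS density depends on event times and classes only, so the tree
  # prior is unchanged by an age-preserving exchange
  if (accept_mh(st, ll_new - st$ll, log(nf) - log(nr))) {
    st$ll <- ll_new
    return(TRUE)
  }
  apply_exchange(st, mv[c(1, 2, 4, 3)])
  refresh_topology_cache(st)
  FALSE
}

move_sa_toggle <- function(st) {
  fossils <- which(st$ages[seq_len(st$ntip)] > 0)
  if (length(fossils) == 0) return(FALSE)
  f <- fossils[sample.int(length(fossils), 1)]
  p <- st$parent[f]
  y <- st$ages[f]
  up <- if (p == st$root) st$origin else st$ages[st$parent[p]]
  if (st$sa[f]) {                        # expand to a fossil tip
    anew <- stats::runif(1, y, up)
    old_age <- st$ages[p]
    st$ages[p] <- anew; st$sa[f] <- FALSE
    refresh_topology_cache(st)
    ll_new <- state_loglik(st)
    lpt_new <- state_lp_tree(st)
    d <- (ll_new - st$ll) + (lpt_new - st$lp_tree)
    if (accept_mh(st, d, log(up - y))) {
      st$ll <- ll_new; st$lp_tree <- lpt_new
      return(TRUE)
    }
    st$ages[p] <- old_age; st$sa[f] <- TRUE
    refresh_topology_cache(st)
    return(FALSE)
  }
  z <- st$children[[p]]
  z <- z[z != f]
  if (length(z) != 1 || st$ages[z] >= y) return(FALSE)
  if (up <= y) return(FALSE)
  old_age <- st$ages[p]
  st$ages[p] <- y; st$sa[f] <- TRUE
  refresh_topology_cache(st)
  ll_new <- state_loglik(st)
  lpt_new <- state_lp_tree(st)
  d <- (ll_new - st$ll) + (lpt_new - st$lp_tree)
  if (accept_mh(st, d, -log(up - y))) {
    st$ll <- ll_new; st$lp_tree <- lpt_new
    return(TRUE)
  }
  st$ages[p] <- old_age; st$sa[f] <- FALSE
  refresh_topology_cache(st)
  FALSE
}

# prune-and-regraft for a fossil tip: detach its attachment node and
# re-insert it on a uniformly chosen compatible edge at a uniform age.
# The candidate edge set is counted on the detached tree, which is the
# same in both directions, so the Hastings ratio reduces to the ratio of
# the attachment-interval lengths.
do_reattach <- function(st, f, p, target, new_age) {
  z <- st$children[[p]]
  z <- z[z != f]
  g <- st$parent[p]
  kg <- st$children[[g]]; kg[kg == p] <- z
  st$children[[g]] <- kg
  st$parent[z] <- g
  u <- st$parent[target]
  ku <- st$children[[u]]; ku[ku == target] <- p
  st$children[[u]] <- ku
  st$parent[p] <- u
  st$children[[p]] <- c(f, target)
  st$parent[target] <- p
  st$ages[p] <- new_age
}

move_fossil_reattach <- function(st, cinfo) {
  fossils <- which(st$ages[seq_len(st$ntip)] > 0 & !st$sa)
  if (length(fossils) == 0) return(FALSE)
  f <- fossils[sample.int(length(fossils), 1)]
  p <- st$parent[f]
  if (p == st$root) return(FALSE)
  g <- st$parent[p]
  z <- st$children[[p]]
  z <- z[z != f]
  if (length(z) != 1) return(FALSE)
  if (z <= st$ntip && st$sa[z]) return(FALSE)   # p pins a sampled ancestor
  y <- st$ages[f]
  lo0 <- max(y, st$ages[z]); hi0 <- st$ages[g]
  # candidate edges of the detached tree (child endpoint v, parent dpar(v))
  dpar <- st$parent
  dpar[z] <- g
  cand_v <- integer(0); cand_lo <- numeric(0); cand_hi <- numeric(0)
  for (v in seq_len(st$nnode)) {
    if (v == f || v == p || v == st$root || dpar[v] == 0) next
    u <- dpar[v]
    if (u == p) u <- g
    lo <- max(y, st$ages[v]); hi <- st$ages[u]
    if (hi > lo) {
      cand_v <- c(cand_v, v); cand_lo <- c(cand_lo, lo)
      cand_hi <- c(cand_hi, hi)
    }
  }
  if (length(cand_v) == 0) return(FALSE)
  j <- sample.int(length(cand_v), 1)
  target <- cand_v[j]
  anew <- stats::runif(1, cand_lo[j], cand_hi[j])
  old_age <- st$ages[p]
  do_reattach(st, f, p, target, anew)
  refresh_topology_cache(st)
  if (!check_constraints_ok(st, cinfo)) {
    do_reattach(st, f, p, z, old_age)
    refresh_topology_cache(st)
    return(FALSE)
  }
  ll_new <- state_loglik(st)
  lpt_new <- state_lp_tree(st)
  hr <- log(cand_hi[j] - cand_lo[j]) - log(hi0 - lo0)
  if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree), hr)) {
    st$ll <- ll_new; st$lp_tree <- lpt_new
    return(TRUE)
  }
  do_reattach(st, f, p, z, old_age)
  refresh_topology_cache(st)
  FALSE
}

move_fossil_age <- function(st) {
  fossils <- which(st$ages[seq_len(st$ntip)] > 0)
  if (length(fossils) == 0) return(FALSE)
  f <- fossils[sample.int(length(fossils), 1)]
  p <- st$parent[f]
  if (st$sa[f]) {
    z <- st$children[[p]]
    z <- z[z != f]
    lo <- if (length(z)) max(st$ages[z]) else 0
    up <- if (p == st$root) st$origin else st$ages[st$parent[p]]
    if (up <= lo) return(FALSE)
    ynew <- stats::runif(1, lo, up)
    oldf <- st$ages[f]; oldp <- st$ages[p]
    st$ages[f] <- ynew; st$ages[p] <- ynew
    ll_new <- state_loglik(st)
    lpt_new <- state_lp_tree(st)
    if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree))) {
      st$ll <- ll_new; st$lp_tree <- lpt_new
      return(TRUE)
    }
    st$ages[f] <- oldf; st$ages[p] <- oldp
    return(FALSE)
  }
  up <- st$ages[p]
  ynew <- stats::runif(1, 0, up)
  old <- st$ages[f]
  st$ages[f] <- ynew
  ll_new <- state_loglik(st)
  lpt_new <- state_lp_tree(st)
  if (accept_mh(st, (ll_new - st$ll) + (lpt_new - st$lp_tree))) {
    st$ll <- ll_new; st$lp_tree <- lpt_new
    return(TRUE)
  }
  st$ages[f] <- old
  FALSE
}

# ---------------------------------------------------------------------

#' Default MCMC move schedule
#'
#' Relative weights and tuning constants for the proposal mixture; entries
#' for parameters that are fixed in the [prior_spec] are dropped by
#' [run_chain()]. Weights are unnormalized selection probabilities.
#'
#' @param sample_fossil_ages Include moves that resample fossil tip ages
#'   (used for prior-coherence validation; empirical fossil ages are data
#'   and stay fixed by default).
#' @return A data frame with columns `move`, `weight`, `tune`.
#' @export
default_moves <- function(sample_fossil_ages = FALSE) {
  mv <- data.frame(
    move = c("c_m", "lambda", "mu", "psi", "p_extant", "L", "y0",
             "branch_rate", "node_age", "root_age", "tree_scale",
             "rate_height", "exchange", "sa_toggle", "fossil_reattach",
             "fossil_age"),
    weight = c(4, 1, 1, 1, 1, 3, 1, 2, 10, 2, 3, 4, 4, 2, 4,
               if (sample_fossil_ages) 3 else 0),
    tune = c(0.4, 0.5, 0.5, 0.5, 0.1, 0.3, 0.5, 0.5, NA, 0.7, 0.25, 0.3, NA,
             NA, NA, NA),
    stringsAsFactors = FALSE)
  mv
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples the joint posterior of the time tree (node ages, topology via
#' constrained subtree exchanges, sampled-ancestor attachments) and the
#' free model parameters, under the continuous-morphology likelihood and
#' the FBD/BDSS tree prior. Proposals violating monophyly constraints or a
#' fixed extant subtopology are rejected; a singular among-character
#' covariance rejects the proposal rather than erroring. The chain is
#' deterministic given `seed`.
#'
#' @param data A [character_matrix], or `NULL` for a prior-only chain.
#' @param tree_init Initial [time_tree] (e.g. from [simulate_fbd()]).
#' @param priors A [prior_spec]; fixed-prior parameters are not sampled.
#' @param moves Move schedule, see [default_moves()].
#' @param chain_length Number of MH iterations.
#' @param sample_every Sampling stride.
#' @param seed Integer seed.
#' @param init_bm Initial [bm_params] (required when `data` is given;
#'   its fixed components — correlations, `v_err`, `y0` mode — define the
#'   model).
#' @param init_episode Initial [episode_params].
#' @param constraints List of [clade_constraint] objects.
#' @param fix_extant_topology Keep the extant-restricted topology at its
#'   initial value (fossil attachments are still sampled).
#' @param store_trees Record a Newick string per sample.
#' @param debug_check_every When `> 0`, re-derive the cached log-posterior
#'   from scratch every so many iterations and stop on disagreement.
#' @return A [tm_trace]; its samples include the posterior decomposition,
#'   all sampled scalars, the root age and the sampled-ancestor count.
#' @export
run_chain <- function(data, tree_init, priors, moves = default_moves(),
                      chain_length = 10000, sample_every = 10, seed,
                      init_bm = NULL, init_episode = NULL,
                      constraints = list(), fix_extant_topology = FALSE,
                      store_trees = TRUE, debug_check_every = 0) {
  set.seed(as.integer(seed))
  if (!is.null(data) && is.null(init_bm))
    stop("`init_bm` is required when data are supplied")
  if (is.null(init_bm)) init_bm <- bm_params(corr = diag(1), y0 = 0)
  if (is.null(init_episode)) {
    init_episode <- episode_params(
      lambda = if (is_fixed_prior(priors$lambda)) priors$lambda$par$value
               else prior_draw(priors$lambda),
      mu = if (is_fixed_prior(priors$mu)) priors$mu$par$value
           else prior_draw(priors$mu),
      psi = if (is_fixed_prior(priors$psi)) priors$psi$par$value
            else prior_draw(priors$psi),
      p_extant = if (is_fixed_prior(priors$p_extant)) priors$p_extant$par$value
                 else prior_draw(priors$p_extant),
      origin_time = if (is_fixed_prior(priors$origin_time) &&
                        !is.null(priors$origin_time$par$value))
        priors$origin_time$par$value else NA_real_)
  }
  st <- mcmc_init_state(tree_init, data, init_bm, init_episode, priors)
  st$ll <- state_loglik(st)
  st$lp_tree <- state_lp_tree(st)
  st$lp_scalar <- state_lp_scalar(st, priors)
  st$lp_rates <- state_lp_rates(st, priors)
  if (!is.finite(st$ll + st$lp_tree + sum(st$lp_scalar) + st$lp_rates))
    stop("initial state has log-posterior -Inf; re-initialize the chain")
  # constraints preprocessed into tip indices + signatures
  cinfo <- NULL
  if (length(constraints) > 0 || fix_extant_topology) {
    cinfo <- list()
    for (cc in constraints) {
      tips <- match(cc$labels, st$tip.label)
      if (anyNA(tips)) stop("constraint names unknown tips: ",
                            paste(cc$labels[is.na(tips)], collapse = ", "))
      cinfo[[length(cinfo) + 1L]] <-
        list(tips = tips, fixed = cc$fixed_subtopology,
             key = paste(sort(tips), collapse = ","),
             sig = topology_signature(st, tips))
    }
    if (fix_extant_topology) {
      ext <- which(st$ages[seq_len(st$ntip)] == 0 & !st$sa)
      cinfo[[length(cinfo) + 1L]] <-
        list(tips = ext, fixed = TRUE, key = "",
             sig = topology_signature(st, ext))
    }
    if (!check_constraints_ok(st, cinfo))
      stop("initial tree violates the supplied constraints")
  }
  # active moves
  mv <- moves
  active <- vapply(seq_len(nrow(mv)), function(i) {
    m <- mv$move[i]
    switch(m,
      c_m = !is_fixed_prior(priors$c_m) && !is.null(data),
      lambda = !is_fixed_prior(priors$lambda),
      mu = !is_fixed_prior(priors$mu),
      psi = !is_fixed_prior(priors$psi),
      p_extant = !is_fixed_prior(priors$p_extant),
      L = !is.null(priors$L_diag) && !is.null(st$L),
      y0 = inherits(priors$y0, "tm_prior") && !is.null(st$y0) &&
        !is.null(data),
      branch_rate = !is.null(priors$branch_rates),
      rate_height = !is_fixed_prior(priors$c_m) && !is.null(data),
      TRUE) && mv$weight[i] > 0
  }, TRUE)
  # prior-only chains still sample c_m if it has a prior
  if (is.null(data) && !is_fixed_prior(priors$c_m))
    active[mv$move == "c_m"] <- TRUE
  mv <- mv[active, , drop = FALSE]
  if (nrow(mv) == 0) stop("no active moves")
  pmv <- mv$weight / sum(mv$weight)
  mvseq <- sample.int(nrow(mv), chain_length, replace = TRUE, prob = pmv)
  nsamp <- floor(chain_length / sample_every)
  k <- if (!is.null(st$Xt)) st$k else 0
  Lnames <- if (!is.null(st$L))
    paste0("L_", which(upper.tri(st$L, diag = TRUE), arr.ind = TRUE)[, 1],
           "_", which(upper.tri(st$L, diag = TRUE), arr.ind = TRUE)[, 2])
  else character(0)
  cols <- c("Sample", "posterior", "likelihood", "prior", "c_m", "lambda",
            "mu", "psi", "p_extant", "root_age", "origin", "sa_count",
            Lnames)
  samp <- matrix(NA_real_, nsamp, length(cols),
                 dimnames = list(NULL, cols))
  trees <- if (store_trees) character(nsamp) else NULL
  acc <- stats::setNames(numeric(nrow(mv)), mv$move)
  tot <- stats::setNames(numeric(nrow(mv)), mv$move)
  row <- 0L
  for (it in seq_len(chain_length)) {
    mi <- mvseq[it]
    m <- mv$move[mi]; tune <- mv$tune[mi]
    ok <- switch(m,
      c_m = move_scaler(st, priors, "c_m", tune),
      lambda = move_scaler(st, priors, "lambda", tune),
      mu = move_scaler(st, priors, "mu", tune),
      psi = move_scaler(st, priors, "psi", tune),
      p_extant = move_p_extant(st, priors, tune),
      L = move_L(st, priors, tune),
      y0 = move_y0(st, priors, tune),
      branch_rate = move_branch_rate(st, priors, tune),
      node_age = move_node_age(st),
      root_age = move_root_age(st, tune),
      tree_scale = move_tree_scale(st, tune),
      rate_height = move_rate_height(st, priors, tune),
      exchange = move_exchange(st, cinfo),
      sa_toggle = move_sa_toggle(st),
      fossil_reattach = move_fossil_reattach(st, cinfo),
      fossil_age = move_fossil_age(st))
    tot[mi] <- tot[mi] + 1
    if (isTRUE(ok)) acc[mi] <- acc[mi] + 1
    if (debug_check_every > 0 && it %% debug_check_every == 0) {
      ref_ll <- state_loglik(st)
      ref_lpt <- state_lp_tree(st)
      ref_lps <- state_lp_scalar(st, priors)
      ref_lpr <- state_lp_rates(st, priors)
      if (abs(ref_ll - st$ll) > 1e-6 || abs(ref_lpt - st$lp_tree) > 1e-6 ||
          abs(sum(ref_lps) - sum(st$lp_scalar)) > 1e-6 ||
          abs(ref_lpr - st$lp_rates) > 1e-6)
        stop("posterior cache incoherent at iteration ", it)
    }
    if (it %% sample_every == 0) {
      row <- row + 1L
      lp <- st$lp_tree + sum(st$lp_scalar) + st$lp_rates
      vals <- c(it, st$ll + lp, st$ll, lp, st$c_m, st$episode$lambda,
                st$episode$mu, st$episode$psi, st$episode$p_extant,
                st$ages[st$root], st$origin, sum(st$sa),
                if (!is.null(st$L)) st$L[upper.tri(st$L, diag = TRUE)])
      samp[row, ] <- vals
      if (store_trees) trees[row] <- state_newick(st)
    }
  }
  out <- as.data.frame(samp[seq_len(row), , drop = FALSE])
  tm_trace(out, trees = if (store_trees) trees[seq_len(row)] else NULL,
           seed = as.integer(seed),
           config = list(chain_length = chain_length,
                         sample_every = sample_every,
                         moves = mv, acceptance = as.list(acc / pmax(tot, 1)),
                         tree_model = priors$tree_model))
}
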