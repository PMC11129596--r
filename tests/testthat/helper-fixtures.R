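# shared fixtures and independent oracles (kept deliberately separate from
# the package's own code paths)

fixture_tree3 <- function() parse_tree("((A:1.0,B:1.0):1.0,C:2.0);")

fixture_sa_tree <- function() parse_tree("((A:1.0,F:0.0):1.0,C:2.0);")

# random FBD tree with n in [lo, hi]
random_fbd_tree <- function(seed, lo = 2, hi = 8,
                            ep = episode_params(1, 0.3, 0.6, origin_time = 2)) {
  for (i in 0:200) {
    tr <- tryCatch(simulate_fbd(ep, seed = seed + i * 1000L, max_tries = 200),
                   error = function(e) NULL)
    if (!is.null(tr) && n_taxa(tr) >= lo && n_taxa(tr) <= hi) return(tr)
  }
  stop("fixture generation failed")
}

random_bm_params <- function(seed, k, with_verr = FALSE, y0 = NULL) {
  set.seed(seed)
  L <- matrix(0, k, k)
  diag(L) <- exp(rnorm(k, 0, 0.2))
  if (k > 1) L[upper.tri(L)] <- rnorm(k * (k - 1) / 2, 0, 0.4)
  bm_params(L = L, c_m = exp(rnorm(1, 0, 0.3)),
            y0 = if (is.null(y0)) rnorm(k) else y0,
            sigma_intra = if (with_verr) runif(k, 0.1, 0.5) else NULL)
}

# independent dense MVN oracle: explicit Kronecker construction and a
# solve()-based quadratic form (the package's dense path uses Cholesky)
oracle_mvn_loglik <- function(M, tree, params) {
  labs <- taxa_labels(tree)
  X <- unclass(M)[labs, , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  Tm <- oracle_phylo_vcv(tree, params$c_m)[labs, labs]
  V <- kronecker(Tm, params$Sigma) + diag(n) %x% params$v_err
  x <- as.vector(t(X))
  mu <- rep(params$y0, times = n)
  ld <- determinant(V, logarithm = TRUE)$modulus
  r <- x - mu
  -0.5 * (n * k * log(2 * pi) + as.numeric(ld) + sum(r * solve(V, r)))
}

# independent path-walk phylogenetic covariance
oracle_phylo_vcv <- function(tree, c_m = 1) {
  phy <- tree$phy
  labs <- sort(phy$tip.label)
  n <- length(labs)
  par <- integer(length(tree$ages))
  par[phy$edge[, 2]] <- phy$edge[, 1]
  root <- length(phy$tip.label) + 1L
  path_nodes <- function(tip) {
    out <- integer(0)
    u <- tip
    while (u != root) { out <- c(out, u); u <- par[u] }
    out
  }
  edge_w <- function(u) (tree$ages[par[u]] - tree$ages[u]) * tree$rates[u] * c_m
  Tm <- matrix(0, n, n, dimnames = list(labs, labs))
  ids <- match(labs, phy$tip.label)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(path_nodes(ids[i]), path_nodes(ids[j]))
    Tm[i, j] <- sum(vapply(shared, edge_w, 0))
  }
  Tm
}

# brute-force shortest-HPD oracle
oracle_hpd <- function(x, level) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(level * n)
  best <- c(s[1], s[n]); bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < bw) { bw <- w; best <- c(s[i], s[i + m - 1]) }
  }
  best
}

# canonical topology signature: sorted clade label keys
extant_signature <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  par <- integer(ntip + phy$Nnode)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  keys <- character(phy$Nnode)
  for (v in seq_len(phy$Nnode)) {
    node <- ntip + v
    tips <- phy$tip.label[vapply(seq_len(ntip), function(t) {
      u <- t
      while (u != 0 && u != node) u <- par[u]
      u == node
    }, TRUE)]
    keys[v] <- paste(sort(tips), collapse = "|")
  }
  sort(keys)
}

# brute-force clade (bipartition) frequency counter keyed by label strings
oracle_clade_freqs <- function(trees) {
  counts <- new.env()
  for (tr in trees) {
    phy <- tr$phy
    ntip <- length(phy$tip.label)
    for (node in (ntip + 1L):(ntip + phy$Nnode)) {
      tips <- phy$tip.label[unlist(lapply(seq_len(ntip), function(t) {
        u <- t
        par <- integer(ntip + phy$Nnode)
        par[phy$edge[, 2]] <- phy$edge[, 1]
        while (u != 0 && u != node) u <- par[u]
        if (u == node) t else NULL
      }))]
      key <- paste(sort(tips), collapse = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  out <- unlist(as.list(counts)) / length(trees)
  out
}
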