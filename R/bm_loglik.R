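stop_singular <- function(msg = "singular covariance") {
  stop(errorCondition(msg, class = c("tedmorph_singular_error", "error")))
}

# Internal likelihood-ready view of a time tree: sampled-ancestor tips are
# merged into their attachment node, which becomes an *observed* internal
# node handled exactly (zero branch variance) by both pruning algorithms.
lik_tree <- function(tree, labs = taxa_labels(tree)) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  par <- parent_vec(phy)
  sa_tip <- which(c(tree$sa, rep(FALSE, phy$Nnode)))
  obs <- integer(nnode)                      # row of M observed at node
  obs[seq_len(ntip)] <- match(phy$tip.label, labs)
  for (f in sa_tip) {
    obs[par[f]] <- obs[f]
    obs[f] <- 0L
  }
  keep <- rep(TRUE, nnode)
  keep[sa_tip] <- FALSE
  eo <- ape::reorder.phylo(phy, "postorder")
  porder <- c(eo$edge[, 2], ntip + 1L)
  porder <- porder[keep[porder]]
  wlen <- numeric(nnode)                     # rate-weighted time on edge to parent
  wlen[phy$edge[, 2]] <- (tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]) *
    tree$rates[phy$edge[, 2]]
  list(n_nodes = nnode, parent = par, porder = porder, wlen = wlen,
       obs = obs, root = ntip + 1L)
}

check_matrix_tree <- function(M, tree) {
  labs <- taxa_labels(tree)
  if (!setequal(rownames(M), labs))
    stop("character matrix taxa do not match the tree's sampled taxa")
  unclass(M)[labs, , drop = FALSE]
}

#' Dense multivariate-normal likelihood of continuous characters (oracle)
#'
#' Evaluates the phylogenetic Brownian-motion log-likelihood by explicit
#' construction of the full `nk x nk` trait covariance
#' `V = T %x% Sigma` (taxon-major), adding the intraspecific block-diagonal
#' increment, and applying the multivariate normal density to the
#' vectorized data. Cost is cubic in `nk`; this is the reference
#' implementation that the pruning algorithms are tested against.
#'
#' @param M A [character_matrix] whose taxa match the tree.
#' @param tree A [time_tree].
#' @param params A [bm_params].
#' @param root_edge_time Extra time (before the root) over which the trait
#'   process diffuses before reaching the root: the root state is
#'   `N(y0, root_edge_time * c_m * Sigma)` rather than exactly `y0`. The
#'   default 0 starts the process at the root. The MCMC engine sets this to
#'   `origin_time - root_age`, which keeps the posterior proper when a
#'   sampled ancestor observes the root state exactly.
#' @return The log-density (scalar). With `y0 = "ML"` the root values are
#'   profiled at their generalized-least-squares optimum.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' M <- character_matrix(matrix(c(0, .1, -.2), 3,
#'                      dimnames = list(c("A", "B", "C"), "c1")))
#' dense_loglik(M, tr, bm_params(corr = diag(1), y0 = 0))
#' @export
dense_loglik <- function(M, tree, params, root_edge_time = 0) {
  X <- check_matrix_tree(M, tree)
  n <- nrow(X); k <- ncol(X)
  if (k != params$k) stop("params dimension k does not match data")
  Tm <- phylo_vcv(tree, params$c_m) + root_edge_time * params$c_m
  V <- Tm %x% params$Sigma
  if (any(params$v_err != 0)) V <- apply_intraspecific(V, params$v_err)
  x <- as.vector(t(X))                       # taxon-major
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop_singular()
  if (identical(params$y0, "ML")) {
    Xd <- rep(1, n) %x% diag(k)
    Vi_X <- backsolve(R, backsolve(R, Xd, transpose = TRUE))
    Vi_x <- backsolve(R, backsolve(R, x, transpose = TRUE))
    y0 <- solve(crossprod(Xd, Vi_X), crossprod(Xd, Vi_x))[, 1]
  } else y0 <- params$y0
  mu <- rep(y0, times = n)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (n * k * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Pruning-algorithm likelihood of continuous characters
#'
#' Computes the same log-density as [dense_loglik()] in time linear in the
#' number of taxa (for fixed `k`), never forming the `nk x nk` covariance:
#' only the `k x k` among-character covariance is factorized. Two variants
#' are provided:
#' \describe{
#'   \item{`"felsenstein"`}{Post-order message passing carrying, per node,
#'     a conditional mean vector, a `k x k` covariance and an accumulated
#'     log-density (implemented in C++). This generalizes the classic
#'     three-quantity contrast recursion to correlated characters and
#'     arbitrary tip-error matrices.}
#'   \item{`"general"`}{The intermediate-coefficient recursion: each node
#'     propagates the quadratic coefficients (matrix, vector, scalar) of
#'     its subtree's log-likelihood as a function of the ancestral state,
#'     combined by Gaussian integrals along branches and evaluated (or
#'     maximized, for `y0 = "ML"`) at the root.}
#' }
#' Sampled ancestors contribute exact observations of internal states
#' (zero-length edges add zero branch variance); intraspecific variance is
#' added at the observations per the block-diagonal tip increment.
#'
#' @inheritParams dense_loglik
#' @param algorithm `"felsenstein"` or `"general"`.
#' @return The log-density. A singular among-character covariance raises an
#'   error of class `tedmorph_singular_error` (the MCMC layer converts this
#'   into proposal rejection).
#' @export
pruning_loglik <- function(M, tree, params,
                           algorithm = c("felsenstein", "general"),
                           root_edge_time = 0) {
  algorithm <- match.arg(algorithm)
  X <- check_matrix_tree(M, tree)
  if (ncol(X) != params$k) stop("params dimension k does not match data")
  lt <- lik_tree(tree, labs = rownames(X))
  if (algorithm == "felsenstein") {
    res <- prune_felsenstein_cpp(lt$parent, lt$porder,
                                 lt$wlen * params$c_m, lt$obs, t(X),
                                 params$Sigma, params$v_err,
                                 if (identical(params$y0, "ML")) numeric(0)
                                 else params$y0,
                                 root_edge_time * params$c_m)
    if (res$status == 1L) stop_singular()
    if (res$status == 2L) stop("degenerate tree: conflicting exact observations")
    return(res$loglik)
  }
  general_loglik(lt, X, params, root_edge_time)
}

#' Maximum-likelihood root character values
#'
#' Profiles the root values out of the Brownian likelihood: the optimizer
#' `y0hat` is obtained as a byproduct of the pruning pass (the root's
#' conditional mean), and equals the generalized-least-squares estimate
#' `(1' T^-1 M) / (1' T^-1 1)` per character when no intraspecific variance
#' is present.
#'
#' @inheritParams dense_loglik
#' @return Named numeric vector of `k` root values.
#' @export
ml_root_values <- function(M, tree, params) {
  X <- check_matrix_tree(M, tree)
  if (ncol(X) != params$k) stop("params dimension k does not match data")
  lt <- lik_tree(tree, labs = rownames(X))
  res <- prune_felsenstein_cpp(lt$parent, lt$porder, lt$wlen * params$c_m,
                               lt$obs, t(X), params$Sigma, params$v_err,
                               numeric(0), 0)
  if (res$status == 1L) stop_singular()
  stats::setNames(as.numeric(res$y0hat), colnames(X))
}

# ------------------------------------------------------------------
# "general" variant: quadratic intermediate-coefficient recursion (pure R)

general_loglik <- function(lt, X, params, root_edge_time = 0) {
  k <- params$k
  Sigma <- params$Sigma
  verr <- params$v_err
  has_verr <- any(verr != 0)
  if (has_verr) {
    Vinv <- tryCatch(chol2inv(chol(verr)), error = function(e) NULL)
    if (is.null(Vinv))
      stop("the general algorithm requires `v_err` to be zero or positive ",
           "definite; use algorithm = 'felsenstein' for singular v_err")
    ld_verr <- 2 * sum(log(diag(chol(verr))))
  }
  if (inherits(tryCatch(chol(Sigma), error = function(e) e), "error"))
    stop_singular()
  c_m <- params$c_m
  # per-node message to parent: list(A, b, c) as quadratic in parent state
  msg <- vector("list", lt$n_nodes)
  children <- split(seq_len(lt$n_nodes)[lt$parent > 0], lt$parent[lt$parent > 0])
  loglik <- NA_real_
  y0hat <- NULL
  for (u in lt$porder) {
    A <- matrix(0, k, k); b <- numeric(k); cc <- 0
    for (ch in children[[as.character(u)]] %||% integer(0)) {
      m <- msg[[ch]]
      if (!is.null(m)) { A <- A + m$A; b <- b + m$b; cc <- cc + m$c }
    }
    is_root <- u == lt$root
    oi <- lt$obs[u]
    if (oi > 0 && !has_verr) {
      # exact observation of this node's state
      x <- X[oi, ]
      C <- drop(crossprod(x, A %*% x) + crossprod(b, x)) + cc
      if (is_root) {
        if (root_edge_time > 0) {
          W0 <- root_edge_time * c_m * Sigma
          if (identical(params$y0, "ML")) {
            loglik <- C - 0.5 * (k * log(2 * pi) + logdet_chol(W0))
            y0hat <- x
          } else {
            Wi0 <- chol2inv(chol(W0))
            d0 <- x - params$y0
            loglik <- C - 0.5 * (k * log(2 * pi) + logdet_chol(W0) +
                                   drop(crossprod(d0, Wi0 %*% d0)))
          }
        } else if (identical(params$y0, "ML")) { loglik <- C; y0hat <- x }
        else loglik <- if (isTRUE(all.equal(params$y0, x))) C else -Inf
        next
      }
      W <- lt$wlen[u] * c_m * Sigma
      Wi <- chol2inv(chol(W))
      msg[[u]] <- list(A = -0.5 * Wi, b = Wi %*% x |> drop(),
                       c = C - 0.5 * (drop(crossprod(x, Wi %*% x)) +
                                        k * log(2 * pi) + logdet_chol(W)))
      next
    }
    if (oi > 0) {
      x <- X[oi, ]
      A <- A - 0.5 * Vinv
      b <- b + drop(Vinv %*% x)
      cc <- cc - 0.5 * (drop(crossprod(x, Vinv %*% x)) +
                          k * log(2 * pi) + ld_verr)
    }
    P <- -2 * A
    if (is_root) {
      if (root_edge_time > 0) {
        # diffuse over the origin branch before evaluating at y0
        W0 <- root_edge_time * c_m * Sigma
        Wi0 <- chol2inv(chol(W0))
        G0 <- chol2inv(chol(P + Wi0))
        A0 <- -0.5 * (Wi0 - Wi0 %*% G0 %*% Wi0)
        b0 <- drop(Wi0 %*% G0 %*% b)
        c0 <- cc + 0.5 * drop(crossprod(b, G0 %*% b)) -
          0.5 * logdet_chol(W0) - 0.5 * logdet_chol(P + Wi0)
        A <- (A0 + t(A0)) / 2; b <- b0; cc <- c0
        P <- -2 * A
      }
      if (identical(params$y0, "ML")) {
        y0hat <- drop(solve(P, b))
        loglik <- cc + 0.5 * drop(crossprod(b, y0hat))
      } else {
        y0 <- params$y0
        loglik <- drop(crossprod(y0, A %*% y0) + crossprod(b, y0)) + cc
      }
      next
    }
    W <- lt$wlen[u] * c_m * Sigma
    Wi <- tryCatch(chol2inv(chol(W)), error = function(e) NULL)
    if (is.null(Wi)) stop_singular()
    PW <- P + Wi
    G <- tryCatch(chol2inv(chol(PW)), error = function(e) NULL)
    if (is.null(G)) stop_singular()
    Anew <- -0.5 * (Wi - Wi %*% G %*% Wi)
    msg[[u]] <- list(A = (Anew + t(Anew)) / 2,
                     b = drop(Wi %*% G %*% b),
                     c = cc + 0.5 * drop(crossprod(b, G %*% b)) -
                       0.5 * logdet_chol(W) - 0.5 * logdet_chol(PW))
  }
  attr(loglik, "y0hat") <- y0hat
  loglik
}

logdet_chol <- function(S) 2 * sum(log(diag(chol(S))))

`%||%` <- function(a, b) if (is.null(a)) b else a
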