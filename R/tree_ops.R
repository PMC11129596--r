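#' Phylogenetic variance-covariance matrix
#'
#' Computes the n x n matrix `T` whose entry for taxa `u`, `w` is the
#' rate-weighted length of the path shared from the root to their most
#' recent common ancestor:
#' \deqn{t_{uw} = \sum_{z \in Path(u,w)} c_m\, b_z\, z,}
#' where `z` runs over the branch lengths on the shared path, `b_z` is the
#' relative rate of the branch and `c_m` the global evolutionary rate. The
#' diagonal entry is the full (weighted) root-to-taxon path length. Under
#' Brownian motion starting at the root, `T` (Kronecker-multiplied with the
#' among-character covariance) is the covariance of the tip observations.
#'
#' Rows and columns are ordered lexicographically by taxon label (see
#' [taxa_labels()]); sampled ancestors are sampled taxa and get rows too.
#'
#' @param tree A [time_tree].
#' @param c_m Global evolutionary rate, `> 0`.
#' @return A symmetric positive semidefinite matrix with dimnames.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' phylo_vcv(tr)  # [[2,1,0],[1,2,0],[0,0,2]]
#' @export
phylo_vcv <- function(tree, c_m = 1) {
  stopifnot(is.numeric(c_m), length(c_m) == 1, c_m > 0)
  phy <- tree$phy
  labs <- taxa_labels(tree)
  ids <- match(labs, phy$tip.label)
  # cumulative rate-weighted distance from root to every node
  d <- weighted_root_dist(tree, c_m)
  if (length(labs) == 1) {
    Tm <- matrix(d[ids], 1, 1)
  } else {
    mr <- ape::mrca(phy)        # tip x tip MRCA node ids (diag = tip)
    mr <- mr[ids, ids, drop = FALSE]
    Tm <- matrix(d[mr], nrow(mr), ncol(mr))
    diag(Tm) <- d[ids]
  }
  dimnames(Tm) <- list(labs, labs)
  Tm
}

weighted_root_dist <- function(tree, c_m = 1) {
  phy <- tree$phy
  nnode <- length(tree$ages)
  d <- numeric(nnode)
  eo <- ape::reorder.phylo(phy, "cladewise")
  len <- tree$ages[eo$edge[, 1]] - tree$ages[eo$edge[, 2]]
  w <- c_m * tree$rates[eo$edge[, 2]]
  for (i in seq_len(nrow(eo$edge)))
    d[eo$edge[i, 2]] <- d[eo$edge[i, 1]] + w[i] * len[i]
  d
}

#' Shared root-to-MRCA path length between two sampled taxa
#'
#' Equals the corresponding entry of [phylo_vcv()] with all relative rates
#' and the global rate equal to 1. `shared_path_length(tree, u, u)` is `u`'s
#' root-to-tip path length.
#'
#' @param tree A [time_tree].
#' @param u,w Tip labels.
#' @return Numeric time.
#' @export
shared_path_length <- function(tree, u, w) {
  phy <- tree$phy
  iu <- match(u, phy$tip.label)
  iw <- match(w, phy$tip.label)
  if (is.na(iu)) stop("unknown taxon label: ", u)
  if (is.na(iw)) stop("unknown taxon label: ", w)
  rates1 <- tree
  rates1$rates <- rep(1, length(tree$rates))
  d <- weighted_root_dist(rates1, 1)
  if (iu == iw) return(d[iu])
  anc <- ape::getMRCA(phy, c(iu, iw))
  d[anc]
}

#' Remove taxa from a time tree
#'
#' Drops the listed tips; resulting degree-2 nodes that are not
#' sampled-ancestor attachments are suppressed (their incident edges merged,
#' with the merged branch rate taken as the length-weighted mean). Ages of
#' all remaining nodes are unchanged, so the phylogenetic covariance of the
#' survivors equals the corresponding sub-block of the original one.
#'
#' @param tree A [time_tree].
#' @param labels Character vector of tip labels to remove (may be empty).
#' @return A [time_tree] on the remaining taxa.
#' @export
prune_taxa <- function(tree, labels) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0) return(tree)
  phy <- tree$phy
  unknown <- setdiff(labels, phy$tip.label)
  if (length(unknown))
    stop("unknown taxon label: ", paste(unknown, collapse = ", "))
  keep <- setdiff(phy$tip.label, labels)
  if (length(keep) < 2)
    stop("pruning would leave fewer than 2 tips")
  new_phy <- ape::drop.tip(phy, labels, collapse.singles = TRUE)
  # anchor ages: retained relative depths are preserved by drop.tip
  depth <- node_depths(new_phy)
  ref <- new_phy$tip.label[1]
  ref_age <- tree$ages[match(ref, phy$tip.label)]
  ages <- (ref_age + depth[match(ref, new_phy$tip.label)]) - depth
  ages[abs(ages) < 1e-9] <- 0
  # map merged-branch rates: weighted mean along the old path between the
  # old nodes matching each new edge's endpoints
  nnode_new <- length(ages)
  rates <- rep(1, nnode_new)
  if (any(tree$rates[-(n_taxa(tree) + 1L)] != 1)) {
    old_of_new <- map_nodes_by_clade(new_phy, phy)
    par_old <- parent_vec(phy)
    for (e in seq_len(nrow(new_phy$edge))) {
      ch <- new_phy$edge[e, 2]; pa <- new_phy$edge[e, 1]
      o_ch <- old_of_new[ch]; o_pa <- old_of_new[pa]
      tot_len <- 0; tot_wl <- 0
      node <- o_ch
      while (node != o_pa && node != 0) {
        l <- tree$ages[par_old[node]] - tree$ages[node]
        tot_len <- tot_len + l
        tot_wl <- tot_wl + l * tree$rates[node]
        node <- par_old[node]
      }
      rates[ch] <- if (tot_len > 0) tot_wl / tot_len else 1
    }
  }
  sa <- tree$sa[match(new_phy$tip.label, phy$tip.label)]
  time_tree(new_phy, ages = ages, rates = rates, sa = sa)
}

# for each node of `sub`, the node of `full` that is the MRCA of the same
# tip set (tips matched by label)
map_nodes_by_clade <- function(sub, full) {
  ntip_s <- length(sub$tip.label)
  nnode_s <- ntip_s + sub$Nnode
  out <- integer(nnode_s)
  out[seq_len(ntip_s)] <- match(sub$tip.label, full$tip.label)
  tipsets <- clade_tip_sets(sub)
  for (v in (ntip_s + 1L):nnode_s) {
    tips <- match(sub$tip.label[tipsets[[v]]], full$tip.label)
    out[v] <- if (length(tips) == 1) tips else ape::getMRCA(full, tips)
  }
  out
}

# list over all nodes: indices of descendant tips
clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; c <- eo$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' Maximum-clade-credibility summary tree
#'
#' Given a posterior sample of trees sharing one tip set, discards the
#' burn-in fraction, computes the posterior frequency of every clade
#' (descendant tip set), and returns the sampled tree that maximizes the
#' product of its clades' frequencies. Node ages on the winner are annotated
#' with the mean and 95%-HPD of the ages of matching clades across the
#' post-burn-in sample.
#'
#' @param trees A list of [time_tree] objects (or a `multiPhylo`-like list).
#' @param burnin_fraction Proportion of initial trees to discard, in `[0,1)`.
#' @param hpd_level Credibility level for node-age intervals.
#' @return A list with elements `tree` (the MCC [time_tree]),
#'   `log_clade_credibility`, `clade_support` (data frame: clade key,
#'   posterior probability), and `node_ages` (data frame per internal node:
#'   clade key, mean age, HPD bounds, support).
#' @export
mcc_tree <- function(trees, burnin_fraction = 0.1, hpd_level = 0.95) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1)
  n <- length(trees)
  drop <- floor(burnin_fraction * n)
  if (n - drop < 1) stop("empty post-burnin tree sample")
  trees <- trees[(drop + 1):n]
  labset <- taxa_labels(trees[[1]])
  # clade keys and ages per tree
  freq <- new.env(hash = TRUE, parent = emptyenv())
  ages_by_clade <- new.env(hash = TRUE, parent = emptyenv())
  per_tree_keys <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!identical(taxa_labels(tr), labset))
      stop("all trees must share one tip label set")
    phy <- tr$phy
    ntip <- length(phy$tip.label)
    sets <- clade_tip_sets(phy)
    keys <- character(phy$Nnode)
    for (v in seq_len(phy$Nnode)) {
      node <- ntip + v
      key <- paste(sort(phy$tip.label[sets[[node]]]), collapse = "|")
      keys[v] <- key
      freq[[key]] <- (if (is.null(freq[[key]])) 0 else freq[[key]]) + 1
      ages_by_clade[[key]] <- c(ages_by_clade[[key]], tr$ages[node])
    }
    per_tree_keys[[i]] <- keys
  }
  m <- length(trees)
  scores <- vapply(per_tree_keys, function(keys)
    sum(log(vapply(keys, function(k) freq[[k]], 0) / m)), 0)
  best <- which.max(scores)
  mcc <- trees[[best]]
  phy <- mcc$phy
  ntip <- length(phy$tip.label)
  keys <- per_tree_keys[[best]]
  supp <- vapply(keys, function(k) freq[[k]] / m, 0)
  mean_age <- numeric(length(keys)); lo <- numeric(length(keys))
  hi <- numeric(length(keys))
  for (v in seq_along(keys)) {
    a <- ages_by_clade[[keys[v]]]
    mean_age[v] <- mean(a)
    if (length(a) >= 2) {
      h <- hpd_interval(a, hpd_level)
      lo[v] <- h[1]; hi[v] <- h[2]
    } else lo[v] <- hi[v] <- a
  }
  all_keys <- ls(freq)
  list(tree = mcc,
       log_clade_credibility = scores[best],
       clade_support = data.frame(clade = all_keys,
                                  support = vapply(all_keys, function(k)
                                    freq[[k]] / m, 0),
                                  row.names = NULL),
       node_ages = data.frame(node = ntip + seq_along(keys), clade = keys,
                              support = supp, mean_age = mean_age,
                              hpd_low = lo, hpd_high = hi,
                              row.names = NULL))
}
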