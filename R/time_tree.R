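#' Time-calibrated phylogeny with heterochronous tips and sampled ancestors
#'
#' A `time_tree` wraps a rooted [ape::phylo] tree together with node ages
#' (time before present), per-branch relative rates, and sampled-ancestor
#' flags. Tips may be sampled at any age (heterochronous sampling); a fossil
#' placed as a direct ancestor of other samples (a *sampled ancestor*) is
#' represented as a tip attached to the lineage by a zero-length pendant
#' edge, the convention used by tip-dating software on disk.
#'
#' Node indices follow `ape` conventions: tips are `1..Ntip`, the root is
#' `Ntip + 1`. Ages are stored for every node; edge lengths of the
#' underlying `phylo` always equal `age(parent) - age(child)`.
#'
#' @param phy A rooted `ape::phylo` object with branch lengths in time units.
#' @param ages Optional numeric vector of node ages (time before present,
#'   `>= 0`), indexed by `ape` node id. When `NULL`, ages are derived from
#'   branch lengths with the youngest tip anchored at age 0.
#' @param rates Optional numeric vector of strictly positive relative branch
#'   rates, indexed by the *child* node of each edge (the root entry is
#'   ignored). Defaults to 1 on every branch (strict clock).
#' @param sa Optional logical vector over tips flagging sampled ancestors.
#'   When `NULL`, tips attached by a zero-length pendant edge are flagged.
#' @param sa_tol Tolerance below which a pendant edge counts as zero-length.
#'
#' @return An object of class `time_tree`: a list with elements `phy`,
#'   `ages`, `rates` and `sa`.
#' @examples
#' tr <- parse_tree("((A:1.0,B:1.0):1.0,C:2.0);")
#' root_age(tr)
#' taxa_labels(tr)
#' @seealso [parse_tree()], [phylo_vcv()], [prune_taxa()]
#' @export
time_tree <- function(phy, ages = NULL, rates = NULL, sa = NULL,
                      sa_tol = 1e-9) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  if (is.null(phy$edge.length) && is.null(ages))
    stop("branch lengths (or explicit ages) are required")
  # a basal polytomy is acceptable: require a unique structural root
  roots <- which(tabulate(phy$edge[, 2],
                          nbins = length(phy$tip.label) + phy$Nnode) == 0)
  roots <- roots[roots > length(phy$tip.label) | phy$Nnode == 0]
  if (length(roots) != 1) stop("tree must be rooted")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  if (is.null(ages)) {
    depth <- node_depths(phy)
    ages <- max(depth[seq_len(ntip)]) - depth
    ages[abs(ages) < sa_tol] <- 0
  }
  if (length(ages) != nnode) stop("`ages` must have one entry per node")
  if (is.null(rates)) rates <- rep(1, nnode)
  if (length(rates) != nnode) stop("`rates` must have one entry per node")
  # keep edge lengths consistent with ages
  par <- parent_vec(phy)
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (is.null(sa)) {
    sa <- rep(FALSE, ntip)
    pend <- ages[par[seq_len(ntip)]] - ages[seq_len(ntip)]
    sa[pend <= sa_tol] <- TRUE
  }
  if (length(sa) != ntip) stop("`sa` must have one entry per tip")
  obj <- structure(list(phy = phy, ages = as.numeric(ages),
                        rates = as.numeric(rates), sa = as.logical(sa)),
                   class = "time_tree")
  validate_time_tree(obj)
  obj
}

#' Validate the invariants of a time tree
#'
#' Checks uniqueness and non-emptiness of tip labels, strictly positive
#' branch rates, non-negative ages, and age monotonicity along edges
#' (`age(parent) > age(child)` for ordinary edges, equality for
#' sampled-ancestor attachments).
#'
#' @param tree A `time_tree`.
#' @param tol Numeric tolerance for age comparisons.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_time_tree <- function(tree, tol = 1e-9) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (any(!nzchar(phy$tip.label))) stop("tip labels must be non-empty")
  if (anyDuplicated(phy$tip.label))
    stop("tip labels must be unique: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(tree$ages < -tol)) stop("node ages must be >= 0")
  edge <- phy$edge
  rt <- tree$rates[edge[, 2]]
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("all branch relative rates must be strictly positive")
  dl <- tree$ages[edge[, 1]] - tree$ages[edge[, 2]]
  if (any(dl < -tol))
    stop("validation error: negative branch length (parent younger than child)")
  is_sa_edge <- edge[, 2] <= ntip & tree$sa[pmin(edge[, 2], ntip)]
  bad <- !is_sa_edge & dl <= tol & edge[, 2] > ntip
  if (any(bad))
    stop("zero-length internal edge not flagged as sampled ancestor")
  invisible(tree)
}

# depth (time from root) of every node, from edge lengths
node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  depth <- numeric(nnode)
  # edges in preorder: reorder guarantees parents before children
  eo <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(eo$edge))) {
    depth[eo$edge[i, 2]] <- depth[eo$edge[i, 1]] + eo$edge.length[i]
  }
  depth
}

# parent index of every node (0 for the root)
parent_vec <- function(phy) {
  ntip <- length(phy$tip.label)
  par <- integer(ntip + phy$Nnode)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf(
    "time_tree: %d sampled taxa (%d extant, %d fossil tips, %d sampled ancestors), root age %.4g\n",
    n_taxa(x), sum(x$ages[seq_len(n_taxa(x))] == 0),
    sum(x$ages[seq_len(n_taxa(x))] > 0 & !x$sa), sum(x$sa), root_age(x)))
  invisible(x)
}

#' Number of sampled taxa (tips, including sampled ancestors)
#' @param tree A `time_tree`.
#' @return Integer count.
#' @export
n_taxa <- function(tree) length(tree$phy$tip.label)

#' Sampled-taxon labels in the canonical (lexicographic) order
#'
#' All matrices keyed to taxa (phylogenetic covariance, character matrices)
#' use this ordering, which is stable across serialization round-trips.
#' @param tree A `time_tree`.
#' @return Character vector of tip labels, sorted.
#' @export
taxa_labels <- function(tree) sort(tree$phy$tip.label, method = "radix")

#' Age of the root node
#' @param tree A `time_tree`.
#' @return Numeric age (time before present).
#' @export
root_age <- function(tree) tree$ages[n_taxa(tree) + 1L]

#' Ages of the sampled taxa
#' @param tree A `time_tree`.
#' @param labels Optional subset of tip labels; default all, canonical order.
#' @return Named numeric vector of tip ages.
#' @export
tip_ages <- function(tree, labels = taxa_labels(tree)) {
  idx <- match(labels, tree$phy$tip.label)
  if (anyNA(idx)) stop("unknown taxon label: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  stats::setNames(tree$ages[idx], labels)
}

#' Count fossils placed as direct ancestors
#'
#' Returns the number of sampled-ancestor nodes: fossils attached to a
#' surviving lineage by a zero-length pendant edge rather than as tips of
#' extinct side branches.
#' @param tree A `time_tree`.
#' @return Integer count of sampled ancestors.
#' @export
count_sampled_ancestors <- function(tree) sum(tree$sa)

#' Monophyly constraint on a set of taxa
#'
#' Used by [run_chain()] to reject topology proposals that break a clade, or
#' (with `fixed_subtopology = TRUE`) to hold an entire extant subtopology
#' constant while fossil attachments are still sampled.
#'
#' @param labels Character vector of tip labels that must form a clade.
#' @param fixed_subtopology Logical; freeze the internal arrangement of
#'   `labels`, not just their monophyly.
#' @return An object of class `clade_constraint`.
#' @export
clade_constraint <- function(labels, fixed_subtopology = FALSE) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0) stop("constraint label set must be non-empty")
  structure(list(labels = labels, fixed_subtopology = isTRUE(fixed_subtopology)),
            class = "clade_constraint")
}
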