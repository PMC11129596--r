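#' Parse a Newick or NEXUS time tree
#'
#' Reads a serialized rooted tree with branch lengths in time units and
#' returns a [time_tree]. Tip ages are recovered from branch lengths, with
#' the youngest tip anchored at age 0 unless explicit dates are supplied
#' (via a sidecar table or embedded `[&age=...]` comments). Zero-length
#' terminal edges become sampled-ancestor flags.
#'
#' BEAST-style `[&...]` metadata comments in Newick input are tolerated;
#' `age` (tip date) and `rate` (relative branch rate) keys are honoured and
#' all other keys ignored. NEXUS input (including translate tables) is
#' supported with comments stripped.
#'
#' @param text A tree string, or the path of a file containing one.
#' @param dialect `"newick"` or `"nexus"`.
#' @param tip_dates Optional data frame with columns `taxon` and `age`
#'   giving absolute tip ages (the on-disk sidecar TSV format, see
#'   [read_tip_dates()]).
#' @return A [time_tree].
#' @examples
#' tr <- parse_tree("((A:1.0,B:1.0):1.0,C:2.0);")
#' tip_ages(tr)           # all 0
#' sa <- parse_tree("((A:1.0,F:0.0):1.0,C:2.0);")
#' count_sampled_ancestors(sa)  # F is a sampled ancestor at age 1
#' @export
parse_tree <- function(text, dialect = c("newick", "nexus"), tip_dates = NULL) {
  dialect <- match.arg(dialect)
  if (length(text) == 1 && !grepl("[(;]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  check_tree_syntax(text)
  meta <- list()
  if (dialect == "newick") {
    ex <- extract_newick_metadata(text)
    text <- ex$text
    meta <- ex$meta
    phy <- tryCatch(ape::read.tree(text = text),
                    error = function(e) NULL, warning = function(w) NULL)
  } else {
    text <- gsub("\\[[^]]*\\]", "", text)
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    phy <- tryCatch(ape::read.nexus(tf),
                    error = function(e) NULL, warning = function(w) NULL)
    if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("parse error: input is not a well-formed ", dialect, " tree")
  if (is.null(phy$edge.length)) stop("parse error: branch lengths are required")
  if (any(phy$edge.length < 0))
    stop("validation error: negative branch length")
  build_time_tree_from_phylo(phy, meta, tip_dates)
}

build_time_tree_from_phylo <- function(phy, meta = list(), tip_dates = NULL) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  # peel metadata markers off labels
  rates <- rep(1, nnode)
  given_age <- rep(NA_real_, ntip)
  peel <- function(labels, ids) {
    for (j in seq_along(labels)) {
      lab <- labels[j]
      m <- regmatches(lab, regexpr("@@M[0-9]+", lab))
      if (length(m) == 1 && nzchar(m)) {
        labels[j] <- sub("@@M[0-9]+", "", lab)
        kv <- meta[[m]]
        if (!is.null(kv$rate)) rates[ids[j]] <<- as.numeric(kv$rate)
        if (!is.null(kv$age) && ids[j] <= ntip)
          given_age[ids[j]] <<- as.numeric(kv$age)
      }
    }
    labels
  }
  phy$tip.label <- peel(phy$tip.label, seq_len(ntip))
  if (!is.null(phy$node.label))
    phy$node.label <- peel(phy$node.label, ntip + seq_len(phy$Nnode))
  if (!is.null(tip_dates)) {
    idx <- match(tip_dates$taxon, phy$tip.label)
    if (anyNA(idx)) stop("tip date given for unknown taxon: ",
                         paste(tip_dates$taxon[is.na(idx)], collapse = ", "))
    given_age[idx] <- tip_dates$age
  }
  depth <- node_depths(phy)
  if (any(!is.na(given_age))) {
    off <- given_age + depth[seq_len(ntip)]
    off <- off[!is.na(off)]
    if (diff(range(off)) > 1e-6)
      stop("supplied tip ages are inconsistent with branch lengths")
    ages <- mean(off) - depth
  } else {
    ages <- max(depth[seq_len(ntip)]) - depth
  }
  ages[abs(ages) < 1e-9] <- 0
  time_tree(phy, ages = ages, rates = rates)
}

# replace [&k=v,...] comments with @@Mi markers appended to the preceding
# label token, so they survive ape's parser as parts of labels
extract_newick_metadata <- function(text) {
  meta <- list()
  i <- 0
  repeat {
    m <- regexpr("\\[&[^]]*\\]", text)
    if (m == -1) break
    i <- i + 1
    com <- substr(text, m + 2, m + attr(m, "match.length") - 2)
    key <- paste0("@@M", i)
    nxt <- substr(text, m + attr(m, "match.length"),
                  m + attr(m, "match.length"))
    before <- substr(text, m - 1, m - 1)
    if (before %in% c(",", "(", ":")) {
      # comment not attached to a node label: drop it
      text <- paste0(substr(text, 1, m - 1),
                     substr(text, m + attr(m, "match.length"), nchar(text)))
      next
    }
    kv <- list()
    for (part in strsplit(com, ",", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", part, fixed = TRUE)
      if (eq > 0)
        kv[[trimws(substr(part, 1, eq - 1))]] <-
          trimws(substr(part, eq + 1, nchar(part)))
    }
    meta[[key]] <- kv
    text <- paste0(substr(text, 1, m - 1), key,
                   substr(text, m + attr(m, "match.length"), nchar(text)))
  }
  # strip any remaining (non-&) comments
  text <- gsub("\\[[^]]*\\]", "", text)
  list(text = text, meta = meta)
}

check_tree_syntax <- function(text) {
  chars <- strsplit(gsub("\\[[^]]*\\]", "", text), "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth < 0)
        stop("parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0)
    stop("parse error: ", depth, " unclosed '(' in tree string")
  invisible(TRUE)
}

#' Serialize a time tree
#'
#' Writes Newick or NEXUS with branch lengths derived from node ages, so the
#' output round-trips through [parse_tree()] with identical topology, ages
#' (within 1e-9) and sampled-ancestor flags (which become zero-length
#' terminal edges on disk). Relative branch rates are not serialized.
#'
#' @param tree A [time_tree].
#' @param path Optional file path; when `NULL` the serialization is returned
#'   as a character string.
#' @param dialect `"newick"` or `"nexus"`.
#' @return The tree string (invisibly when `path` is given).
#' @export
write_tree <- function(tree, path = NULL, dialect = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  phy <- tree$phy
  phy$edge.length <- tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]
  phy$edge.length[phy$edge.length < 0] <- 0
  phy$node.label <- NULL
  if (dialect == "newick") {
    out <- ape::write.tree(phy)
    if (!is.null(path)) {
      writeLines(out, path)
      return(invisible(out))
    }
    return(out)
  }
  tf <- if (is.null(path)) tempfile(fileext = ".nex") else path
  ape::write.nexus(phy, file = tf)
  out <- paste(readLines(tf, warn = FALSE), collapse = "\n")
  if (is.null(path)) unlink(tf)
  invisible(out)
}

#' Read a tip-date sidecar table
#'
#' The sidecar format is a two-column tab-separated file,
#' `taxon<TAB>age`, with ages in time before present. A header line is
#' optional.
#'
#' @param path File path.
#' @return Data frame with columns `taxon` (character) and `age` (numeric).
#' @export
read_tip_dates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("tip-date sidecar must have two columns")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  data.frame(taxon = as.character(df[, 1]), age = as.numeric(df[, 2]),
             stringsAsFactors = FALSE)
}
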