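#' Landmark coordinate set
#'
#' Three-dimensional landmark configurations for a set of specimens. All
#' specimens must share the landmark count; the `aligned` flag records
#' whether a Procrustes superimposition has been applied.
#'
#' @param coords A list of `L x 3` numeric matrices (one per specimen), or
#'   a 3-dimensional array `L x 3 x n`.
#' @param specimens Specimen labels.
#' @param aligned Logical flag.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, specimens = NULL, aligned = FALSE) {
  if (is.array(coords) && length(dim(coords)) == 3)
    coords <- lapply(seq_len(dim(coords)[3]), function(i) coords[, , i])
  if (!is.list(coords)) stop("`coords` must be a list or a 3-d array")
  L <- nrow(coords[[1]])
  for (m in coords) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != L)
      stop("all specimens must share an L x 3 landmark layout")
    if (any(!is.finite(m))) stop("landmark coordinates must be finite")
  }
  if (is.null(specimens)) specimens <- names(coords) %||%
      paste0("s", seq_along(coords))
  structure(list(coords = stats::setNames(coords, specimens),
                 specimens = as.character(specimens),
                 aligned = isTRUE(aligned)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d specimens x %d landmarks (3-D)%s\n",
              length(x$coords), nrow(x$coords[[1]]),
              if (x$aligned) " [aligned]" else ""))
  invisible(x)
}

#' Read the landmark TSV format
#'
#' Columns: `specimen<TAB>landmark<TAB>x<TAB>y<TAB>z` with a header row.
#' @param path File path.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sp <- unique(df[[1]])
  coords <- lapply(sp, function(s) {
    d <- df[df[[1]] == s, ]
    d <- d[order(d[[2]]), ]
    as.matrix(d[, 3:5])
  })
  landmark_set(coords, specimens = sp)
}

#' @rdname read_landmarks
#' @param lm A [landmark_set].
#' @export
write_landmarks <- function(lm, path) {
  rows <- do.call(rbind, lapply(lm$specimens, function(s) {
    m <- lm$coords[[s]]
    data.frame(specimen = s, landmark = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

center_scale_config <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs == 0) stop("degenerate landmark configuration (all coincident)")
  list(conf = m / cs, size = cs)
}

# optimal rotation (optionally with reflection) of b onto a
procrustes_rotation <- function(a, b, allow_reflection = TRUE) {
  s <- svd(crossprod(b, a))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes superimposition
#'
#' Iteratively translates every configuration to the origin, scales it to
#' unit centroid size, and rotates it onto the current mean configuration
#' until the mean changes by less than `tol` — the alignment that
#' minimizes the summed squared distances among configurations. Reflection
#' is part of the rotation group by default.
#'
#' @param specimens A [landmark_set] with at least 2 specimens.
#' @param allow_reflection Allow improper rotations.
#' @param tol Convergence tolerance on the mean configuration.
#' @param max_iter Iteration cap.
#' @return A list: `aligned` (a [landmark_set] with the flag set),
#'   `centroid_size` (per-specimen sizes before scaling), `mean_shape`,
#'   and `iterations`.
#' @export
procrustes_superimpose <- function(specimens, allow_reflection = TRUE,
                                   tol = 1e-10, max_iter = 200) {
  n <- length(specimens$coords)
  if (n < 2) stop("at least 2 specimens are required")
  cs <- lapply(specimens$coords, center_scale_config)
  confs <- lapply(cs, `[[`, "conf")
  sizes <- vapply(cs, `[[`, 0, "size")
  mean_shape <- confs[[1]]
  for (it in seq_len(max_iter)) {
    confs <- lapply(confs, function(m)
      m %*% procrustes_rotation(mean_shape, m, allow_reflection))
    new_mean <- Reduce(`+`, confs) / n
    nm <- center_scale_config(new_mean)$conf
    delta <- sqrt(sum((nm - mean_shape)^2))
    mean_shape <- nm
    if (delta < tol) break
  }
  list(aligned = landmark_set(confs, specimens = specimens$specimens,
                              aligned = TRUE),
       centroid_size = stats::setNames(sizes, specimens$specimens),
       mean_shape = mean_shape, iterations = it)
}

#' Procrustes distance between two configurations
#'
#' The square root of the summed squared landmark distances after both
#' configurations are centered, scaled to unit centroid size, and
#' optimally rotated onto each other. Zero iff the two configurations
#' have the same shape; symmetric in its arguments.
#'
#' @param a,b `L x 3` landmark matrices.
#' @param allow_reflection Allow improper rotations.
#' @return Non-negative distance.
#' @export
procrustes_distance <- function(a, b, allow_reflection = TRUE) {
  if (!identical(dim(a), dim(b))) stop("landmark counts differ")
  ca <- center_scale_config(a)$conf
  cb <- center_scale_config(b)$conf
  cb <- cb %*% procrustes_rotation(ca, cb, allow_reflection)
  sqrt(sum((ca - cb)^2))
}

#' Flatten aligned landmarks to a character matrix, normalizing variances
#'
#' Each specimen's `L x 3` configuration becomes one row of `3 L`
#' characters (x, y, z per landmark); each column is divided by the square
#' root of its supplied per-coordinate variance, the intraspecific
#' normalization applied before phylogenetic analysis.
#'
#' @param specimens An *aligned* [landmark_set].
#' @param sd2_hat Positive per-coordinate variances, length `3 L` (or 1,
#'   recycled).
#' @return A [character_matrix] with the `normalized` flag set when
#'   variances were supplied.
#' @export
flatten_and_normalize <- function(specimens, sd2_hat = 1) {
  if (!specimens$aligned)
    stop("landmarks must be superimposed before flattening")
  L <- nrow(specimens$coords[[1]])
  X <- t(vapply(specimens$coords, function(m) as.vector(t(m)),
                numeric(3 * L)))
  colnames(X) <- paste0(rep(paste0("lm", seq_len(L)), each = 3),
                        c("_x", "_y", "_z"))
  sd2_hat <- rep_len(as.numeric(sd2_hat), 3 * L)
  if (any(sd2_hat <= 0)) stop("per-coordinate variances must be > 0")
  M <- character_matrix(X, taxa = specimens$specimens,
                        characters = colnames(X))
  normalize_by_sd(M, sd2_hat)
}

stress_raw <- function(D, X) {
  d <- as.matrix(stats::dist(X))
  sum((D - d)[upper.tri(D)]^2)
}

#' Metric multidimensional scaling by stress majorization
#'
#' SMACOF-style embedding of a distance matrix into `dim` dimensions: the
#' Guttman transform decreases the (raw) metric stress
#' `sum (delta_ij - d_ij)^2` at every iteration. Several seeded starts
#' (classical scaling plus random configurations) are run and the best
#' final stress kept. Both raw and normalized
#' (`sqrt(stress / sum delta^2)`) stress values are returned.
#'
#' @param dist Symmetric matrix of dissimilarities with zero diagonal.
#' @param dim Target dimension, `>= 1`.
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of starts (the first uses classical scaling).
#' @param max_iter,tol Majorization iteration controls.
#' @return A list: `points` (n x dim), `stress` (raw), `stress1`
#'   (normalized Kruskal-type), `stress_trace` of the winning start, and
#'   `converged`.
#' @export
mds_embed <- function(dist, dim = 2, seed = 1, n_starts = 4,
                      max_iter = 500, tol = 1e-12) {
  D <- as.matrix(dist)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  if (dim < 1) stop("`dim` must be >= 1")
  set.seed(as.integer(seed))
  n <- nrow(D)
  starts <- vector("list", n_starts)
  cm <- tryCatch(suppressWarnings(stats::cmdscale(D, k = min(dim, n - 1))),
                 error = function(e) NULL)
  if (!is.null(cm)) {
    if (ncol(cm) < dim)
      cm <- cbind(cm, matrix(0, n, dim - ncol(cm)))
    starts[[1]] <- cm
  } else starts[[1]] <- matrix(stats::rnorm(n * dim), n, dim)
  for (s in seq_len(n_starts)[-1])
    starts[[s]] <- matrix(stats::rnorm(n * dim, sd = stats::sd(D)), n, dim)
  best <- NULL
  for (s in seq_len(n_starts)) {
    X <- starts[[s]]
    tr <- numeric(0)
    st <- stress_raw(D, X)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(X))
      B <- -D / pmax(d, 1e-12)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n                  # Guttman transform (V = n J)
      X <- sweep(X, 2, colMeans(X))
      st_new <- stress_raw(D, X)
      tr <- c(tr, st_new)
      if (st - st_new < tol * max(st, 1)) { conv <- TRUE; st <- st_new; break }
      st <- st_new
    }
    if (is.null(best) || st < best$stress)
      best <- list(points = X, stress = st,
                   stress1 = sqrt(st / sum(D[upper.tri(D)]^2)),
                   stress_trace = tr, converged = conv)
  }
  rownames(best$points) <- rownames(D)
  best
}
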