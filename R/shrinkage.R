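#' Within-species replicate measurement table
#'
#' Raw measurements of `k` characters on `m` individuals of one species,
#' used to estimate intraspecific variances and the among-character
#' correlation matrix.
#'
#' @param values `m x k` numeric matrix (individuals x characters).
#' @param species Single species label.
#' @param characters Optional character names.
#' @return An object of class `replicate_table`.
#' @export
replicate_table <- function(values, species = "sp", characters = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("replicate values must be numeric with no missing entries")
  if (is.null(characters)) characters <- paste0("c", seq_len(ncol(values)))
  colnames(values) <- characters
  structure(list(species = as.character(species), values = values),
            class = "replicate_table")
}

#' @export
print.replicate_table <- function(x, ...) {
  cat(sprintf("replicate_table: species %s, %d individuals x %d characters\n",
              x$species, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read the replicate TSV format
#'
#' Columns: `species<TAB>individual<TAB>char1...chark`, with a header row.
#' Only a single species per file is supported (a designated reference
#' species supplies the intraspecific estimates).
#'
#' @param path File path.
#' @return A [replicate_table].
#' @export
read_replicate_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sp <- unique(df[[1]])
  if (length(sp) != 1)
    stop("replicate table must contain a single species; found: ",
         paste(sp, collapse = ", "))
  replicate_table(as.matrix(df[, -(1:2), drop = FALSE]), species = sp,
                  characters = colnames(df)[-(1:2)])
}

#' Unbiased per-character intraspecific variances
#'
#' Sample variances with denominator `m - 1` over the individuals of the
#' replicate table; these are the `sd2_hat` used by [normalize_by_sd()].
#'
#' @param reps A [replicate_table] with at least 2 individuals.
#' @return Named numeric vector of `k` variances.
#' @export
estimate_variances <- function(reps) {
  v <- reps$values
  if (nrow(v) < 2) stop("at least 2 individuals are required")
  apply(v, 2, stats::var)
}

#' Sample among-character correlation matrix
#'
#' Pearson correlations across individuals. The estimate has rank at most
#' `m - 1`, hence is singular whenever the number of characters exceeds
#' `m - 1`; see [ridge_shrink()] for the regularization restoring
#' invertibility.
#'
#' @param reps A [replicate_table] with at least 2 individuals.
#' @return `k x k` correlation matrix.
#' @export
estimate_correlation <- function(reps) {
  v <- reps$values
  if (nrow(v) < 2) stop("at least 2 individuals are required")
  sds <- apply(v, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero variance for character ",
         paste(colnames(v)[zero], collapse = ", "))
  rho <- stats::cor(v)
  diag(rho) <- 1
  (rho + t(rho)) / 2
}

#' Linear (archetypal ridge) shrinkage of a correlation matrix
#'
#' `rho_star = delta * I + (1 - delta) * rho_hat`: a convex combination of
#' the identity target and the sample correlation. Any `delta > 0` raises
#' the minimum eigenvalue to at least
#' `delta + (1 - delta) * min_eig(rho_hat)`, restoring positive
#' definiteness when characters outnumber effective observations.
#'
#' @param rho_hat `k x k` sample correlation matrix.
#' @param delta Shrinkage weight in `[0, 1]`.
#' @return The shrunk correlation matrix `rho_star`.
#' @export
ridge_shrink <- function(rho_hat, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1)
    stop("`delta` must be a single value in [0, 1]")
  rho_hat <- as.matrix(rho_hat)
  delta * diag(nrow(rho_hat)) + (1 - delta) * rho_hat
}

#' Choose the shrinkage weight by leave-one-out cross-validation
#'
#' Deterministic grid search over `delta` in `{0.01, 0.02, ..., 0.99}`: for
#' each held-out individual, the Gaussian log-density of its measurements
#' is scored under the mean, variances and shrunk correlation estimated
#' from the remaining individuals; the `delta` with the highest summed
#' score wins (ties break toward more shrinkage). The selected
#' `rho_star(delta)` is always invertible.
#'
#' @param reps A [replicate_table] with at least 3 individuals.
#' @param grid Candidate `delta` values in `(0, 1]`.
#' @return A list of class `shrinkage_result` with elements `rho_hat`,
#'   `delta`, `rho_star`, `sd2_hat` and the per-delta CV score table.
#' @export
choose_delta <- function(reps, grid = seq(0.01, 0.99, by = 0.01)) {
  v <- reps$values
  m <- nrow(v); k <- ncol(v)
  if (m < 3) stop("at least 3 individuals are required for cross-validation")
  if (any(grid <= 0 | grid > 1)) stop("grid values must lie in (0, 1]")
  sd2_hat <- estimate_variances(reps)
  if (all(apply(v, 2, stats::sd) == 0) ||
      all(apply(v, 1, function(r) all(r == v[1, ])))) {
    warning("degenerate replicate data (all individuals identical); delta = 1")
    return(shrinkage_result(diag(k), 1, sd2_hat, colnames(v),
                            data.frame(delta = 1, score = NA_real_)))
  }
  rho_hat <- estimate_correlation(reps)
  scores <- vapply(grid, function(d) {
    s <- 0
    for (i in seq_len(m)) {
      vi <- v[-i, , drop = FALSE]
      sds <- apply(vi, 2, stats::sd)
      if (any(sds == 0)) return(-Inf)
      rh <- suppressWarnings(stats::cor(vi))
      rh[!is.finite(rh)] <- 0
      diag(rh) <- 1
      rs <- ridge_shrink(rh, d)
      Sg <- diag(sds, k) %*% rs %*% diag(sds, k)
      R <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(R)) return(-Inf)
      z <- backsolve(R, v[i, ] - colMeans(vi), transpose = TRUE)
      s <- s - 0.5 * (k * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
    }
    s
  }, 0)
  best <- grid[which(scores == max(scores))]
  delta <- max(best)                       # deterministic tie-break
  shrinkage_result(rho_hat, delta, sd2_hat, colnames(v),
                   data.frame(delta = grid, score = scores))
}

shrinkage_result <- function(rho_hat, delta, sd2_hat, characters, cv) {
  structure(list(rho_hat = rho_hat, delta = delta,
                 rho_star = ridge_shrink(rho_hat, delta),
                 sd2_hat = sd2_hat, characters = characters, cv = cv),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("shrinkage_result: k = %d, delta = %.2f\n",
              ncol(x$rho_star), x$delta))
  invisible(x)
}

#' One-call shrinkage estimation from replicates
#'
#' Convenience wrapper: estimates variances and the sample correlation,
#' selects `delta` by cross-validation and returns the shrunk correlation.
#'
#' @param reps A [replicate_table].
#' @return A `shrinkage_result` (see [choose_delta()]).
#' @export
shrink_correlation <- function(reps) choose_delta(reps)
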