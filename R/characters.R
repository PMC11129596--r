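#' Continuous character matrix
#'
#' An `n x k` matrix of continuous trait values (taxa in rows, characters in
#' columns) keyed to the sampled taxa of a [time_tree]. The `normalized`
#' attribute records whether columns have been divided by intraspecific
#' standard deviations (see [normalize_by_sd()]), in which case the
#' intraspecific covariance reduces to the character correlation matrix.
#'
#' @param values Numeric matrix (or coercible) with no missing values.
#' @param taxa Row labels; defaults to `rownames(values)`.
#' @param characters Column labels; defaults to `colnames(values)` or
#'   `c1..ck`.
#' @param normalized Logical flag.
#' @return An object of class `character_matrix` (a numeric matrix with
#'   dimnames and a `normalized` attribute).
#' @export
character_matrix <- function(values, taxa = rownames(values),
                             characters = colnames(values),
                             normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("character values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite character values are not supported")
  if (is.null(taxa)) stop("taxa labels are required")
  if (anyDuplicated(taxa)) stop("taxa labels must be unique")
  if (is.null(characters)) characters <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(taxa), as.character(characters))
  structure(values, normalized = isTRUE(normalized),
            class = c("character_matrix", "matrix", "array"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read / write the character-matrix TSV format
#'
#' The on-disk format is tab-separated with a header row of character names;
#' the first column holds taxon labels.
#'
#' @param path File path.
#' @return For `read_character_matrix`, a [character_matrix].
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  character_matrix(as.matrix(df[, -1, drop = FALSE]), taxa = df[[1]],
                   characters = colnames(df)[-1])
}

#' @rdname read_character_matrix
#' @param m A [character_matrix].
#' @export
write_character_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brownian-motion model parameters for continuous characters
#'
#' Bundles the parameters of the multivariate phylogenetic Brownian model:
#' per-character relative rates `r` and correlation `corr` (giving the
#' among-character covariance `Sigma = diag(r) %*% corr %*% diag(r)`), or
#' alternatively an upper-triangular factor `L` with `Sigma = L %*% t(L)`;
#' the global rate `c_m`; root character values `y0` (a numeric vector, or
#' `"ML"` to profile them out at their maximum-likelihood values); and the
#' intraspecific (tip) covariance, given either as per-character standard
#' deviations `sigma_intra` (combined with `corr` as
#' `diag(sigma) %*% corr %*% diag(sigma)`) or as a full matrix `v_err`.
#'
#' @param r Positive numeric vector of relative character rates (recycled to
#'   length `k` when scalar). Ignored when `L` is given.
#' @param corr `k x k` correlation matrix (symmetric, unit diagonal, entries
#'   in `[-1, 1]`). Exactly one of `corr` and `L` must be supplied.
#' @param L `k x k` upper-triangular factor with positive diagonal.
#' @param c_m Global evolutionary rate, `> 0`.
#' @param y0 Numeric vector of root values, or `"ML"`.
#' @param sigma_intra Non-negative per-character intraspecific SDs
#'   (scalar recycled), or `NULL`.
#' @param v_err Full `k x k` intraspecific covariance (overrides
#'   `sigma_intra`), or `NULL` for none.
#' @param k Number of characters; inferred when possible.
#' @return An object of class `bm_params`.
#' @examples
#' p <- bm_params(r = c(2, 3), corr = matrix(c(1, .5, .5, 1), 2), y0 = c(0, 0))
#' build_sigma(p$r, p$corr)
#' @export
bm_params <- function(r = 1, corr = NULL, L = NULL, c_m = 1, y0 = "ML",
                      sigma_intra = NULL, v_err = NULL, k = NULL) {
  if (is.null(corr) == is.null(L))
    stop("exactly one of `corr` and `L` must be supplied")
  if (!is.null(L)) {
    Sigma <- sigma_from_factor(L)
    k <- ncol(L)
    r <- sqrt(diag(Sigma))
    corr <- Sigma / tcrossprod(r)
    diag(corr) <- 1
  } else {
    corr <- as.matrix(corr)
    if (is.null(k)) k <- ncol(corr)
    r <- rep_len(r, k)
    Sigma <- build_sigma(r, corr)
  }
  stopifnot(is.numeric(c_m), length(c_m) == 1, c_m > 0)
  if (!identical(y0, "ML")) {
    y0 <- as.numeric(y0)
    if (length(y0) == 1) y0 <- rep(y0, k)
    if (length(y0) != k) stop("`y0` must have one value per character")
  }
  if (is.null(v_err)) {
    if (!is.null(sigma_intra)) {
      sigma_intra <- rep_len(as.numeric(sigma_intra), k)
      if (any(sigma_intra < 0)) stop("`sigma_intra` must be >= 0")
      v_err <- diag(sigma_intra, k) %*% corr %*% diag(sigma_intra, k)
    } else {
      v_err <- matrix(0, k, k)
    }
  } else {
    v_err <- as.matrix(v_err)
    if (!isTRUE(all.equal(v_err, t(v_err), tolerance = 1e-8)))
      stop("`v_err` must be symmetric")
    if (nrow(v_err) != k) stop("`v_err` must be k x k")
  }
  structure(list(r = r, corr = corr, L = L, Sigma = Sigma, c_m = c_m,
                 y0 = y0, sigma_intra = sigma_intra,
                 v_err = (v_err + t(v_err)) / 2, k = k),
            class = "bm_params")
}

#' Among-character covariance from rates and correlations
#'
#' `Sigma = diag(r) %*% corr %*% diag(r)`, so `Sigma[i,i] = r[i]^2` and
#' `Sigma[i,j] = r[i] r[j] corr[i,j]`. With all relative rates equal to 1,
#' `Sigma` equals the correlation matrix itself.
#'
#' @param r Positive numeric vector of relative character rates.
#' @param corr Correlation matrix (symmetric, unit diagonal).
#' @return The `k x k` covariance matrix.
#' @export
build_sigma <- function(r, corr) {
  corr <- as.matrix(corr)
  k <- ncol(corr)
  r <- rep_len(as.numeric(r), k)
  if (any(r <= 0)) stop("relative rates must be > 0")
  if (nrow(corr) != k) stop("`corr` must be square")
  if (any(abs(diag(corr) - 1) > 1e-8))
    stop("validation error: correlation matrix must have unit diagonal")
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("validation error: correlation matrix must be symmetric")
  if (any(corr < -1 - 1e-8 | corr > 1 + 1e-8))
    stop("validation error: correlations must lie in [-1, 1]")
  out <- diag(r, k) %*% corr %*% diag(r, k)
  (out + t(out)) / 2
}

#' Among-character covariance from an upper-triangular factor
#'
#' `Sigma = L %*% t(L)`. Parameterizing the MCMC in terms of `L` guarantees
#' a positive-definite `Sigma` for any `L` with non-zero diagonal; the rates
#' are recovered afterwards as `sqrt(diag(Sigma))` and the correlations by
#' rescaling `Sigma` to unit diagonal.
#'
#' @param L Upper-triangular `k x k` matrix with non-zero diagonal.
#' @return The `k x k` positive definite covariance matrix.
#' @export
sigma_from_factor <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("`L` must be square")
  if (any(abs(L[lower.tri(L)]) > 1e-12))
    stop("`L` must be upper-triangular")
  if (any(diag(L) == 0)) stop("singular covariance: zero diagonal in `L`")
  tcrossprod(L)
}

#' Add intraspecific variance to a dense phylogenetic covariance
#'
#' Adds the `k x k` intraspecific covariance `verr` to each taxon's own
#' diagonal block of the `nk x nk` trait covariance `V` (taxon-major
#' layout, `V = T %x% Sigma`), leaving between-taxon blocks untouched.
#'
#' @param V `nk x nk` covariance matrix in taxon-major order.
#' @param verr Symmetric positive semidefinite `k x k` matrix.
#' @return The updated covariance `V'`.
#' @export
apply_intraspecific <- function(V, verr) {
  verr <- as.matrix(verr)
  k <- nrow(verr)
  if (!isTRUE(all.equal(verr, t(verr), tolerance = 1e-8)))
    stop("`verr` must be symmetric")
  if (nrow(V) %% k != 0)
    stop("dimension mismatch: nrow(V) is not a multiple of nrow(verr)")
  n <- nrow(V) %/% k
  ev <- eigen(verr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("`verr` must be PSD")
  V + diag(n) %x% verr
}

#' Normalize characters by intraspecific standard deviations
#'
#' Divides character `i` by `sqrt(sd2_hat[i])`, producing the normalized
#' matrix for which unit intraspecific variances hold and the tip-error
#' covariance reduces to the character correlation matrix.
#'
#' @param M A [character_matrix].
#' @param sd2_hat Positive per-character variance estimates (length `k`).
#' @return A [character_matrix] with the `normalized` flag set.
#' @export
normalize_by_sd <- function(M, sd2_hat) {
  sd2_hat <- as.numeric(sd2_hat)
  if (length(sd2_hat) != ncol(M))
    stop("`sd2_hat` must have one variance per character")
  zero <- which(sd2_hat <= 0)
  if (length(zero))
    stop("zero variance for character ",
         paste(colnames(M)[zero], collapse = ", "))
  character_matrix(sweep(unclass(M), 2, sqrt(sd2_hat), "/"),
                   taxa = rownames(M), characters = colnames(M),
                   normalized = TRUE)
}
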