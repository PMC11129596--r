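#' Highest-posterior-density interval
#'
#' The shortest contiguous window of the sorted sample containing
#' `ceiling(level * N)` points. For multimodal samples this is the usual
#' sample-based approximation to the HPD region by a single interval.
#'
#' @param samples Numeric vector with at least one value.
#' @param level Credibility level in `(0, 1)`.
#' @return Numeric `c(low, high)`.
#' @examples
#' hpd_interval(1:100, 0.95)   # width 94
#' @export
hpd_interval <- function(samples, level = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty sample")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)")
  n <- length(samples)
  m <- ceiling(level * n)
  s <- sort(samples)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 * sum(acf))` with the autocorrelation sum truncated at the
#' first non-positive pair sum (Geyer's initial positive-sequence rule),
#' so the estimate is capped at `N` and robust to noisy tails. For i.i.d.
#' input ESS is close to `N`.
#'
#' @param samples Numeric vector of at least 10 values.
#' @return Effective sample size (scalar).
#' @export
ess <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 10) stop("at least 10 samples are required")
  v <- stats::var(samples)
  if (v == 0) return(1)
  ac <- stats::acf(samples, lag.max = n - 2, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # pair sums rho[2t] + rho[2t+1], lags starting at 1
  s <- 0
  t <- 2                      # ac[1] is lag 0
  while (t + 1 <= length(ac)) {
    pair <- ac[t] + ac[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  out <- n / (1 + 2 * s)
  min(out, n)
}

#' Posterior trace container
#'
#' A data frame of sampled scalar parameters (one row per retained MCMC
#' sample, fixed stride), plus optional serialized trees and provenance
#' (seed, configuration) attributes.
#'
#' @param samples Data frame with a `Sample` column and parameter columns.
#' @param trees Optional character vector of Newick strings, same length.
#' @param seed,config Provenance.
#' @return An object of class `tm_trace`.
#' @export
tm_trace <- function(samples, trees = NULL, seed = NA_integer_, config = list()) {
  stopifnot(is.data.frame(samples), "Sample" %in% names(samples))
  if (!is.null(trees) && length(trees) != nrow(samples))
    stop("one tree per sample row is required")
  structure(list(samples = samples, trees = trees, seed = seed,
                 config = config), class = "tm_trace")
}

#' @export
print.tm_trace <- function(x, ...) {
  cat(sprintf("tm_trace: %d samples x %d columns%s\n", nrow(x$samples),
              ncol(x$samples),
              if (!is.null(x$trees)) " (+trees)" else ""))
  invisible(x)
}

#' Discard burn-in from a trace
#' @param trace A [tm_trace].
#' @param fraction Proportion of initial samples to drop (default 10%).
#' @return A [tm_trace].
#' @export
trace_burnin <- function(trace, fraction = 0.1) {
  n <- nrow(trace$samples)
  drop <- floor(fraction * n)
  keep <- (drop + 1):n
  tm_trace(trace$samples[keep, , drop = FALSE],
           trees = trace$trees[keep], seed = trace$seed, config = trace$config)
}

#' Write a trace as a BEAST-style tab-delimited log (plus NEXUS trees)
#'
#' @param trace A [tm_trace].
#' @param path Log file path; trees (if any) go to `paste0(path, ".trees")`
#'   unless `trees_path` is given.
#' @param trees_path Optional path for the NEXUS trees file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, trees_path = NULL) {
  utils::write.table(trace$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trace$trees)) {
    if (is.null(trees_path)) trees_path <- paste0(path, ".trees")
    con <- file(trees_path, "w")
    writeLines("#NEXUS", con)
    writeLines("begin trees;", con)
    for (i in seq_along(trace$trees))
      writeLines(sprintf("tree STATE_%d = %s",
                         trace$samples$Sample[i], trace$trees[i]), con)
    writeLines("end;", con)
    close(con)
  }
  prov <- list(seed = trace$seed, config = trace$config)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
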