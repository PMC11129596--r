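#' Prior distribution constructors
#'
#' Small named prior objects used in a [prior_spec]. Every sampled
#' parameter gets exactly one prior; densities are evaluated in log space.
#' `prior_fixed` pins a parameter at a constant (it is then not sampled).
#'
#' @param meanlog,sdlog Log-space mean and standard deviation.
#' @return An object of class `tm_prior`.
#' @export
prior_lognormal <- function(meanlog = 0, sdlog = 1)
  new_prior("lognormal", meanlog = meanlog, sdlog = sdlog)

#' @rdname prior_lognormal
#' @param mean,sd Mean and standard deviation.
#' @export
prior_normal <- function(mean = 0, sd = 1) new_prior("normal", mean = mean, sd = sd)

#' @rdname prior_lognormal
#' @param min,max Bounds.
#' @export
prior_uniform <- function(min = 0, max = 1) new_prior("uniform", min = min, max = max)

#' @rdname prior_lognormal
#' @param rate Rate parameter.
#' @export
prior_exponential <- function(rate = 1) new_prior("exponential", rate = rate)

#' @rdname prior_lognormal
#' @param lower,upper Truncation bounds.
#' @export
prior_truncnormal <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf)
  new_prior("truncnormal", mean = mean, sd = sd, lower = lower, upper = upper)

#' @rdname prior_lognormal
#' @param value Fixed value.
#' @export
prior_fixed <- function(value) new_prior("fixed", value = value)

new_prior <- function(dist, ...) {
  structure(list(dist = dist, par = list(...)), class = "tm_prior")
}

#' @export
print.tm_prior <- function(x, ...) {
  cat("prior:", x$dist, "(",
      paste(names(x$par), unlist(x$par), sep = " = ", collapse = ", "), ")\n")
  invisible(x)
}

is_fixed_prior <- function(p) is.null(p) || identical(p$dist, "fixed")

#' Log prior density
#' @param prior A `tm_prior`.
#' @param x Value(s).
#' @return Log density (vectorized over `x`).
#' @export
prior_logdens <- function(prior, x) {
  p <- prior$par
  switch(prior$dist,
    lognormal = stats::dlnorm(x, p$meanlog, p$sdlog, log = TRUE),
    normal = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    uniform = stats::dunif(x, p$min, p$max, log = TRUE),
    exponential = stats::dexp(x, p$rate, log = TRUE),
    truncnormal = {
      z <- stats::pnorm(p$upper, p$mean, p$sd) - stats::pnorm(p$lower, p$mean, p$sd)
      ifelse(x < p$lower | x > p$upper, -Inf,
             stats::dnorm(x, p$mean, p$sd, log = TRUE) - log(z))
    },
    fixed = ifelse(x == p$value, 0, -Inf),
    stop("unknown prior distribution: ", prior$dist))
}

#' Draw from a prior
#' @param prior A `tm_prior`.
#' @param n Number of draws.
#' @return Numeric vector.
#' @export
prior_draw <- function(prior, n = 1) {
  p <- prior$par
  switch(prior$dist,
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    normal = stats::rnorm(n, p$mean, p$sd),
    uniform = stats::runif(n, p$min, p$max),
    exponential = stats::rexp(n, p$rate),
    truncnormal = {
      lo <- stats::pnorm(p$lower, p$mean, p$sd)
      hi <- stats::pnorm(p$upper, p$mean, p$sd)
      stats::qnorm(stats::runif(n, lo, hi), p$mean, p$sd)
    },
    fixed = rep(p$value, n),
    stop("unknown prior distribution: ", prior$dist))
}

# exact moments, used by the prior-sampling validation
prior_moments <- function(prior) {
  p <- prior$par
  switch(prior$dist,
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      list(mean = m, var = (exp(p$sdlog^2) - 1) * m^2)
    },
    normal = list(mean = p$mean, var = p$sd^2),
    uniform = list(mean = (p$min + p$max) / 2, var = (p$max - p$min)^2 / 12),
    exponential = list(mean = 1 / p$rate, var = 1 / p$rate^2),
    stop("moments not implemented for: ", prior$dist))
}

#' Prior specification for the integrative model
#'
#' Collects the priors on the free parameters of the posterior restricted
#' to continuous morphology: the global morphological clock rate `c_m`
#' (log-normal by convention), per-branch relative rates (`NULL` for a
#' strict clock with all rates 1, or a log-normal for i.i.d. relaxed
#' rates), root values `y0` (`"ML"` to profile, or a normal prior), the
#' upper-triangular factor elements (`L_diag`, `L_offdiag`) when the
#' among-character covariance is estimated, and the tree-process rates.
#' `tree_model` selects the FBD or BDSS prior on the tree.
#'
#' @param c_m Prior on the global evolutionary rate.
#' @param lambda,mu,psi Priors (or `prior_fixed`) on the tree-process rates.
#' @param p_extant Prior on the extant sampling probability.
#' @param origin_time Prior (usually `prior_fixed`) on the origin age.
#' @param branch_rates `NULL` (strict clock) or a log-normal prior for
#'   i.i.d. per-branch relative rates.
#' @param y0 `"ML"`, or a normal prior applied i.i.d. to each root value.
#' @param L_diag,L_offdiag Priors on the factor elements, or `NULL` when
#'   the correlation structure is fixed.
#' @param tree_model `"fbd"` or `"bdss"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(c_m = prior_lognormal(0, 1),
                       lambda = prior_fixed(1),
                       mu = prior_fixed(0),
                       psi = prior_fixed(0),
                       p_extant = prior_fixed(1),
                       origin_time = prior_fixed(NA_real_),
                       branch_rates = NULL,
                       y0 = "ML",
                       L_diag = NULL, L_offdiag = NULL,
                       tree_model = c("fbd", "bdss")) {
  structure(list(c_m = c_m, lambda = lambda, mu = mu, psi = psi,
                 p_extant = p_extant, origin_time = origin_time,
                 branch_rates = branch_rates, y0 = y0,
                 L_diag = L_diag, L_offdiag = L_offdiag,
                 tree_model = match.arg(tree_model)),
            class = "prior_spec")
}
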