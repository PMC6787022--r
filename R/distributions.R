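#' Specify a jump-length or waiting-time distribution
#'
#' Builds a validated distribution specification used by
#' [motility_params()] for the jump-length (micrometre) and waiting-time
#' (second) marginals of the run-and-tumble generator. All families are
#' sampled by inversion, which is what makes the Gaussian-copula lag-1
#' correlation scheme of [generate_trajectories()] exact.
#'
#' Supported families:
#' \describe{
#'   \item{`"lognormal"`}{parameters `meanlog`, `sdlog`, optional upper
#'     truncation `max`. The default jump marginal uses this family with a
#'     mode near 5.5 um and a hard maximum of 100 um.}
#'   \item{`"pareto"`}{truncated Pareto with parameters `xmin` (scale),
#'     `alpha` (tail exponent) and `max` (upper truncation, required).
#'     Heavy-tailed; the default waiting-time marginal.}
#'   \item{`"exponential"`}{parameter `rate`, optional `max`.}
#'   \item{`"degenerate"`}{point mass at `value`; useful for exact
#'     oracle tests.}
#' }
#'
#' @param family Character, one of `"lognormal"`, `"pareto"`,
#'   `"exponential"`, `"degenerate"`.
#' @param ... Named numeric parameters of the family (see Details).
#' @return An object of class `dist_spec`.
#' @examples
#' js <- dist_spec("lognormal", meanlog = log(5.5) + 0.81, sdlog = 0.9, max = 100)
#' quantile_dist(c(.25, .5, .75), js)
#' @export
dist_spec <- function(family = c("lognormal", "pareto", "exponential", "degenerate"),
                      ...) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    lognormal   = c("meanlog", "sdlog"),
    pareto      = c("xmin", "alpha", "max"),
    exponential = "rate",
    degenerate  = "value"
  )
  missing <- setdiff(need, names(pars))
  if (length(missing) > 0L) {
    stop("dist_spec('", family, "') requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (family == "pareto" && (pars$xmin <= 0 || pars$alpha <= 0 || pars$max <= pars$xmin)) {
    stop("pareto requires xmin > 0, alpha > 0, max > xmin", call. = FALSE)
  }
  if (family == "exponential" && pars$rate <= 0) {
    stop("exponential requires rate > 0", call. = FALSE)
  }
  if (family == "degenerate" && pars$value <= 0) {
    stop("degenerate requires value > 0", call. = FALSE)
  }
  if (!is.null(pars$max) && pars$max <= 0) stop("max must be > 0", call. = FALSE)
  structure(c(list(family = family), pars), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<dist_spec> ", x$family, "(",
      paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Quantile function of a distribution specification
#'
#' Inverse CDF used both for plain sampling and for rank-based (Gaussian
#' copula) correlated sampling. Upper truncation at `max` is implemented
#' by inversion restricted to `[0, F(max)]`, so truncated samples remain a
#' monotone transform of the uniforms.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param spec A [dist_spec()].
#' @return Numeric vector of quantiles (strictly positive).
#' @export
quantile_dist <- function(p, spec) {
  stopifnot(inherits(spec, "dist_spec"), all(p >= 0 & p <= 1))
  switch(spec$family,
    lognormal = {
      pmax_ <- if (is.null(spec$max)) 1 else
        stats::plnorm(spec$max, spec$meanlog, spec$sdlog)
      stats::qlnorm(p * pmax_, spec$meanlog, spec$sdlog)
    },
    exponential = {
      pmax_ <- if (is.null(spec$max)) 1 else stats::pexp(spec$max, spec$rate)
      stats::qexp(p * pmax_, spec$rate)
    },
    pareto = {
      # truncated Pareto: F(x) = (1 - (xmin/x)^alpha) / (1 - (xmin/max)^alpha)
      z <- 1 - (spec$xmin / spec$max)^spec$alpha
      spec$xmin * (1 - p * z)^(-1 / spec$alpha)
    },
    degenerate = rep(spec$value, length(p))
  )
}

#' Draw independent samples from a distribution specification
#'
#' @param n Number of samples.
#' @param spec A [dist_spec()].
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(n, spec) {
  quantile_dist(stats::runif(n), spec)
}

#' Upper support bound of a distribution specification
#' @param spec A [dist_spec()].
#' @return The configured maximum (`Inf` when untruncated).
#' @export
dist_max <- function(spec) {
  if (!is.null(spec$max)) return(spec$max)
  if (spec$family == "degenerate") return(spec$value)
  Inf
}

# Mean/variance and lag-1 Pearson correlation of X = Q(Phi(Z)) under a
# bivariate-normal (Z1, Z2) with correlation rho_z, by Gauss-Hermite
# quadrature. Used to calibrate the copula so the *Pearson* correlation of
# the generated jump/wait series equals the requested value.
.gh_nodes <- function(n = 120) {
  gh <- pracma::gaussHermite(n)
  # convert physicists' rule (weight e^{-x^2}) to standard-normal expectation
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

.dist_moments_gh <- function(spec, gh = .gh_nodes()) {
  x <- quantile_dist(stats::pnorm(gh$z), spec)
  m <- sum(gh$w * x)
  v <- sum(gh$w * (x - m)^2)
  list(mean = m, var = v, x = x)
}

.pearson_given_rhoz <- function(rho_z, spec, gh = .gh_nodes()) {
  mom <- .dist_moments_gh(spec, gh)
  if (mom$var <= 0) return(0)
  s <- sqrt(pmax(1 - rho_z^2, 0))
  # E[X1 X2] with Z2 = rho*Z1 + s*Z2'
  exy <- 0
  for (i in seq_along(gh$z)) {
    z2 <- rho_z * gh$z[i] + s * gh$z
    x2 <- quantile_dist(stats::pnorm(z2), spec)
    exy <- exy + gh$w[i] * mom$x[i] * sum(gh$w * x2)
  }
  (exy - mom$mean^2) / mom$var
}

#' Calibrate the Gaussian-copula parameter for a target Pearson correlation
#'
#' The run-and-tumble generator imposes lag-1 dependence between successive
#' jump lengths (or waiting times) through a stationary AR(1) Gaussian
#' series pushed through the marginal's quantile function. Because the
#' marginal transform distorts correlation, the latent AR(1) coefficient is
#' calibrated numerically (Gauss-Hermite quadrature + root finding) so the
#' Pearson lag-1 correlation of the *transformed* series equals `rho`.
#'
#' Not every Pearson correlation is attainable for a given marginal: a
#' strongly skewed, heavy-tailed marginal bounds the correlation away from
#' -1 (and from +1), because Pearson correlation is not invariant under
#' the marginal transform. Targets outside the attainable interval raise
#' an error reporting that interval.
#'
#' @param rho Target Pearson lag-1 correlation in `(-1, 1)`.
#' @param spec Marginal [dist_spec()] (non-degenerate).
#' @return The latent Gaussian correlation to use in the AR(1) driver.
#' @export
calibrate_copula_rho <- function(rho, spec) {
  stopifnot(abs(rho) < 1)
  if (rho == 0) return(0)
  if (spec$family == "degenerate") {
    stop("correlation is undefined for a degenerate marginal", call. = FALSE)
  }
  gh <- .gh_nodes()
  lo <- .pearson_given_rhoz(-0.999, spec, gh)
  hi <- .pearson_given_rhoz(0.999, spec, gh)
  if (rho <= lo || rho >= hi) {
    stop(sprintf(
      "correlation %.3g is not attainable for this marginal (range %.3g to %.3g)",
      rho, lo, hi), call. = FALSE)
  }
  f <- function(a) .pearson_given_rhoz(a, spec, gh) - rho
  stats::uniroot(f, lower = -0.999, upper = 0.999, tol = 1e-6)$root
}

# Stationary AR(1) Gaussian driver pushed through the marginal quantile.
# Returns samples plus the final latent state so a chain can be extended.
.draw_correlated <- function(n, spec, rho_z, z_last = NULL) {
  if (n == 0L) return(list(x = numeric(0), z_last = z_last))
  eps <- stats::rnorm(n)
  z <- numeric(n)
  if (rho_z == 0) {
    z <- eps
  } else {
    s <- sqrt(1 - rho_z^2)
    prev <- if (is.null(z_last)) stats::rnorm(1) else z_last
    for (i in seq_len(n)) {
      z[i] <- if (i == 1L && is.null(z_last)) prev else rho_z * prev + s * eps[i]
      prev <- z[i]
    }
  }
  list(x = quantile_dist(stats::pnorm(z), spec), z_last = z[n])
}
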