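#' Time-varying diffusion coefficient from the variance growth
#'
#' Estimates `D(t) = 0.5 * d(sigma^2)/dt` by central finite differences of
#' the ensemble variance with respect to time (one-sided at the ends),
#' optionally after moving-average smoothing of the variance series. Under
#' Fickian (linear-in-time) variance growth the estimate is constant;
#' super-Fickian growth yields a rising `D(t)`. Negative finite-difference
#' estimates — possible when the variance series is noisy — are floored at
#' zero and counted in a message. Beyond the last observed time `D` is
#' held constant at its final in-range value, the value computed for the
#' longest recorded trajectories.
#'
#' Note the variance convention: with the radial (2-D) variance of
#' [ensemble_moments()], a Brownian ensemble with per-axis diffusion `D0`
#' has `sigma^2 = 4 * D0 * t`, so this estimator returns `2 * D0`.
#'
#' @param moments An [ensemble_moments()] tibble with at least 3 rows and
#'   strictly increasing times.
#' @param smooth_window Odd moving-average window length on the variance
#'   (1 = no smoothing).
#' @return Tibble `(t_s, D_um2_s)` with attribute `D_const_tail`, the
#'   value held constant beyond the observation window.
#' @export
diffusion_coefficient <- function(moments, smooth_window = 1) {
  if (nrow(moments) < 3L) stop("need at least 3 moment time points", call. = FALSE)
  t <- moments$t_s
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  v <- moments$var_um2
  if (smooth_window > 1) {
    k <- smooth_window + (smooth_window %% 2 == 0)  # force odd
    sm <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  D <- 0.5 * pracma::gradient(v, t)
  n_neg <- sum(D < 0)
  if (n_neg > 0) {
    message(n_neg, " negative diffusion estimate(s) floored at 0")
    D <- pmax(D, 0)
  }
  out <- tibble::tibble(t_s = t, D_um2_s = D)
  attr(out, "D_const_tail") <- D[length(D)]
  out
}

#' Parameters of the advection-diffusion breakthrough model
#'
#' @param V Average (drift) velocity, micrometres per second, from the
#'   slope of the mean displacement over time ([drift_speed()]).
#' @param D Diffusion coefficient: a single non-negative number, or a
#'   `(t_s, D_um2_s)` tibble from [diffusion_coefficient()] for the
#'   time-varying case (held constant beyond its last time).
#' @param radii Control-plane distances `L`, micrometres.
#' @return An object of class `ade_params`.
#' @export
ade_params <- function(V, D, radii) {
  stopifnot(V >= 0, all(radii > 0))
  if (is.data.frame(D)) {
    stopifnot(all(c("t_s", "D_um2_s") %in% names(D)), all(D$D_um2_s >= 0))
  } else {
    stopifnot(is.numeric(D), length(D) == 1L, D >= 0)
  }
  structure(list(V = V, D = D, radii = radii), class = "ade_params")
}

.erfc <- function(x) pracma::erfc(x)

.D_at <- function(D, t) {
  if (is.data.frame(D)) {
    stats::approx(D$t_s, D$D_um2_s, xout = t, rule = 2)$y
  } else {
    rep(D, length(t))
  }
}

#' Advection-diffusion breakthrough curves
#'
#' Evaluates the one-dimensional semi-infinite ADE solution
#' `C/C0 = 0.5 * erfc((L - V t) / (2 sqrt(D t)))` pointwise on a time
#' grid, with `D = D(t)` interpolated from the supplied series (held
#' constant beyond its range). The solution is applied radially, with `L`
#' the control radius — a deliberate approximation inherited from treating
#' radial spreading with the planar solution. This is a resident- rather
#' than strict first-passage concentration, which is exactly how the
#' breakthrough comparison uses it.
#'
#' The arrival-time density is the numerical time derivative of `C/C0`,
#' floored at zero (a time-varying `D` can make the raw derivative locally
#' negative) and rescaled to integrate to the window recovery; arrival
#' moments are density-weighted over the evaluation horizon.
#'
#' @param params An [ade_params()].
#' @param times Strictly positive, increasing evaluation grid, seconds
#'   (`t = 0` is excluded since the solution divides by `sqrt(t)`).
#' @return Named list of `breakthrough_curve` objects (density form), one
#'   per control radius.
#' @export
ade_breakthrough <- function(params, times) {
  stopifnot(inherits(params, "ade_params"))
  if (any(times <= 0)) stop("time grid must be strictly positive", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be increasing", call. = FALSE)
  Dt <- .D_at(params$D, times)
  out <- list()
  for (L in params$radii) {
    arg <- (L - params$V * times) / (2 * sqrt(pmax(Dt * times, .Machine$double.eps)))
    C <- 0.5 * .erfc(arg)
    dens <- pracma::gradient(C, times)
    dens <- pmax(dens, 0)
    area <- pracma::trapz(times, dens)
    recovery <- C[length(C)]
    if (area > 0) dens <- dens * (recovery / area)
    w <- dens / sum(dens)
    mu <- if (recovery > 0) sum(w * times) else NA_real_
    sd_ <- if (recovery > 0) sqrt(sum(w * (times - mu)^2)) else NA_real_
    out[[as.character(L)]] <- structure(list(
      L = L, times = times, density = dens, cumulative = C,
      recovery = recovery, mean_arrival = mu, std_arrival = sd_,
      n_arrived = NA_integer_, n_total = NA_integer_, arrivals = NULL,
      t_max = max(times), unreliable = recovery < 0.02, source = "ade"
    ), class = "breakthrough_curve")
  }
  out
}
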