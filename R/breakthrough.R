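#' Breakthrough curve at a radial control plane
#'
#' Container for a first-arrival-time (breakthrough) curve at control
#' radius `L`: the arrival-time density normalized by the total ensemble
#' size `C0` (so its integral equals the recovery), the cumulative
#' recovery `C/C0`, and arrival-time moments over arrivers. Built either
#' from sampled arrival times (real paths, CTRW) or from a model CDF
#' (ADE).
#'
#' @param L Control radius, micrometres.
#' @param arrivals Numeric vector of arrival times (censored particles
#'   excluded).
#' @param n_total Ensemble size `C0`.
#' @param t_max Time horizon of the curve.
#' @param n_bins Number of density bins.
#' @param min_recovery Recovery threshold below which the curve is flagged
#'   as lacking a clear profile.
#' @return An object of class `breakthrough_curve` with fields `L`,
#'   `times` (bin centres), `density` (1/s, integrates to `recovery`),
#'   `cumulative`, `recovery`, `mean_arrival`, `std_arrival`,
#'   `n_arrived`, `n_total`, `arrivals`, `unreliable`.
#' @export
breakthrough_curve <- function(L, arrivals, n_total, t_max,
                               n_bins = 50, min_recovery = 0.02) {
  stopifnot(L > 0, n_total >= 1)
  arrivals <- arrivals[is.finite(arrivals)]
  n_arr <- length(arrivals)
  recovery <- n_arr / n_total
  edges <- seq(0, t_max, length.out = n_bins + 1L)
  w <- diff(edges)
  cnt <- if (n_arr > 0) {
    graphics::hist(arrivals, breaks = edges, plot = FALSE,
                   include.lowest = TRUE, right = FALSE)$counts
  } else rep(0L, n_bins)
  dens <- cnt / (n_total * w)
  structure(list(
    L = L,
    times = (edges[-1] + edges[-length(edges)]) / 2,
    density = dens,
    cumulative = cumsum(cnt) / n_total,
    recovery = recovery,
    mean_arrival = if (n_arr > 0) mean(arrivals) else NA_real_,
    std_arrival = if (n_arr > 0) sqrt(mean((arrivals - mean(arrivals))^2)) else NA_real_,
    n_arrived = n_arr,
    n_total = n_total,
    arrivals = arrivals,
    t_max = t_max,
    unreliable = recovery < min_recovery,
    source = "sampled"
  ), class = "breakthrough_curve")
}

#' @export
print.breakthrough_curve <- function(x, ...) {
  cat("<breakthrough_curve> L = ", x$L, " um: recovery ",
      signif(100 * x$recovery, 3), "%, mean ",
      signif(x$mean_arrival, 4), " s, std ", signif(x$std_arrival, 4), " s",
      if (isTRUE(x$unreliable)) "  [unreliable: recovery < threshold]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Real-path breakthrough curves from observed trajectories
#'
#' Translates every (filtered) trajectory to the origin and records, per
#' control radius, the first time its radial distance reaches `L`, with
#' positions interpolated linearly between samples. Curves are limited in
#' time by the longest recorded duration, so recovery is the fraction of
#' trajectories observed to break through within the recording window.
#'
#' @param trajs Micrometre-unit trajectory tibble (ideally filtered with
#'   [filter_trajectories()]).
#' @param radii Control radii, micrometres.
#' @param t_max Horizon; defaults to the longest trajectory duration.
#' @param n_bins Density bins.
#' @return Named list of [breakthrough_curve()] objects, one per radius.
#' @export
real_breakthrough <- function(trajs, radii, t_max = NULL, n_bins = 50) {
  if (is.null(trajs) || nrow(trajs) == 0L) {
    stop("no trajectories supplied", call. = FALSE)
  }
  h <- as_walk_history(trajs, t_max = t_max)
  first_passage(h, radii, t_max = h$t_max, n_bins = n_bins)
}

#' Arrival-time moments of a breakthrough curve
#'
#' Mean and mean-centered standard deviation (population convention) of
#' the arrival times. For sampled curves these are computed over arrivers
#' only; for density-form curves (ADE) they are density-weighted moments
#' over the evaluation horizon.
#'
#' @param curve A `breakthrough_curve`.
#' @return Named numeric vector `c(mean_arrival, std_arrival)`; `NA` with
#'   a warning when nothing arrived.
#' @export
moments_of_curve <- function(curve) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  if ((curve$source == "sampled" && curve$n_arrived == 0L) ||
      (curve$source != "sampled" && curve$recovery <= 0)) {
    warning("no arrivals: moments undefined")
    return(c(mean_arrival = NA_real_, std_arrival = NA_real_))
  }
  c(mean_arrival = curve$mean_arrival, std_arrival = curve$std_arrival)
}

#' Model-vs-real breakthrough comparison report
#'
#' Collects recovery, mean and standard deviation of arrival time for the
#' real-path curves and each model (ADE, coupled CTRW, uncoupled CTRW) at
#' every control radius into one tidy table. Curves whose recovery falls
#' below `recovery_threshold` are flagged `excluded` (they do not display
#' a clear breakthrough profile) and are dropped from the comparison
#' plots.
#'
#' @param real,ade,ctrw_coupled,ctrw_uncoupled Named lists of
#'   `breakthrough_curve` objects on the same radii (any model may be
#'   `NULL` to omit it).
#' @param recovery_threshold Exclusion threshold on recovery.
#' @return Tibble `(L_um, source, recovery, mean_arrival_s, std_arrival_s,
#'   n_arrived, excluded)`.
#' @export
compare_report <- function(real, ade = NULL, ctrw_coupled = NULL,
                           ctrw_uncoupled = NULL, recovery_threshold = 0.02) {
  sources <- list(real = real, ade = ade, ctrw_coupled = ctrw_coupled,
                  ctrw_uncoupled = ctrw_uncoupled)
  sources <- sources[!vapply(sources, is.null, logical(1))]
  radii <- names(sources[[1]])
  for (s in sources) {
    if (!identical(names(s), radii)) {
      stop("curve lists are on different control-radius sets", call. = FALSE)
    }
  }
  rows <- list()
  for (nm in names(sources)) {
    for (Lc in radii) {
      cv <- sources[[nm]][[Lc]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        L_um = cv$L, source = nm, recovery = cv$recovery,
        mean_arrival_s = cv$mean_arrival, std_arrival_s = cv$std_arrival,
        n_arrived = cv$n_arrived,
        excluded = cv$recovery < recovery_threshold)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$L_um, .data$source)
}

#' Overlaid breakthrough-density comparison plot
#'
#' One panel per control radius, overlaying the arrival-time densities of
#' the real paths and the models. Curves excluded for low recovery are
#' omitted.
#'
#' @inheritParams compare_report
#' @return A ggplot object.
#' @export
plot_breakthrough_comparison <- function(real, ade = NULL, ctrw_coupled = NULL,
                                         ctrw_uncoupled = NULL,
                                         recovery_threshold = 0.02) {
  sources <- list(real = real, ade = ade, ctrw_coupled = ctrw_coupled,
                  ctrw_uncoupled = ctrw_uncoupled)
  sources <- sources[!vapply(sources, is.null, logical(1))]
  dat <- list()
  for (nm in names(sources)) {
    for (cv in sources[[nm]]) {
      if (cv$recovery < recovery_threshold) next
      dat[[length(dat) + 1L]] <- tibble::tibble(
        L_um = cv$L, source = nm, t_s = cv$times, density = cv$density)
    }
  }
  dat <- dplyr::bind_rows(dat)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s, y = .data$density,
                                    colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~L_um, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "first-arrival density (1/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
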