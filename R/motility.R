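#' Convert a pixel/frame trajectory to physical units
#'
#' Applies the acquisition unit conversions: time in seconds is the frame
#' count times the frame interval, `t = frame / frequency`; distance in
#' micrometres is the pixel count times the on-sample pixel size,
#' `um = px * sensor_pixel / magnification`. At 20X with a 13 um sensor
#' pixel, one pixel is 0.65 um and a 1024 px window spans 665.6 um; 1000
#' frames at 8 Hz last 125 s.
#'
#' @param traj Trajectory tibble with columns `cell_id, frame, x_px, y_px`.
#' @param frequency Frame rate, Hz (> 0).
#' @param magnification Magnification factor (> 0).
#' @param sensor_pixel Sensor pixel pitch, micrometres.
#' @return Tibble `(cell_id, frame, t_s, x_um, y_um)` with attribute
#'   `units = "um"`.
#' @export
convert_units <- function(traj, frequency, magnification, sensor_pixel = 13) {
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  if (magnification <= 0) stop("magnification must be positive", call. = FALSE)
  px <- sensor_pixel / magnification
  out <- tibble::tibble(
    cell_id = traj$cell_id,
    frame = traj$frame,
    t_s = traj$frame / frequency,
    x_um = traj$x_px * px,
    y_um = traj$y_px * px)
  attr(out, "units") <- "um"
  out
}

#' @rdname convert_units
#' @param n_frames Number of frames.
#' @export
frames_to_seconds <- function(n_frames, frequency) {
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  n_frames / frequency
}

#' @rdname convert_units
#' @param n_pixels Number of pixels.
#' @export
pixels_to_um <- function(n_pixels, magnification, sensor_pixel = 13) {
  if (magnification <= 0) stop("magnification must be positive", call. = FALSE)
  n_pixels * sensor_pixel / magnification
}

# absolute angle (radians) between 2-D vectors a and b
.vec_angle <- function(ax, ay, bx, by) {
  dot <- ax * bx + ay * by
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  acos(pmin(1, pmax(-1, dot / (na * nb))))
}

#' Segment a trajectory into jumps and waiting periods
#'
#' Implements the two-rule step decomposition of a run-and-tumble path. A
#' frame-to-frame displacement smaller than the body length marks a
#' *waiting state*; consecutive waiting frames accumulate into the waiting
#' component of the next step. A *run* opens when the displacement reaches
#' the body length and extends while each per-frame displacement direction
#' stays within `angle_threshold` degrees of the run's current mean
#' direction (the direction of its net displacement so far). A new jump is
#' therefore registered when the cell moves out of a waiting state, or
#' when the turn angle exceeds the threshold.
#'
#' Each emitted step carries the net x/y increments of the run, the jump
#' length `eps` (the net displacement), the run duration `tau_run`, the
#' preceding accumulated wait `tau_wait`, and the total step time
#' `tau = tau_wait + tau_run`, so the step times of a trajectory sum to
#' its covered duration. A trajectory that ends in a waiting state emits a
#' terminal pure-wait record with `eps = 0`.
#'
#' The decomposition depends on displacements only, so it is invariant to
#' translating or rotating the trajectory.
#'
#' @param traj Micrometre-unit trajectory tibble (single cell or many;
#'   segmented per `cell_id`), columns `cell_id, t_s, x_um, y_um`.
#' @param body_length Waiting-state threshold, micrometres.
#' @param angle_threshold Turn-angle threshold, degrees.
#' @return Step tibble `(cell_id, step_index, dx_um, dy_um, eps_um, tau_s,
#'   tau_wait_s, tau_run_s)`. Fewer than 2 samples yield zero rows.
#' @export
segment_steps <- function(traj, body_length, angle_threshold = 5) {
  stopifnot(body_length > 0, angle_threshold > 0)
  thr_rad <- angle_threshold * pi / 180
  res <- lapply(split(traj, traj$cell_id), function(d) {
    m <- nrow(d)
    if (m < 2L) return(NULL)
    dx <- diff(d$x_um); dy <- diff(d$y_um); dt <- diff(d$t_s)
    len <- sqrt(dx^2 + dy^2)
    steps <- list(); k <- 0L
    wait_acc <- 0
    run_open <- FALSE
    rsx <- 0; rsy <- 0; rtime <- 0; rwait <- 0
    emit <- function() {
      k <<- k + 1L
      steps[[k]] <<- c(rsx, rsy, sqrt(rsx^2 + rsy^2), rwait + rtime, rwait, rtime)
    }
    for (i in seq_len(m - 1L)) {
      if (len[i] < thr_wait_len(body_length)) {
        if (run_open) { emit(); run_open <- FALSE }
        wait_acc <- wait_acc + dt[i]
      } else {
        if (run_open) {
          ang <- .vec_angle(rsx, rsy, dx[i], dy[i])
          if (ang <= thr_rad) {
            rsx <- rsx + dx[i]; rsy <- rsy + dy[i]; rtime <- rtime + dt[i]
          } else {
            emit()
            rsx <- dx[i]; rsy <- dy[i]; rtime <- dt[i]; rwait <- 0
          }
        } else {
          rsx <- dx[i]; rsy <- dy[i]; rtime <- dt[i]
          rwait <- wait_acc; wait_acc <- 0
          run_open <- TRUE
        }
      }
    }
    if (run_open) {
      emit()
    } else if (wait_acc > 0) {
      # terminal pure wait: keeps sum(tau) equal to the covered duration
      k <- k + 1L
      steps[[k]] <- c(0, 0, 0, wait_acc, wait_acc, 0)
    }
    if (k == 0L) return(NULL)
    sm <- do.call(rbind, steps)
    tibble::tibble(cell_id = d$cell_id[1], step_index = seq_len(k),
                   dx_um = sm[, 1], dy_um = sm[, 2], eps_um = sm[, 3],
                   tau_s = sm[, 4], tau_wait_s = sm[, 5], tau_run_s = sm[, 6])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(cell_id = integer(), step_index = integer(),
                          dx_um = numeric(), dy_um = numeric(),
                          eps_um = numeric(), tau_s = numeric(),
                          tau_wait_s = numeric(), tau_run_s = numeric())
  }
  out
}

# the waiting-state displacement threshold is exactly the body length
thr_wait_len <- function(body_length) body_length

#' Merge per-trajectory step tables into the master table
#'
#' Concatenates step records from all trajectories of a dataset into one
#' master table — x-increment, y-increment, jump length and waiting time
#' for every jump — preserving cell identity and step order. This pooled
#' empirical joint distribution is the sole input to CTRW sampling.
#'
#' @param step_tables A list of step tibbles from [segment_steps()], or a
#'   single tibble.
#' @return The master step tibble.
#' @export
build_master <- function(step_tables) {
  if (is.data.frame(step_tables)) step_tables <- list(step_tables)
  out <- dplyr::bind_rows(step_tables)
  if (nrow(out) == 0L) warning("master table is empty")
  out
}

#' Empirical probability density on given bins
#'
#' Histogram density: counts divided by `n * bin_width`, so that
#' `sum(density * width) == 1`.
#'
#' @param values Non-negative sample values (jump lengths or waits).
#' @param bin_edges Increasing bin edges covering the data.
#' @return An object of class `empirical_pdf`: tibble
#'   `(bin_left, bin_right, density)` with attribute `n_samples`.
#' @export
empirical_pdf <- function(values, bin_edges) {
  if (length(values) == 0L) stop("no values supplied", call. = FALSE)
  stopifnot(all(diff(bin_edges) > 0))
  h <- graphics::hist(values, breaks = bin_edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  out <- tibble::tibble(bin_left = utils::head(bin_edges, -1),
                        bin_right = utils::tail(bin_edges, -1),
                        density = h$density)
  attr(out, "n_samples") <- length(values)
  class(out) <- c("empirical_pdf", class(out))
  out
}

#' Log-spaced bin edges
#'
#' Default binning for jump-length and waiting-time densities, whose
#' supports span several decades.
#'
#' @param lo,hi Range to cover (positive).
#' @param per_decade Bins per decade.
#' @return Numeric vector of edges.
#' @export
log_bins <- function(lo, hi, per_decade = 30) {
  stopifnot(lo > 0, hi > lo)
  n <- ceiling(per_decade * log10(hi / lo))
  10^seq(log10(lo), log10(hi), length.out = n + 1L)
}

#' Ensemble displacement moments over time
#'
#' Translates every trajectory to a common origin (its own start point)
#' and a common clock (its own start time), then reports, on the native
#' frame grid, the ensemble mean displacement and the mean-centered
#' variance of cell locations as functions of time. Trajectories
#' contribute only over their recorded span, so the ensemble thins with
#' time; the series is truncated at the last time at which at least
#' `min_unique` unique trajectories remain.
#'
#' Two conventions are exposed for the mean displacement — the mean of the
#' displacement magnitudes (default) or the magnitude of the mean
#' displacement vector (the right quantity for estimating a slow uniform
#' drift) — and two for the variance: radial,
#' `mean(|r - rbar|^2)`, or per-axis, half the radial value.
#'
#' @param trajs Micrometre-unit trajectory tibble.
#' @param min_unique Minimum number of live trajectories per reported time.
#' @param disp `"mean_magnitude"` or `"magnitude_of_mean"`.
#' @param variance `"radial"` or `"per_axis"`.
#' @return Tibble `(t_s, mean_disp_um, var_um2, n_alive)`; zero rows (with
#'   a warning) when no time has `min_unique` live trajectories.
#' @export
ensemble_moments <- function(trajs, min_unique = 50,
                             disp = c("mean_magnitude", "magnitude_of_mean"),
                             variance = c("radial", "per_axis")) {
  disp <- match.arg(disp)
  variance <- match.arg(variance)
  sp <- split(trajs, trajs$cell_id)
  rel <- lapply(sp, function(d) {
    tibble::tibble(k = seq_len(nrow(d)) - 1L,
                   t = d$t_s - d$t_s[1],
                   x = d$x_um - d$x_um[1],
                   y = d$y_um - d$y_um[1])
  })
  rel <- dplyr::bind_rows(rel)
  agg <- dplyr::summarise(dplyr::group_by(rel, .data$k),
    t_s = mean(.data$t),
    n_alive = dplyr::n(),
    mx = mean(.data$x), my = mean(.data$y),
    mean_mag = mean(sqrt(.data$x^2 + .data$y^2)),
    var_rad = mean((.data$x - mean(.data$x))^2 + (.data$y - mean(.data$y))^2),
    .groups = "drop")
  agg <- agg[agg$n_alive >= min_unique, , drop = FALSE]
  if (nrow(agg) == 0L) {
    warning("no time point has ", min_unique, " live trajectories")
    return(tibble::tibble(t_s = numeric(), mean_disp_um = numeric(),
                          var_um2 = numeric(), n_alive = integer()))
  }
  md <- if (disp == "mean_magnitude") agg$mean_mag else sqrt(agg$mx^2 + agg$my^2)
  v <- if (variance == "radial") agg$var_rad else agg$var_rad / 2
  tibble::tibble(t_s = agg$t_s, mean_disp_um = md, var_um2 = v,
                 n_alive = as.integer(agg$n_alive))
}

#' Ensemble drift speed from the mean-displacement slope
#'
#' The average velocity is the ordinary least-squares slope of the
#' ensemble mean displacement against time (free intercept).
#'
#' @param moments A [ensemble_moments()] tibble with at least 3 time points.
#' @return Drift speed, micrometres per second.
#' @export
drift_speed <- function(moments) {
  if (nrow(moments) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (length(unique(moments$t_s)) < 2L) {
    stop("degenerate time axis", call. = FALSE)
  }
  unname(stats::coef(stats::lm(mean_disp_um ~ t_s, data = moments))[2])
}

#' Lag-1 correlations of successive steps
#'
#' Pearson correlation between consecutive jump lengths and between
#' consecutive waiting times, with pairs formed only within the same
#' trajectory. Terminal pure-wait records (`eps = 0`) are excluded by
#' default so jump-length pairs compare actual jumps. Results with fewer
#' than 10 pairs are flagged sparse.
#'
#' @param master Master step tibble.
#' @param drop_zero_eps Drop `eps = 0` records before pairing.
#' @param tau Which time to correlate: the total step time
#'   (`"total"`, waiting plus run, the CTRW increment) or only its
#'   waiting component (`"wait"`).
#' @return A list with elements `eps_corr`, `tau_corr`, `n_pairs`,
#'   `sparse`.
#' @export
step_correlation <- function(master, drop_zero_eps = TRUE,
                             tau = c("total", "wait")) {
  tau <- match.arg(tau)
  m <- master
  if (tau == "wait") m$tau_s <- m$tau_wait_s
  if (drop_zero_eps) m <- m[m$eps_um > 0, , drop = FALSE]
  pairs_e <- list(); pairs_t <- list()
  for (d in split(m, m$cell_id)) {
    n <- nrow(d)
    if (n < 2L) next
    pairs_e[[length(pairs_e) + 1L]] <- cbind(d$eps_um[-n], d$eps_um[-1])
    pairs_t[[length(pairs_t) + 1L]] <- cbind(d$tau_s[-n], d$tau_s[-1])
  }
  pe <- do.call(rbind, pairs_e)
  pt <- do.call(rbind, pairs_t)
  n_pairs <- if (is.null(pe)) 0L else nrow(pe)
  safe_cor <- function(m) {
    if (n_pairs < 2L || stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
      return(NA_real_)  # undefined for constant series
    }
    stats::cor(m[, 1], m[, 2])
  }
  list(
    eps_corr = safe_cor(pe),
    tau_corr = safe_cor(pt),
    n_pairs = n_pairs,
    sparse = n_pairs < 10L
  )
}
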