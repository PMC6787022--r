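#' Parameters of the run-and-tumble trajectory generator
#'
#' Bundles the motility model under which ground-truth trajectories are
#' generated: a cell alternates between *waiting* (position fixed, duration
#' drawn from `wait_pdf_spec`) and *runs* (straight displacement of length
#' drawn from `jump_pdf_spec`, direction uniform on the circle, traversed
#' at constant `run_speed` so that runs span multiple frames). Optional
#' lag-1 correlation between successive jump lengths and/or waiting times
#' is imposed with a Gaussian copula calibrated so the Pearson lag-1
#' correlation of the generated series equals `jump_corr` / `wait_corr`
#' (see [calibrate_copula_rho()]). An optional slow uniform drift is added
#' to every position, emulating the residual ensemble motion seen in
#' sealed, nominally no-flow chambers.
#'
#' Defaults describe a flagellated swimmer: jump lengths truncated-Pareto
#' with mode 5.5 um and hard maximum 100 um, waiting times truncated-Pareto
#' reaching 250 s, body length 3 um.
#'
#' @param jump_pdf_spec [dist_spec()] for run (jump) lengths, micrometres.
#' @param wait_pdf_spec [dist_spec()] for waiting durations, seconds.
#' @param body_length Cell body length, micrometres (used downstream as the
#'   waiting-state threshold).
#' @param drift_speed Magnitude of the uniform drift, micrometres/second.
#' @param drift_direction Drift direction, radians.
#' @param jump_corr,wait_corr Target lag-1 Pearson correlations of
#'   successive jump lengths / waiting times, in `(-1, 1)`. `0` gives
#'   independent steps.
#' @param n_cells Number of cells to generate.
#' @param t_max Duration of each trajectory, seconds.
#' @param seed Integer seed; the same seed reproduces the ensemble
#'   bit-for-bit.
#' @param run_speed Speed at which a run traverses its chord, um/s. Must
#'   exceed `body_length` times the intended sampling frequency for the
#'   per-frame displacement during runs to register as motion.
#' @param arena Side of the square region (um) over which starting
#'   positions are scattered uniformly; default matches a 1024 px window
#'   at 20X (1024 x 13/20 um).
#' @param start_margin Margin (um) kept between starting positions and the
#'   arena edge, reducing early exits from the rendered window.
#' @param idle_fraction Probability that a cell is completely idle (never
#'   jumps) for its whole recording; such cells are exactly what the
#'   trajectory filters are designed to drop.
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(jump_pdf_spec = dist_spec("pareto",
                              xmin = 5.5, alpha = 1.6, max = 100),
                            wait_pdf_spec = dist_spec("pareto",
                              xmin = 0.25, alpha = 1.2, max = 250),
                            body_length = 3,
                            drift_speed = 0,
                            drift_direction = 0,
                            jump_corr = 0,
                            wait_corr = 0,
                            n_cells = 100,
                            t_max = 125,
                            seed = 1L,
                            run_speed = 30,
                            arena = 1024 * 13 / 20,
                            start_margin = 0,
                            idle_fraction = 0) {
  stopifnot(inherits(jump_pdf_spec, "dist_spec"), inherits(wait_pdf_spec, "dist_spec"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("n_cells must be a positive count", call. = FALSE)
  }
  if (!is.numeric(t_max) || t_max <= 0) {
    stop("t_max must be positive", call. = FALSE)
  }
  stopifnot(body_length > 0, run_speed > 0, arena > 0,
            abs(jump_corr) < 1, abs(wait_corr) < 1,
            idle_fraction >= 0, idle_fraction <= 1,
            drift_speed >= 0, start_margin >= 0, 2 * start_margin < arena)
  structure(list(
    jump_pdf_spec = jump_pdf_spec, wait_pdf_spec = wait_pdf_spec,
    body_length = body_length,
    drift_speed = drift_speed, drift_direction = drift_direction,
    jump_corr = jump_corr, wait_corr = wait_corr,
    n_cells = as.integer(n_cells), t_max = t_max, seed = as.integer(seed),
    run_speed = run_speed, arena = arena, start_margin = start_margin,
    idle_fraction = idle_fraction
  ), class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat("<motility_params>\n")
  cat("  jump:", x$jump_pdf_spec$family, " wait:", x$wait_pdf_spec$family, "\n")
  cat("  n_cells:", x$n_cells, " t_max:", x$t_max, "s  seed:", x$seed, "\n")
  cat("  drift:", x$drift_speed, "um/s  jump_corr:", x$jump_corr,
      " wait_corr:", x$wait_corr, "\n")
  invisible(x)
}

# expected value of a spec, for chunk sizing only
.dist_mean <- function(spec) {
  if (spec$family == "degenerate") return(spec$value)
  .dist_moments_gh(spec)$mean
}

#' Generate ground-truth run-and-tumble trajectories
#'
#' Simulates `n_cells` independent cells under a [motility_params()] model.
#' Each trajectory is an alternating sequence of waits (position fixed) and
#' straight runs (constant direction and speed within a run, direction
#' resampled uniformly at each run). The per-step bookkeeping — x/y
#' increments, jump length `eps`, waiting time `tau = tau_wait + tau_run` —
#' is returned alongside the continuous piecewise-linear paths, so every
#' downstream stage (rendering, tracking, segmentation, CTRW) can be
#' checked against the exact ground truth.
#'
#' Step increments in `$steps` are the pure motility increments; the drift,
#' when present, is added to the path positions only.
#'
#' @param params A [motility_params()] object.
#' @return An object of class `rt_ensemble`: a list with
#'   \describe{
#'     \item{`paths`}{tibble `(cell_id, t_s, x_um, y_um)` of piecewise-linear
#'       breakpoints; positions between breakpoints interpolate linearly.}
#'     \item{`steps`}{tibble
#'       `(cell_id, step_index, dx_um, dy_um, eps_um, tau_s, tau_wait_s, tau_run_s)`
#'       of completed ground-truth steps.}
#'     \item{`idle`}{logical vector flagging completely idle cells.}
#'     \item{`params`}{the input parameters.}
#'   }
#' @export
generate_trajectories <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  set.seed(params$seed)
  p <- params

  rho_jump <- if (p$jump_corr != 0) calibrate_copula_rho(p$jump_corr, p$jump_pdf_spec) else 0
  rho_wait <- if (p$wait_corr != 0) calibrate_copula_rho(p$wait_corr, p$wait_pdf_spec) else 0

  mean_tau <- .dist_mean(p$wait_pdf_spec) + .dist_mean(p$jump_pdf_spec) / p$run_speed
  idle <- stats::runif(p$n_cells) < p$idle_fraction
  x0 <- stats::runif(p$n_cells, p$start_margin, p$arena - p$start_margin)
  y0 <- stats::runif(p$n_cells, p$start_margin, p$arena - p$start_margin)

  paths <- vector("list", p$n_cells)
  steps <- vector("list", p$n_cells)

  for (cell in seq_len(p$n_cells)) {
    if (idle[cell]) {
      paths[[cell]] <- tibble::tibble(
        cell_id = cell, t_s = c(0, p$t_max), x_um = x0[cell], y_um = y0[cell])
      next
    }
    t <- 0; x <- x0[cell]; y <- y0[cell]
    zj <- NULL; zw <- NULL
    bp_t <- 0; bp_x <- x; bp_y <- y
    st <- list()
    k <- 0L
    while (t < p$t_max) {
      n_draw <- max(16L, ceiling(1.3 * (p$t_max - t) / mean_tau))
      dw <- .draw_correlated(n_draw, p$wait_pdf_spec, rho_wait, zw)
      dj <- .draw_correlated(n_draw, p$jump_pdf_spec, rho_jump, zj)
      zw <- dw$z_last; zj <- dj$z_last
      theta <- stats::runif(n_draw, 0, 2 * pi)
      for (i in seq_len(n_draw)) {
        tw <- dw$x[i]; eps <- dj$x[i]; tr <- eps / p$run_speed
        if (t + tw + tr > p$t_max) {
          # partial step: truncate the path at t_max, record no step
          if (t + tw >= p$t_max) {
            bp_t <- c(bp_t, p$t_max); bp_x <- c(bp_x, x); bp_y <- c(bp_y, y)
          } else {
            frac <- (p$t_max - t - tw) / tr
            bp_t <- c(bp_t, t + tw, p$t_max)
            bp_x <- c(bp_x, x, x + frac * eps * cos(theta[i]))
            bp_y <- c(bp_y, y, y + frac * eps * sin(theta[i]))
          }
          t <- p$t_max
          break
        }
        dx <- eps * cos(theta[i]); dy <- eps * sin(theta[i])
        bp_t <- c(bp_t, t + tw, t + tw + tr)
        bp_x <- c(bp_x, x, x + dx)
        bp_y <- c(bp_y, y, y + dy)
        x <- x + dx; y <- y + dy; t <- t + tw + tr
        k <- k + 1L
        st[[k]] <- c(dx, dy, eps, tw + tr, tw, tr)
      }
    }
    paths[[cell]] <- tibble::tibble(cell_id = cell, t_s = bp_t, x_um = bp_x, y_um = bp_y)
    if (k > 0L) {
      m <- do.call(rbind, st)
      steps[[cell]] <- tibble::tibble(
        cell_id = cell, step_index = seq_len(k),
        dx_um = m[, 1], dy_um = m[, 2], eps_um = m[, 3],
        tau_s = m[, 4], tau_wait_s = m[, 5], tau_run_s = m[, 6])
    }
  }

  paths <- dplyr::bind_rows(paths)
  if (p$drift_speed > 0) {
    paths$x_um <- paths$x_um + p$drift_speed * cos(p$drift_direction) * paths$t_s
    paths$y_um <- paths$y_um + p$drift_speed * sin(p$drift_direction) * paths$t_s
  }
  structure(list(
    paths = paths,
    steps = if (length(steps)) dplyr::bind_rows(steps) else tibble::tibble(),
    idle = idle,
    params = p
  ), class = "rt_ensemble")
}

#' @export
print.rt_ensemble <- function(x, ...) {
  cat("<rt_ensemble> ", x$params$n_cells, " cells, t_max ", x$params$t_max,
      " s, ", nrow(x$steps), " ground-truth steps\n", sep = "")
  invisible(x)
}

#' Sample ground-truth paths on a regular frame grid
#'
#' Evaluates the piecewise-linear ground-truth paths at the frame times of
#' an acquisition running at `frequency` Hz, yielding trajectories in the
#' same form the tracking stage produces (after unit conversion).
#'
#' @param ensemble An [generate_trajectories()] result.
#' @param frequency Frame rate, Hz.
#' @param n_frames Number of frames; default covers the full `t_max`.
#' @return Tibble `(cell_id, frame, t_s, x_um, y_um)` with attribute
#'   `units = "um"`; `frame` is 0-based.
#' @export
sample_trajectories <- function(ensemble, frequency, n_frames = NULL) {
  stopifnot(inherits(ensemble, "rt_ensemble"), frequency > 0)
  t_max <- ensemble$params$t_max
  if (is.null(n_frames)) n_frames <- floor(t_max * frequency) + 1L
  tg <- (seq_len(n_frames) - 1L) / frequency
  tg <- tg[tg <= t_max + 1e-12]
  out <- lapply(split(ensemble$paths, ensemble$paths$cell_id), function(d) {
    tibble::tibble(
      cell_id = d$cell_id[1],
      frame = seq_along(tg) - 1L,
      t_s = tg,
      x_um = stats::approx(d$t_s, d$x_um, xout = tg, rule = 2)$y,
      y_um = stats::approx(d$t_s, d$y_um, xout = tg, rule = 2)$y)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "units") <- "um"
  out
}

#' Imaging model for rendering synthetic frame stacks
#'
#' Acquisition metadata plus the simple photometric model used by
#' [render_frames()]: bright noisy background, cells as dark filled disks.
#'
#' @param magnification Microscope magnification (e.g. 20 for 20X).
#' @param frequency Frame rate, Hz.
#' @param sensor_pixel Physical sensor pixel pitch, micrometres.
#' @param frame_size Frame side length, pixels.
#' @param n_frames Number of frames to render.
#' @param cell_radius_px Rendered cell radius in pixels (disk; diameter of
#'   at least 2 px so a cell occupies several pixels).
#' @param background_level,cell_level Mean background and cell intensities
#'   on a 0-255 scale; cells must be darker than background and separated
#'   from it by more than 3 noise standard deviations.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(magnification = 20, frequency = 8,
                           sensor_pixel = 13, frame_size = 1024L,
                           n_frames = 1000L, cell_radius_px = 2,
                           background_level = 200, cell_level = 60,
                           noise_sd = 5) {
  stopifnot(magnification > 0, frequency > 0, sensor_pixel > 0,
            frame_size > 0, n_frames > 0, cell_radius_px >= 1)
  if (abs(cell_level - background_level) <= 3 * noise_sd) {
    stop("cell_level must differ from background_level by more than 3*noise_sd",
         call. = FALSE)
  }
  structure(list(
    magnification = magnification, frequency = frequency,
    sensor_pixel = sensor_pixel, frame_size = as.integer(frame_size),
    n_frames = as.integer(n_frames), cell_radius_px = cell_radius_px,
    background_level = background_level, cell_level = cell_level,
    noise_sd = noise_sd
  ), class = "imaging_params")
}

#' Render trajectories into a microscopy-like frame stack
#'
#' Converts micrometre positions to pixel coordinates (the inverse of the
#' distance conversion `um = px * sensor_pixel / magnification`), then draws
#' each cell as a filled dark disk on a bright background with i.i.d.
#' Gaussian noise. Cells whose disk falls (partly) outside the frame are
#' clipped; cells fully outside a frame are simply absent from it,
#' emulating entry into and exit from the viewing window.
#'
#' Pixel convention: 0-based, `x` = column, `y` = row, origin top-left;
#' pixel centres at integer coordinates.
#'
#' @param trajectories An `rt_ensemble` (sampled internally at the imaging
#'   frame rate) or a micrometre-unit tibble with columns
#'   `cell_id, frame, x_um, y_um`.
#' @param imaging An [imaging_params()] object.
#' @return A [frame_stack()] with integer intensities in 0-255.
#' @export
render_frames <- function(trajectories, imaging) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (inherits(trajectories, "rt_ensemble")) {
    trajectories <- sample_trajectories(trajectories, imaging$frequency,
                                        imaging$n_frames)
  }
  n <- imaging$frame_size
  nf <- imaging$n_frames
  scale <- imaging$magnification / imaging$sensor_pixel  # px per um
  r <- imaging$cell_radius_px

  stack <- array(0L, dim = c(n, n, nf))
  pos <- trajectories[trajectories$frame < nf, , drop = FALSE]
  pos$x_px <- pos$x_um * scale
  pos$y_px <- pos$y_um * scale
  by_frame <- split(pos, pos$frame)

  clipped <- FALSE
  for (f in seq_len(nf)) {
    mat <- matrix(imaging$background_level, n, n)
    if (imaging$noise_sd > 0) {
      mat <- mat + stats::rnorm(n * n, sd = imaging$noise_sd)
    }
    cells <- by_frame[[as.character(f - 1L)]]
    if (!is.null(cells)) {
      for (i in seq_len(nrow(cells))) {
        cx <- cells$x_px[i]; cy <- cells$y_px[i]
        # rows are y, cols are x, 0-based centre coordinates
        rows <- max(0, floor(cy - r)):min(n - 1, ceiling(cy + r))
        cols <- max(0, floor(cx - r)):min(n - 1, ceiling(cx + r))
        if (cy < -r || cy > n - 1 + r || cx < -r || cx > n - 1 + r) next
        if (cy - r < 0 || cy + r > n - 1 || cx - r < 0 || cx + r > n - 1) {
          clipped <- TRUE
        }
        if (length(rows) == 0 || length(cols) == 0) next
        dr2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
        sel <- which(dr2 <= r^2, arr.ind = TRUE)
        if (nrow(sel) > 0) {
          mat[cbind(rows[sel[, 1]] + 1L, cols[sel[, 2]] + 1L)] <- imaging$cell_level
        }
      }
    }
    stack[, , f] <- as.integer(pmin(255, pmax(0, round(mat))))
  }
  if (clipped) warning("some cells extended beyond the frame and were clipped")
  frame_stack(stack, frequency = imaging$frequency,
              magnification = imaging$magnification,
              sensor_pixel = imaging$sensor_pixel)
}
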