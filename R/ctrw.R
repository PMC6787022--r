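#' Configuration of the CTRW Monte-Carlo simulator
#'
#' @param coupled Logical; `TRUE` draws whole master rows so each jump
#'   keeps the waiting time observed with it (the empirical joint),
#'   `FALSE` draws jump and waiting time from independent rows (all
#'   waiting times equally likely regardless of jump length).
#' @param n_particles Number of walkers (>= 1).
#' @param t_max Simulation horizon, seconds (> 0). Each walker takes steps
#'   until its clock passes `t_max`, so every walker takes at least one
#'   step.
#' @param seed Integer seed.
#' @param resample_direction Logical; when `TRUE` each sampled increment is
#'   replaced by `eps * (cos theta, sin theta)` with a fresh uniform
#'   direction, isotropizing the walk. Off by default, preserving any
#'   anisotropy present in the master table.
#' @return An object of class `ctrw_config`.
#' @export
ctrw_config <- function(coupled = TRUE, n_particles = 1000, t_max = 250,
                        seed = 1L, resample_direction = FALSE) {
  stopifnot(n_particles >= 1, t_max > 0)
  structure(list(coupled = coupled, n_particles = as.integer(n_particles),
                 t_max = t_max, seed = as.integer(seed),
                 resample_direction = resample_direction),
            class = "ctrw_config")
}

#' Simulate a continuous-time random walk from the master table
#'
#' Monte-Carlo realization of the walk recursion `r[n+1] = r[n] + eps[n]`,
#' `t[n+1] = t[n] + tau[n]`: every particle starts at the origin at time
#' zero and repeatedly draws steps from the empirical master table until
#' its clock exceeds `t_max`. In the *coupled* variant a whole row
#' `(dx, dy, tau)` is drawn uniformly with replacement, so waiting times
#' stay attached to the jump lengths they were observed with; in the
#' *uncoupled* variant the displacement and the waiting time come from two
#' independently drawn rows. The full event history is retained for
#' first-passage analysis.
#'
#' Each event consists of a stationary wait of `tau_wait` followed by a
#' straight traversal of the jump chord over `tau_run` (at constant
#' speed), matching the step convention of [segment_steps()].
#'
#' @param master Non-empty master step tibble (see [build_master()]).
#' @param cfg A [ctrw_config()].
#' @return An object of class `walk_history`: a list with `events`
#'   (tibble `particle, step, t0, t1, x0, y0, x1, y1, tau_wait, tau_run`),
#'   `n_particles` and `t_max`. Identical seeds give identical output.
#' @export
simulate_ctrw <- function(master, cfg) {
  stopifnot(inherits(cfg, "ctrw_config"))
  if (is.null(master) || nrow(master) == 0L) {
    stop("master table is empty", call. = FALSE)
  }
  set.seed(cfg$seed)
  n <- cfg$n_particles
  nr <- nrow(master)
  has_split <- all(c("tau_wait_s", "tau_run_s") %in% names(master))

  x <- numeric(n); y <- numeric(n); t <- numeric(n)
  step_no <- integer(n)
  active <- rep(TRUE, n)
  chunks <- list(); nc <- 0L
  while (any(active)) {
    ia <- which(active)
    na <- length(ia)
    ri <- sample.int(nr, na, replace = TRUE)
    dx <- master$dx_um[ri]; dy <- master$dy_um[ri]; eps <- master$eps_um[ri]
    if (cfg$coupled) {
      tau <- master$tau_s[ri]
      tw <- if (has_split) master$tau_wait_s[ri] else rep(0, na)
      tr <- if (has_split) master$tau_run_s[ri] else tau
    } else {
      rj <- sample.int(nr, na, replace = TRUE)
      tau <- master$tau_s[rj]
      tw <- if (has_split) master$tau_wait_s[rj] else rep(0, na)
      tr <- if (has_split) master$tau_run_s[rj] else tau
    }
    if (cfg$resample_direction) {
      th <- stats::runif(na, 0, 2 * pi)
      dx <- eps * cos(th); dy <- eps * sin(th)
    }
    nc <- nc + 1L
    chunks[[nc]] <- tibble::tibble(
      particle = ia, step = step_no[ia] + 1L,
      t0 = t[ia], t1 = t[ia] + tau,
      x0 = x[ia], y0 = y[ia], x1 = x[ia] + dx, y1 = y[ia] + dy,
      tau_wait = tw, tau_run = tr)
    x[ia] <- x[ia] + dx; y[ia] <- y[ia] + dy; t[ia] <- t[ia] + tau
    step_no[ia] <- step_no[ia] + 1L
    active[ia] <- t[ia] <= cfg$t_max
  }
  events <- dplyr::bind_rows(chunks)
  events <- events[order(events$particle, events$step), , drop = FALSE]
  structure(list(events = events, n_particles = n, t_max = cfg$t_max,
                 coupled = cfg$coupled),
            class = "walk_history")
}

#' @export
print.walk_history <- function(x, ...) {
  cat("<walk_history> ", x$n_particles, " particles, ",
      nrow(x$events), " events, t_max ", x$t_max, " s\n", sep = "")
  invisible(x)
}

#' Encode observed trajectories as a walk history
#'
#' Translates each trajectory so it starts at the origin at time zero and
#' turns every consecutive-sample segment into an event traversed at
#' constant speed. [first_passage()] then treats observed trajectories and
#' CTRW ensembles identically, so "real-path" and modeled breakthroughs
#' share one interpolation rule.
#'
#' @param trajs Micrometre-unit trajectory tibble.
#' @param t_max Observation horizon; defaults to the longest relative
#'   trajectory duration.
#' @return A `walk_history`.
#' @export
as_walk_history <- function(trajs, t_max = NULL) {
  sp <- split(trajs, trajs$cell_id)
  if (length(sp) == 0L) stop("no trajectories supplied", call. = FALSE)
  ev <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    d <- sp[[i]]
    m <- nrow(d)
    if (m < 2L) next
    t <- d$t_s - d$t_s[1]
    x <- d$x_um - d$x_um[1]
    y <- d$y_um - d$y_um[1]
    ev[[i]] <- tibble::tibble(
      particle = i, step = seq_len(m - 1L),
      t0 = t[-m], t1 = t[-1],
      x0 = x[-m], y0 = y[-m], x1 = x[-1], y1 = y[-1],
      tau_wait = 0, tau_run = diff(t))
  }
  events <- dplyr::bind_rows(ev)
  if (is.null(t_max)) t_max <- max(events$t1)
  structure(list(events = events, n_particles = length(sp), t_max = t_max,
                 coupled = NA),
            class = "walk_history")
}

#' First-passage (breakthrough) analysis at radial control planes
#'
#' For each control radius `L`, finds for every particle the first time
#' its radial distance from the origin reaches `L`. Radial position is
#' interpolated linearly along each jump: the particle waits motionless
#' for `tau_wait`, then traverses the jump chord at constant speed over
#' `tau_run`. Because the distance from the origin is convex along a
#' straight chord, a segment produces a first crossing exactly when it
#' ends at or beyond `L` having started inside, and the crossing time
#' solves a quadratic along the chord. Particles that never reach `L`
#' within `t_max` are censored.
#'
#' The arrival-time density is normalized by the *total* particle count
#' `C0`, so its integral equals the recovery (the fraction of the ensemble
#' that breaks through) rather than 1. Arrival-time mean and standard
#' deviation (population convention) are computed over arrivers only, and
#' are flagged unreliable when recovery is below `min_recovery`.
#'
#' @param history A `walk_history` from [simulate_ctrw()] or
#'   [as_walk_history()].
#' @param radii Control-plane radii, micrometres (positive).
#' @param t_max Censoring horizon; defaults to the history's.
#' @param n_bins Number of time bins for the reported density.
#' @param min_recovery Recovery below which moments are flagged
#'   unreliable.
#' @return A named list (one per radius) of `breakthrough_curve` objects.
#' @export
first_passage <- function(history, radii, t_max = history$t_max,
                          n_bins = 50, min_recovery = 0.02) {
  stopifnot(inherits(history, "walk_history"), all(radii > 0))
  ev <- history$events
  if (is.null(ev) || nrow(ev) == 0L) stop("empty history", call. = FALSE)
  r1 <- sqrt(ev$x1^2 + ev$y1^2)
  n_total <- history$n_particles
  out <- list()
  for (L in radii) {
    cand <- ev[r1 >= L, , drop = FALSE]
    cand <- cand[order(cand$particle, cand$step), , drop = FALSE]
    cand <- cand[!duplicated(cand$particle), , drop = FALSE]
    if (nrow(cand) > 0L) {
      ddx <- cand$x1 - cand$x0; ddy <- cand$y1 - cand$y0
      a <- ddx^2 + ddy^2
      b <- 2 * (cand$x0 * ddx + cand$y0 * ddy)
      cc <- cand$x0^2 + cand$y0^2 - L^2
      # start strictly inside (cc < 0): positive root
      u <- (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a)
      u <- pmin(pmax(u, 0), 1)
      # degenerate: start already at/beyond L (only possible at step 1)
      u[cc >= 0] <- 0
      run_t <- ifelse(cand$tau_run > 0, cand$tau_run,
                      cand$t1 - cand$t0 - cand$tau_wait)
      t_cross <- cand$t0 + cand$tau_wait + u * run_t
      arrivals <- t_cross[t_cross <= t_max]
    } else {
      arrivals <- numeric(0)
    }
    out[[as.character(L)]] <- breakthrough_curve(
      L = L, arrivals = arrivals, n_total = n_total, t_max = t_max,
      n_bins = n_bins, min_recovery = min_recovery)
  }
  out
}
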