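# Shared in-code fixtures: tiny constructed trajectories and generator
# configurations used across the module tests.

# a single-cell micrometre trajectory from explicit positions
um_traj <- function(x, y, dt = 0.125, cell_id = 1L) {
  out <- tibble::tibble(
    cell_id = cell_id,
    frame = seq_along(x) - 1L,
    t_s = (seq_along(x) - 1L) * dt,
    x_um = x, y_um = y)
  attr(out, "units") <- "um"
  out
}

# straight constant-velocity path: speed um/s, direction radians
straight_traj <- function(n = 20, speed = 8, theta = 0, dt = 0.125) {
  s <- (seq_len(n) - 1L) * speed * dt
  um_traj(s * cos(theta), s * sin(theta), dt = dt)
}

# a fast-converging generator config for tests; short waits keep the
# temporal-median background model valid on short renders
test_params <- function(...) {
  args <- list(...)
  defaults <- list(
    wait_pdf_spec = dist_spec("exponential", rate = 1, max = 5),
    n_cells = 20, t_max = 25, seed = 42L, body_length = 2
  )
  do.call(motility_params, utils::modifyList(defaults, args))
}

# 2-D Brownian trajectories with per-axis diffusion D0 (um^2/s)
brownian_trajs <- function(n_cells, n_steps, dt, D0, seed = 1L) {
  set.seed(seed)
  sd_ <- sqrt(2 * D0 * dt)
  out <- lapply(seq_len(n_cells), function(i) {
    um_traj(cumsum(c(0, stats::rnorm(n_steps, sd = sd_))),
            cumsum(c(0, stats::rnorm(n_steps, sd = sd_))),
            dt = dt, cell_id = i)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "units") <- "um"
  out
}

# re-centre each cell of a generated ensemble onto given start positions
recenter_ensemble <- function(ens, x0, y0) {
  sp <- split(seq_len(nrow(ens$paths)), ens$paths$cell_id)
  for (i in seq_along(sp)) {
    ix <- sp[[i]]
    ens$paths$x_um[ix] <- ens$paths$x_um[ix] - ens$paths$x_um[ix[1]] + x0[i]
    ens$paths$y_um[ix] <- ens$paths$y_um[ix] - ens$paths$y_um[ix[1]] + y0[i]
  }
  ens
}

# exact CDF of a dist_spec, for one-sample KS distances
dist_cdf <- function(spec) {
  switch(spec$family,
    pareto = function(q) {
      z <- 1 - (spec$xmin / spec$max)^spec$alpha
      pmin(1, pmax(0, (1 - (spec$xmin / pmin(q, spec$max))^spec$alpha) / z))
    },
    exponential = function(q) {
      pm <- if (is.null(spec$max)) 1 else stats::pexp(spec$max, spec$rate)
      stats::pexp(pmin(q, dist_max(spec)), spec$rate) / pm
    },
    stop("no cdf helper for ", spec$family)
  )
}

ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}
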