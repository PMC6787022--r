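# master tables constructed directly for oracle tests
degenerate_master <- function(dx = 5, dy = 0, tau = 1) {
  tibble::tibble(cell_id = 1L, step_index = 1L, dx_um = dx, dy_um = dy,
                 eps_um = sqrt(dx^2 + dy^2), tau_s = tau,
                 tau_wait_s = 0, tau_run_s = tau)
}

independent_master <- function(n, seed = 1) {
  set.seed(seed)
  eps <- stats::qlnorm(stats::runif(n), meanlog = 1.5, sdlog = 0.6)
  th <- stats::runif(n, 0, 2 * pi)
  tibble::tibble(cell_id = 1L, step_index = seq_len(n),
                 dx_um = eps * cos(th), dy_um = eps * sin(th), eps_um = eps,
                 tau_s = stats::qexp(stats::runif(n), rate = 0.5),
                 tau_wait_s = 0, tau_run_s = stats::qexp(stats::runif(n), 0.5))
}

test_that("a degenerate master table gives a deterministic walk", {
  h <- simulate_ctrw(degenerate_master(), ctrw_config(n_particles = 50,
                                                      t_max = 10, seed = 3))
  # after 10 steps each particle is at x = 50 um at t = 10 s exactly
  ev10 <- h$events[h$events$step == 10L, ]
  expect_equal(nrow(ev10), 50L)
  expect_equal(ev10$t1, rep(10, 50))
  expect_equal(ev10$x1, rep(50, 50))
  expect_equal(ev10$y1, rep(0, 50))
})

test_that("every particle takes at least one step even for tiny horizons", {
  h <- simulate_ctrw(degenerate_master(tau = 5),
                     ctrw_config(n_particles = 20, t_max = 0.01, seed = 1))
  expect_equal(nrow(h$events), 20L)
})

test_that("an empty master table is rejected", {
  empty <- degenerate_master()[0, ]
  expect_error(simulate_ctrw(empty, ctrw_config()), "empty")
})

test_that("fixed seeds reproduce the ensemble bit-identically", {
  m <- independent_master(500)
  cfg <- ctrw_config(n_particles = 100, t_max = 50, seed = 11)
  expect_identical(simulate_ctrw(m, cfg)$events, simulate_ctrw(m, cfg)$events)
})

test_that("coupled and uncoupled walks agree when the columns are independent", {
  m <- independent_master(4000)
  hc <- simulate_ctrw(m, ctrw_config(coupled = TRUE, n_particles = 5000,
                                     t_max = 150, seed = 21))
  hu <- simulate_ctrw(m, ctrw_config(coupled = FALSE, n_particles = 5000,
                                     t_max = 150, seed = 22))
  bc <- first_passage(hc, radii = 25)[["25"]]
  bu <- first_passage(hu, radii = 25)[["25"]]
  expect_gt(bc$recovery, 0.5)
  expect_gt(suppressWarnings(
    stats::ks.test(bc$arrivals, bu$arrivals))$p.value, 0.01)
})

test_that("step counts obey the renewal theorem", {
  m <- independent_master(2000, seed = 4)
  cfg <- ctrw_config(n_particles = 400, t_max = 500, seed = 5)
  h <- simulate_ctrw(m, cfg)
  steps_done <- tapply(h$events$step, h$events$particle, max) - 1  # completed by t_max
  expect_lt(abs(mean(steps_done) - cfg$t_max / mean(m$tau_s)) /
            (cfg$t_max / mean(m$tau_s)), 0.05)
})

test_that("coupled sampling preserves the empirical joint of (eps, tau)", {
  m <- independent_master(200, seed = 6)
  h <- simulate_ctrw(m, ctrw_config(coupled = TRUE, n_particles = 300,
                                    t_max = 200, seed = 7))
  drawn <- nrow(h$events)
  # every drawn (eps, tau) pair must be a master row (bootstrap resampling;
  # positions accumulate, so compare increments at 8 significant digits)
  key_m <- paste(signif(m$eps_um, 8), signif(m$tau_s, 8))
  key_h <- paste(signif(sqrt((h$events$x1 - h$events$x0)^2 +
                             (h$events$y1 - h$events$y0)^2), 8),
                 signif(h$events$t1 - h$events$t0, 8))
  expect_true(all(key_h %in% key_m))
  # and the joint frequencies match within multinomial error (2x2 quadrants)
  me <- stats::median(m$eps_um); mt <- stats::median(m$tau_s)
  p_m <- mean(m$eps_um > me & m$tau_s > mt)
  p_h <- mean(sqrt((h$events$x1 - h$events$x0)^2 +
                   (h$events$y1 - h$events$y0)^2) > me &
              (h$events$t1 - h$events$t0) > mt)
  expect_lt(abs(p_h - p_m), 4 * sqrt(p_m * (1 - p_m) / drawn))
})

test_that("a constant-speed master bounds every particle's average speed", {
  set.seed(8)
  v <- 10
  eps <- stats::rlnorm(500, 1, 0.5)
  th <- stats::runif(500, 0, 2 * pi)
  m <- tibble::tibble(cell_id = 1L, step_index = 1:500,
                      dx_um = eps * cos(th), dy_um = eps * sin(th),
                      eps_um = eps, tau_s = eps / v,
                      tau_wait_s = 0, tau_run_s = eps / v)
  h <- simulate_ctrw(m, ctrw_config(n_particles = 200, t_max = 60, seed = 9))
  r1 <- sqrt(h$events$x1^2 + h$events$y1^2)
  expect_true(all(r1 <= v * h$events$t1 + 1e-9))
})

test_that("a deterministic radial walker crosses L = 10 um at exactly t = 10 s", {
  m <- degenerate_master(dx = 1, dy = 0, tau = 1)
  h <- simulate_ctrw(m, ctrw_config(n_particles = 10, t_max = 30, seed = 2))
  bt <- first_passage(h, radii = 10)[["10"]]
  expect_equal(bt$arrivals, rep(10, 10))
  expect_equal(bt$recovery, 1)
  expect_equal(unname(moments_of_curve(bt)), c(10, 0))
})

test_that("unreachable control planes are censored, not extrapolated", {
  m <- degenerate_master(dx = 1, dy = 0, tau = 1)
  h <- simulate_ctrw(m, ctrw_config(n_particles = 10, t_max = 5, seed = 2))
  bt <- first_passage(h, radii = 50)[["50"]]
  expect_equal(bt$recovery, 0)
  expect_equal(bt$n_arrived, 0L)
  expect_true(bt$unreliable)
})

test_that("mean first-arrival time is non-decreasing in the control radius", {
  m <- independent_master(1000, seed = 10)
  h <- simulate_ctrw(m, ctrw_config(n_particles = 500, t_max = 200, seed = 12))
  bts <- first_passage(h, radii = c(10, 20, 30, 40))
  means <- vapply(bts, function(b) b$mean_arrival, numeric(1))
  expect_true(all(diff(means) >= 0))
  recs <- vapply(bts, function(b) b$recovery, numeric(1))
  expect_true(all(diff(recs) <= 0))
})

test_that("CTRW first-passage matches a dense-step Brownian reference", {
  # walk history built from coarse Brownian trajectories vs an independent
  # fine-step simulation of the same process
  D0 <- 1.5; L <- 8
  tr <- brownian_trajs(n_cells = 800, n_steps = 500, dt = 0.1, D0 = D0,
                       seed = 13)
  bt <- first_passage(as_walk_history(tr, t_max = 50), radii = L)[[1]]
  set.seed(14)
  nref <- 800; nstep <- 5000; dtf <- 0.01
  sd_ <- sqrt(2 * D0 * dtf)
  ref <- vapply(seq_len(nref), function(i) {
    x <- cumsum(stats::rnorm(nstep, sd = sd_))
    y <- cumsum(stats::rnorm(nstep, sd = sd_))
    hit <- which(x^2 + y^2 >= L^2)
    if (length(hit) == 0) NA_real_ else hit[1] * dtf
  }, numeric(1))
  ref <- ref[!is.na(ref) & ref <= 50]
  expect_gt(suppressWarnings(stats::ks.test(bt$arrivals, ref))$p.value, 0.01)
})

test_that("isotropizing resampling preserves jump lengths", {
  m <- degenerate_master(dx = 3, dy = 4, tau = 1)
  h <- simulate_ctrw(m, ctrw_config(n_particles = 50, t_max = 5, seed = 15,
                                    resample_direction = TRUE))
  eps <- sqrt((h$events$x1 - h$events$x0)^2 + (h$events$y1 - h$events$y0)^2)
  expect_equal(eps, rep(5, length(eps)))
  # directions actually vary
  expect_gt(stats::sd(h$events$x1 - h$events$x0), 0.5)
})
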