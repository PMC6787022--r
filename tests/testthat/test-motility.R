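test_that("unit conversions follow the acquisition conventions", {
  expect_identical(frames_to_seconds(1000, 8), 125)
  expect_identical(pixels_to_um(1, 20), 0.65)
  expect_identical(pixels_to_um(1024, 20), 665.6)
  expect_identical(pixels_to_um(1, 50), 0.26)
  tr <- tibble::tibble(cell_id = 1L, frame = c(0L, 999L), x_px = c(0, 1024),
                       y_px = 0)
  cv <- convert_units(tr, frequency = 8, magnification = 20)
  expect_equal(cv$t_s[2], 124.875)  # frame 999 of 1000
  expect_equal(cv$x_um[2], 665.6)
  expect_error(convert_units(tr, frequency = 0, magnification = 20), "frequency")
  expect_error(convert_units(tr, frequency = 8, magnification = -1),
               "magnification")
})

test_that("a straight constant-velocity path segments into a single jump", {
  tr <- straight_traj(n = 20, speed = 40, theta = 0.3)  # 5 um per frame
  st <- segment_steps(tr, body_length = 3)
  expect_equal(nrow(st), 1L)
  expect_equal(st$eps_um, 19 * 5)     # net displacement = total path length
  expect_equal(st$tau_wait_s, 0)
  expect_equal(st$tau_s, 19 * 0.125)
})

test_that("a 90-degree turn splits the path into two jumps", {
  out <- c(seq(0, 45, by = 5), rep(45, 9))
  side <- c(rep(0, 10), seq(5, 45, by = 5))
  st <- segment_steps(um_traj(out, side), body_length = 3)
  expect_equal(nrow(st), 2L)
  expect_equal(st$eps_um, c(45, 45))
})

test_that("sub-body-length jitter accumulates into the next jump's waiting time", {
  set.seed(6)
  # 41 samples (40 intervals) of jitter, then a straight run
  jx <- cumsum(c(0, stats::runif(40, -0.3, 0.3)))
  jy <- cumsum(c(0, stats::runif(40, -0.3, 0.3)))
  rx <- jx[41] + seq(5, 50, by = 5)
  ry <- rep(jy[41], 10)
  st <- segment_steps(um_traj(c(jx, rx), c(jy, ry)), body_length = 3)
  expect_equal(nrow(st), 1L)
  expect_equal(st$tau_wait_s, 40 / 8)
  expect_equal(st$tau_run_s, 10 * 0.125)
})

test_that("segmentation handles degenerate inputs", {
  expect_equal(nrow(segment_steps(um_traj(0, 0), body_length = 2)), 0L)
  # an all-waiting trajectory yields one terminal pure-wait record
  st <- segment_steps(um_traj(rep(0, 30), rep(0, 30)), body_length = 2)
  expect_equal(nrow(st), 1L)
  expect_equal(st$eps_um, 0)
  expect_equal(st$tau_s, 29 / 8)
})

test_that("segmentation is invariant to translation and rotation", {
  g <- generate_trajectories(test_params(n_cells = 8, t_max = 30, seed = 14))
  tr <- sample_trajectories(g, frequency = 8)
  st0 <- segment_steps(tr, body_length = 2)
  for (ang in c(0.37, 2.1)) {
    rot <- tr
    rot$x_um <- cos(ang) * tr$x_um - sin(ang) * tr$y_um + 17
    rot$y_um <- sin(ang) * tr$x_um + cos(ang) * tr$y_um - 5
    st1 <- segment_steps(rot, body_length = 2)
    expect_equal(st1$eps_um, st0$eps_um, tolerance = 1e-9)
    expect_equal(st1$tau_s, st0$tau_s, tolerance = 1e-9)
  }
})

test_that("step times of a trajectory sum to its covered duration", {
  g <- generate_trajectories(test_params(n_cells = 10, t_max = 40, seed = 15))
  tr <- sample_trajectories(g, frequency = 8)
  st <- segment_steps(tr, body_length = 2)
  for (cid in unique(st$cell_id)) {
    dur <- diff(range(tr$t_s[tr$cell_id == cid]))
    expect_lt(abs(sum(st$tau_s[st$cell_id == cid]) - dur), 1 / 8 + 1e-9)
  }
})

test_that("the master table concatenates per-trajectory steps in order", {
  a <- tibble::tibble(cell_id = 1L, step_index = 1:3, dx_um = 1, dy_um = 0,
                      eps_um = 1, tau_s = 1, tau_wait_s = 0.5, tau_run_s = 0.5)
  b <- tibble::tibble(cell_id = 2L, step_index = 1:4, dx_um = 0, dy_um = 2,
                      eps_um = 2, tau_s = 2, tau_wait_s = 1, tau_run_s = 1)
  m <- build_master(list(a, b))
  expect_equal(nrow(m), 7L)
  expect_equal(m$cell_id, c(rep(1L, 3), rep(2L, 4)))
  expect_warning(build_master(list()), "empty")
})

test_that("master-table marginals match the generator's (KS) on synthetic data", {
  p <- test_params(n_cells = 100, t_max = 200, seed = 44)
  g <- generate_trajectories(p)
  st <- segment_steps(g$paths, body_length = 2)  # exact breakpoint segmentation
  # censor each trajectory's final (possibly truncated) record
  st <- dplyr::filter(dplyr::group_by(st, cell_id),
                      step_index < max(step_index))
  m <- build_master(dplyr::ungroup(st))
  expect_gt(nrow(m), 1e4)
  set.seed(1)
  ref_j <- sample_dist(nrow(m), p$jump_pdf_spec)
  ref_w <- sample_dist(nrow(m), p$wait_pdf_spec)
  expect_gt(suppressWarnings(stats::ks.test(m$eps_um, ref_j))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(m$tau_wait_s, ref_w))$p.value, 0.01)
})

test_that("empirical pdf integrates to one and matches closed forms", {
  # single repeated value: all mass in its bin
  pdf1 <- empirical_pdf(rep(2.5, 40), bin_edges = 0:5)
  expect_equal(sum(pdf1$density * (pdf1$bin_right - pdf1$bin_left)), 1)
  expect_equal(pdf1$density[3], 1)  # bin [2,3): mass 1 over width 1
  # uniform samples: density about 1
  set.seed(2)
  pdfu <- empirical_pdf(stats::runif(2e4), bin_edges = seq(0, 1, 0.25))
  expect_true(all(abs(pdfu$density - 1) < 0.05))
  # truncated exponential(1): per-bin density within 3 binomial SE of the
  # analytic value
  n <- 1e5
  spec <- dist_spec("exponential", rate = 1, max = 8)
  x <- sample_dist(n, spec)
  edges <- seq(0, 8, 0.5)
  pdfe <- empirical_pdf(x, edges)
  p_bin <- (stats::pexp(pdfe$bin_right) - stats::pexp(pdfe$bin_left)) /
    stats::pexp(8)
  se <- sqrt(p_bin * (1 - p_bin) / n) / 0.5
  dens_true <- p_bin / 0.5
  expect_true(all(abs(pdfe$density - dens_true) < 3 * se + 1e-8))
  expect_error(empirical_pdf(numeric(0), 0:1), "values")
})

test_that("ensemble moments recover closed-form oracles", {
  # identical trajectories: zero variance at all times
  tr <- dplyr::bind_rows(lapply(1:60, function(i) {
    d <- straight_traj(n = 15, speed = 10); d$cell_id <- i; d
  }))
  mom <- ensemble_moments(tr, min_unique = 50)
  expect_true(all(mom$var_um2 == 0))
  # deterministic radial motion at speed v: mean displacement is exactly v t
  expect_equal(mom$mean_disp_um, 10 * mom$t_s)
  # 2-D Brownian motion with per-axis D0: radial variance grows as 4 D0 t
  D0 <- 2
  btr <- brownian_trajs(n_cells = 500, n_steps = 60, dt = 0.5, D0 = D0, seed = 9)
  bmom <- ensemble_moments(btr, min_unique = 50)
  slope <- stats::coef(stats::lm(var_um2 ~ t_s, data = bmom))[2]
  expect_lt(abs(slope - 4 * D0) / (4 * D0), 0.05)
  # per-axis convention is half the radial variance
  bmom2 <- ensemble_moments(btr, min_unique = 50, variance = "per_axis")
  expect_equal(bmom2$var_um2, bmom$var_um2 / 2)
})

test_that("the moment series is truncated at the unique-trajectory cutoff", {
  tr <- dplyr::bind_rows(lapply(1:60, function(i) {
    n <- if (i <= 55) 20 else 10  # only 55 cells last beyond 10 frames
    d <- straight_traj(n = n, speed = 5); d$cell_id <- i; d
  }))
  mom <- ensemble_moments(tr, min_unique = 56)
  expect_equal(nrow(mom), 10L)
  expect_true(all(mom$n_alive >= 56))
  expect_warning(ensemble_moments(tr, min_unique = 100), "live trajectories")
})

test_that("drift speed is the OLS slope of mean displacement", {
  mk <- function(v) tibble::tibble(t_s = seq(0.5, 50, 0.5),
                                   mean_disp_um = v * seq(0.5, 50, 0.5),
                                   var_um2 = 1, n_alive = 100L)
  expect_equal(drift_speed(mk(0.22)), 0.22)
  expect_equal(drift_speed(mk(0.15)), 0.15)
  expect_equal(drift_speed(mk(0)), 0)
  expect_error(drift_speed(mk(1)[1:2, ]), "3 time points")
  flat <- tibble::tibble(t_s = rep(1, 5), mean_disp_um = 1:5)
  expect_error(drift_speed(flat), "degenerate")
})

test_that("step correlations detect independence, sign, and sparsity", {
  set.seed(10)
  m <- tibble::tibble(cell_id = rep(1:50, each = 40),
                      step_index = rep(1:40, 50),
                      eps_um = stats::rexp(2000) + 0.1,
                      tau_s = stats::rexp(2000) + 0.1)
  sc <- step_correlation(m)
  expect_false(sc$sparse)
  expect_lt(abs(sc$eps_corr), 3 / sqrt(sc$n_pairs))
  expect_lt(abs(sc$tau_corr), 3 / sqrt(sc$n_pairs))
  # alternating long/short waits: negative lag-1 tau correlation
  alt <- tibble::tibble(cell_id = 1L, step_index = 1:40, eps_um = 5,
                        tau_s = rep(c(10, 0.5), 20))
  expect_lt(step_correlation(alt)$tau_corr, 0)
  # fewer than 10 pairs: flagged sparse
  expect_true(step_correlation(m[m$cell_id == 1, ][1:5, ])$sparse)
})

test_that("segmented-marginal KS distance shrinks as the sample grows", {
  one_ks <- function(seed, t_max) {
    p <- test_params(n_cells = 30, t_max = t_max, seed = seed)
    g <- generate_trajectories(p)
    st <- segment_steps(g$paths, body_length = 2)
    st <- st[st$eps_um > 0, ]
    ks_distance(st$eps_um, dist_cdf(p$jump_pdf_spec))
  }
  # 16x more steps: KS distance to the generating marginal should drop
  # about 4-fold; individual draws fluctuate, so average over seed pairs
  ratios <- vapply(51:53, function(s) one_ks(s, 60) / one_ks(s, 960), numeric(1))
  expect_true(all(ratios > 1))
  expect_gt(mean(ratios), 2)
})
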