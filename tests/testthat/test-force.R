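test_that("needle frame rotates onto the centroid-to-tip axis", {
  # particle at the origin, tip at (30, 40): 3-4-5 triangle
  nf <- needle_frame(c(0, 0.1), c(0, 0), tip = c(30, 40))
  expect_equal(nf$dist[1], 50)
  # tip due east of eastward motion: no rotation, x motion stays parallel
  nf_e <- needle_frame(c(0, 1, 2), c(0, 0, 0), tip = c(100, 0))
  expect_equal(nf_e$angle, 0)
  expect_equal(diff(nf_e$x_par), c(1, 1))
  expect_equal(nf_e$y_perp, c(0, 0, 0))
  # tip due north: 90 degree rotation moves x motion into the perpendicular
  nf_n <- needle_frame(c(0, 1, 2), c(0, 0, 0), tip = c(1, 100))
  expect_equal(abs(nf_n$angle), pi / 2, tolerance = 1e-4)
  expect_equal(max(abs(diff(nf_n$x_par))), 0, tolerance = 1e-3)
  expect_equal(abs(diff(nf_n$y_perp)), c(1, 1), tolerance = 1e-3)
  expect_error(needle_frame(c(0, 2), c(0, 0), tip = c(1, 0)), "centroid")
})

test_that("window force reproduces the hand-evaluated drift/diffusion ratio", {
  # v_x = 0.2 um/s exactly; alternating y gives mean step^2 = 0.02 um^2
  # so D_perp = 0.1 um^2/s; F = kB*298K * (0.2e-6 m/s)/(0.1e-12 m^2/s)
  x <- 0.02 * (0:10)
  y <- rep(c(0, sqrt(0.02)), length.out = 11)
  wf <- window_force(x, y, dt = 0.1, min_window = 11)
  expect_equal(wf$v_x, 0.2, tolerance = 1e-12)
  expect_equal(wf$D_perp, 0.1, tolerance = 1e-12)
  expect_equal(wf$F_x, 1.380649e-23 * 298 * (0.2e-6 / 0.1e-12) * 1e15,
               tolerance = 1e-12)
  expect_equal(wf$F_x, 8.23, tolerance = 1e-3)
  # v_x = 0.1, D = 0.1 -> 4.11 fN (thermal energy in fN um)
  wf2 <- window_force(0.01 * (0:10), y, dt = 0.1, min_window = 11)
  expect_equal(round(wf2$F_x, 2), 4.11)
  # zero slope -> zero force
  wf0 <- window_force(rep(0, 11), y, dt = 0.1, min_window = 11)
  expect_equal(wf0$F_x, 0)
  # noise-free straight perpendicular line -> undefined force
  expect_error(window_force(x, rep(0, 11), dt = 0.1, min_window = 11),
               "undefined")
  expect_error(window_force(x[1:5], y[1:5], dt = 0.1, min_window = 11),
               "below the minimum")
})

test_that("optional localization-noise correction shifts D_perp by sigma^2/dt", {
  x <- 0.02 * (0:20)
  y <- rep(c(0, sqrt(0.02)), length.out = 21)
  raw <- window_force(x, y, dt = 0.1, min_window = 21)
  corr <- window_force(x, y, dt = 0.1, min_window = 21, sigma_loc = 0.01)
  expect_equal(raw$D_perp - corr$D_perp, 0.01^2 / 0.1, tolerance = 1e-12)
})

test_that("sliding windows are counted and placed as specified", {
  set.seed(91)
  tr <- data.frame(x_um = cumsum(rnorm(200, 0.02, 0.05)),
                   y_um = cumsum(rnorm(200, 0, 0.05)))
  est <- track_forces(tr, tip = c(1e4, 0), dt = 0.1, window_len = 50,
                      step = 25, track_id = 7L)
  expect_equal(nrow(est), 7L)  # floor((200 - 50)/25) + 1
  expect_equal(est$w_start, seq(0, 150, by = 25))
  expect_equal(est$w_end, est$w_start + 49)
  expect_true(all(est$track_id == 7L))
  # non-overlapping windows
  est2 <- track_forces(tr, tip = c(1e4, 0), dt = 0.1, window_len = 50,
                       step = 50)
  expect_equal(nrow(est2), 4L)
  # too-short track: zero rows, flagged
  short <- track_forces(tr[1:30, ], tip = c(1e4, 0), dt = 0.1)
  expect_equal(nrow(short), 0L)
  expect_true(attr(short, "too_short"))
})

test_that("constant drift with synthetic perpendicular noise gives equal windows", {
  v <- 0.3
  dt <- 0.1
  tr <- data.frame(x_um = v * (0:199) * dt,
                   y_um = rep(c(0, sqrt(0.02)), 100))
  est <- track_forces(tr, tip = c(1e6, 0), dt = dt)
  expect_equal(nrow(est), 7L)
  expect_lt(diff(range(est$F_x)) / mean(est$F_x), 1e-6)
  expect_equal(mean(est$v_x), v, tolerance = 1e-6)
})

test_that("per-track force is the unweighted window mean", {
  est <- data.frame(track_id = 1, F_x = c(10, 12, 14))
  expect_equal(per_track_force(est), 12)
  expect_equal(per_track_force(est[1, ]), 10)
  expect_error(per_track_force(est[0, ]), "no window")
})

test_that("force-distance profile bins correctly and recovers the decay", {
  est <- data.frame(F_x = c(1, 2, 3), d_x = c(12, 15, 18))
  prof <- force_distance_profile(est, bin_edges = c(10, 20))
  expect_equal(prof$profile$mean_F, 2)
  expect_equal(prof$profile$count, 3)
  expect_equal(prof$n_excluded, 0)
  expect_error(force_distance_profile(est, c(20, 10)), "increasing")
  # points beyond the last edge are excluded but counted
  prof2 <- force_distance_profile(est, bin_edges = c(10, 16))
  expect_equal(prof2$profile$count, 2)
  expect_equal(prof2$n_excluded, 1)
  # simulated 1/d field: binned means decrease with distance
  phys <- physical_params()
  ndl <- needle_geometry(tip = c(150, 0), F0 = 30, d0 = 50, p = 1)
  cfg <- sim_config(D_true = 0.13, dt = 0.1, n_frames = 300, n_tracks = 60,
                    sigma_loc = 0, arena = c(-140, 140, -140, 140),
                    start_box = c(-120, 100, -20, 20), seed = 13)
  ts <- simulate_tracks(cfg, ndl, phys)
  est3 <- trackset_forces(ts, ndl)
  prof3 <- force_distance_profile(est3, bin_edges = seq(25, 275, by = 50))
  expect_gte(nrow(prof3$profile), 3)
  rho <- cor(prof3$profile$d_mid, prof3$profile$mean_F, method = "spearman")
  expect_lt(rho, 0)
})

test_that("force estimates are invariant under a global rotation", {
  set.seed(17)
  tr <- data.frame(x_um = cumsum(rnorm(100, 0.03, 0.08)),
                   y_um = cumsum(rnorm(100, 0, 0.08)))
  tip <- c(500, -200)
  est <- track_forces(tr, tip, dt = 0.1)
  th <- 2.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- as.matrix(tr[, c("x_um", "y_um")]) %*% t(R)
  trR <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
  estR <- track_forces(trR, drop(R %*% tip), dt = 0.1)
  expect_equal(estR$F_x, est$F_x, tolerance = 1e-9)
  expect_equal(estR$d_x, est$d_x, tolerance = 1e-9)
})

test_that("ensemble force statistics follow the stated conventions", {
  s <- ensemble_force_stats(c(1, 2, 3))
  expect_equal(s$mean_fN, 2)
  expect_equal(s$sd_fN, 1)
  expect_equal(s$n, 3)
  s1 <- ensemble_force_stats(5)
  expect_true(is.na(s1$sd_fN))
  expect_equal(s1$n, 1)
  expect_error(ensemble_force_stats(numeric(0)), "no forces")
})

test_that("force estimator is consistent and linear in the injected force", {
  phys <- physical_params()
  mean_at <- function(F0, seed, n_tracks = 150) {
    ndl <- constant_force_needle(F0 = F0, tip = c(1000, 0))
    ts <- simulate_tracks(calib_config(n_tracks = n_tracks, seed = seed), ndl,
                          phys)
    ensemble_force_stats(per_track_forces(trackset_forces(ts, ndl)))$mean_fN
  }
  m5 <- mean_at(5, seed = 101)
  m13 <- mean_at(13.4, seed = 102)
  m30 <- mean_at(30, seed = 103)
  expect_lt(abs(m5 - 5) / 5, 0.15)
  expect_lt(abs(m13 - 13.4) / 13.4, 0.15)
  expect_lt(abs(m30 - 30) / 30, 0.15)
  # doubling the injected force doubles the estimate within Monte-Carlo error
  expect_equal(m30 / (2 * 15), 1, tolerance = 0.15)
  m15 <- mean_at(15, seed = 104)
  expect_equal(m30 / m15, 2, tolerance = 0.2)
})

test_that("doubling D at fixed force leaves the estimate centred on the truth", {
  phys <- physical_params()
  ndl <- constant_force_needle(F0 = 13.4, tip = c(1000, 0))
  ts <- simulate_tracks(calib_config(n_tracks = 60, seed = 105,
                                     D_true = 0.26), ndl, phys)
  ptf <- per_track_forces(trackset_forces(ts, ndl))
  s <- ensemble_force_stats(ptf)
  expect_lt(abs(s$mean_fN - 13.4) / 13.4, 0.15)
  # drift velocity doubles with D at fixed force
  v <- mean(unlist(lapply(split_tracks(ts), function(tr) diff(tr$x_um)))) / 0.1
  expect_equal(v, 2 * 13.4 * 0.13 / kBT_fN_um(phys), tolerance = 0.1)
})
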