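test_that("MSD of ballistic motion is exactly quadratic", {
  v <- 1  # um/s
  dt <- 0.1
  tr <- data.frame(x_um = v * (0:50) * dt, y_um = 0)
  msd <- compute_msd(tr, dt, max_lag = 5)
  expect_equal(msd$msd_um2, (v * msd$lag_s)^2, tolerance = 1e-12)
  expect_equal(msd$count, 51 - (1:5))
})

test_that("single-step MSD equals the squared displacement", {
  tr <- data.frame(x_um = c(0, 0.3), y_um = c(0, 0.4))
  msd <- compute_msd(tr, dt = 0.02, max_lag = 1)
  expect_equal(msd$msd_um2, 0.25)
  expect_error(compute_msd(tr, dt = 0.02, max_lag = 2), "track length")
})

test_that("diffusion fit recovers slope/4 and tolerates a noise offset", {
  dt <- 0.02
  lags <- (1:6) * dt
  exact <- structure(data.frame(lag_s = lags, msd_um2 = 4 * 0.13 * lags,
                                count = 100), class = c("msd_curve", "data.frame"))
  est <- fit_diffusion(exact, n_fit_lags = 4)
  expect_equal(est$D, 0.13, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  # a static offset 4*sigma^2 moves the intercept, not the slope
  offset <- exact
  offset$msd_um2 <- offset$msd_um2 + 4 * 0.01^2
  est2 <- fit_diffusion(offset, n_fit_lags = 4)
  expect_equal(est2$D, 0.13, tolerance = 1e-12)
  expect_equal(est2$intercept, 4e-4, tolerance = 1e-12)
  expect_false(est2$negative)
  # a decreasing curve yields a flagged negative estimate, not an error
  dec <- exact
  dec$msd_um2 <- rev(dec$msd_um2)
  expect_true(fit_diffusion(dec, 4)$negative)
})

test_that("per-track D estimates recover the simulated truth", {
  for (D in c(0.03, 0.13)) {
    cfg <- sim_config(D_true = D, dt = 0.02, n_frames = 500, n_tracks = 100,
                      sigma_loc = 0, arena = c(-300, 300, -300, 300),
                      start_box = c(-5, 5, -5, 5), seed = 50 + round(100 * D))
    ts <- simulate_tracks(cfg)
    Dtab <- track_diffusion(ts)
    se <- sd(Dtab$D) / sqrt(nrow(Dtab))
    expect_lt(abs(mean(Dtab$D) - D), 3 * se)
    expect_lt(abs(median(Dtab$D) / D - 1), 0.1)
  }
})

test_that("filters reproduce hand-computed survivor counts", {
  set.seed(61)
  # three tracks: (length, D) = (40, 0.002), (60, 0.02), (300, 0.05)
  coords <- list(brownian_coords(40, 0.002, 0.02),
                 brownian_coords(60, 0.02, 0.02),
                 brownian_coords(300, 0.05, 0.02))
  ts <- multi_track_set(coords, dt = 0.02)
  D <- c(`1` = 0.002, `2` = 0.02, `3` = 0.05)
  kept <- apply_filters(ts, filter_spec_spt(), D)
  expect_equal(n_tracks(kept), 2L)
  expect_equal(attr(kept, "n_discarded"), 1L)
  expect_equal(unique(kept$tracks$track_id), c(2L, 3L))
  # idempotence
  again <- apply_filters(kept, filter_spec_spt(), D)
  expect_equal(again$tracks, kept$tracks)
  # force preset: a 300-frame mobile track with net displacement ~4 um fails
  # the 10 um displacement rule
  straight <- multi_track_set(list(cbind(seq(0, 4, length.out = 300),
                                         0)), dt = 0.1)
  out <- apply_filters(straight, filter_spec_force(), c(`1` = 0.05))
  expect_equal(n_tracks(out), 0L)
  # ...and passes once it runs 12 um
  long <- multi_track_set(list(cbind(seq(0, 12, length.out = 300), 0)),
                          dt = 0.1)
  expect_equal(n_tracks(apply_filters(long, filter_spec_force(),
                                      c(`1` = 0.05))), 1L)
  # missing D errors
  expect_error(apply_filters(ts, filter_spec_spt(), D[1:2]), "missing")
})

test_that("filtering an empty track set returns an empty track set", {
  empty <- track_set(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)), dt = 0.02)
  out <- apply_filters(empty, filter_spec_spt(), setNames(numeric(0), character(0)))
  expect_equal(nrow(out$tracks), 0L)
})

test_that("diffusion summaries use log-scale moments", {
  s <- summarize_D(c(0.1, 0.1, 0.1))
  expect_equal(s$mean, 0.1)
  expect_equal(s$median, 0.1)
  expect_equal(s$sd_logD, 0)
  s2 <- summarize_D(c(0.05, 0.15))
  expect_equal(s2$mean, 0.10)
  expect_equal(s2$median, 0.10)
  # non-positive values excluded from log moments, with count
  s3 <- summarize_D(c(-0.01, 0.1, 0.2))
  expect_equal(s3$n_nonpositive, 1L)
  expect_equal(s3$mean_logD, mean(log(c(0.1, 0.2))))
  expect_error(summarize_D(numeric(0)), "no diffusion")
  # sampling: log-normal D around ln(0.13)
  set.seed(71)
  Ds <- exp(rnorm(1000, log(0.13), 0.5))
  s4 <- summarize_D(Ds)
  expect_lt(abs(s4$mean_logD - log(0.13)), 3 * 0.5 / sqrt(1000))
})

test_that("paired log t-test matches its closed form and invariances", {
  expect_error(paired_logD_test(c(1, 2), c(1, 2, 3)), "equal lengths")
  expect_error(paired_logD_test(c(1, -2), c(1, 2)), "positive")
  # identical pairs: t = 0, p = 1
  r0 <- paired_logD_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # symmetric log differences {+0.1, -0.1}: t = 0, p = 1
  r1 <- paired_logD_test(exp(c(0.1, -0.1)), c(1, 1))
  expect_equal(r1$t, 0, tolerance = 1e-12)
  expect_equal(r1$p, 1, tolerance = 1e-12)
  # rescaling every D by a common factor leaves the test unchanged
  before <- c(0.04, 0.05, 0.03, 0.06, 0.05)
  after <- c(0.05, 0.04, 0.04, 0.05, 0.06)
  ra <- paired_logD_test(before, after)
  rb <- paired_logD_test(7.3 * before, 7.3 * after)
  expect_equal(ra$t, rb$t, tolerance = 1e-10)
  expect_equal(ra$p, rb$p, tolerance = 1e-10)
  expect_equal(ra$df, length(before) - 1)
})

test_that("ten pairs built for t = 0.63 on logs give p = 0.54", {
  d0 <- (1:10) - mean(1:10)           # mean-zero log differences
  m <- 0.63 * sd(d0) / sqrt(10)       # shift so the paired t equals 0.63
  d <- d0 + m
  res <- paired_logD_test(exp(d), rep(1, 10))
  expect_equal(res$t, 0.63, tolerance = 1e-10)
  expect_equal(res$df, 9)
  expect_equal(round(res$p, 2), 0.54)
})

test_that("two-sided t p-value is symmetric, monotone and correct at limits", {
  expect_equal(students_t_pvalue(0, 5), 1)
  expect_lt(students_t_pvalue(50, 9), 1e-10)
  expect_error(students_t_pvalue(1, 0), "degrees of freedom")
  ts <- seq(0, 5, by = 0.25)
  ps <- students_t_pvalue(ts, 9)
  expect_true(all(diff(ps) < 0))
  expect_equal(students_t_pvalue(-1.7, 7), students_t_pvalue(1.7, 7))
  # agrees with the generic t.test machinery on real data
  set.seed(81)
  x <- rnorm(12)
  ht <- t.test(x)
  expect_equal(students_t_pvalue(unname(ht$statistic), 11), ht$p.value,
               tolerance = 1e-12)
})
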