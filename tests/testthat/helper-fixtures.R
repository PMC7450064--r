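# Shared fixtures for the test suite. All fixtures are built in code with
# fixed seeds; nothing is read from disk.

# a far-away needle with a spatially constant pull (p = 0), used for
# constant-force calibration simulations
constant_force_needle <- function(F0 = 13.4, tip = c(1000, 0)) {
  needle_geometry(tip = tip, F0 = F0, d0 = 50, p = 0)
}

# calibration-style simulation config: 0.1 s frames, 500-frame tracks
calib_config <- function(n_tracks, seed, D_true = 0.13, sigma_loc = 0.01,
                         n_frames = 500) {
  sim_config(D_true = D_true, dt = 0.1, n_frames = n_frames,
             n_tracks = n_tracks, sigma_loc = sigma_loc,
             arena = c(-80, 80, -80, 80), start_box = c(-30, 30, -30, 30),
             seed = seed)
}

# single-track track_set from bare coordinate vectors
toy_track_set <- function(x, y, dt = 0.1, id = 1L) {
  n <- length(x)
  track_set(data.frame(track_id = id, frame = 0:(n - 1),
                       t_s = (0:(n - 1)) * dt, x_um = x, y_um = y), dt = dt)
}

# multi-track set from a list of (x, y) matrices
multi_track_set <- function(coords, dt = 0.1) {
  dfs <- lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    n <- nrow(m)
    data.frame(track_id = i, frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
               x_um = m[, 1], y_um = m[, 2])
  })
  track_set(do.call(rbind, dfs), dt = dt)
}

# Brownian track coordinates (no drift), in code rather than via the
# simulator, for tests that need an oracle independent of simulate_tracks()
brownian_coords <- function(n, D, dt, x0 = 0, y0 = 0) {
  s <- sqrt(2 * D * dt)
  cbind(x0 + cumsum(c(0, rnorm(n - 1, sd = s))),
        y0 + cumsum(c(0, rnorm(n - 1, sd = s))))
}
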