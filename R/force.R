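#' Rotate a trajectory into the needle frame
#'
#' Decomposes positions into the component directed at the needle tip and
#' the perpendicular (Brownian) component. The +x axis of the rotated frame
#' points from the trajectory centroid towards the tip, so positive
#' parallel velocity means motion towards the needle; coordinates are
#' reported relative to the centroid.
#'
#' @param x,y Numeric position vectors (um).
#' @param tip Length-2 needle tip position (um).
#' @return List with `x_par` (along centroid-to-tip axis), `y_perp`,
#'   `dist` (per-frame Euclidean distance to the tip, um) and `angle`
#'   (rotation angle, rad).
#' @export
needle_frame <- function(x, y, tip) {
  stopifnot(length(x) == length(y), length(tip) == 2L)
  cx <- mean(x)
  cy <- mean(y)
  ux <- tip[1] - cx
  uy <- tip[2] - cy
  d <- sqrt(ux^2 + uy^2)
  if (d < 1e-9) stop("needle tip coincides with the trajectory centroid")
  ux <- ux / d
  uy <- uy / d
  list(x_par = (x - cx) * ux + (y - cy) * uy,
       y_perp = -(x - cx) * uy + (y - cy) * ux,
       dist = sqrt((tip[1] - x)^2 + (tip[2] - y)^2),
       angle = atan2(uy, ux))
}

#' Force on a particle from one trajectory window
#'
#' Implements the drift-to-diffusion force estimate
#' \deqn{F_x = k_B T \, v_x / D_\perp:}
#' the directed velocity `v_x` is the OLS slope of the tip-directed
#' coordinate against time ("linear movement" towards the needle), and the
#' diffusion coefficient is estimated from the fluctuations perpendicular
#' to the pull, \eqn{D_\perp = \langle \Delta y_\perp^2 \rangle / (2 dt)}
#' over lag-1 steps. No localization-noise correction is applied by
#' default; `sigma_loc` enables the optional correction subtracting
#' \eqn{\sigma_{loc}^2/dt} from \eqn{D_\perp}.
#'
#' @param x_par Tip-directed coordinate (um), e.g. from [needle_frame()].
#' @param y_perp Perpendicular coordinate (um).
#' @param dt Frame interval (s).
#' @param phys A [physical_params()] object.
#' @param min_window Minimum number of frames (default 20).
#' @param sigma_loc Optional localization noise s.d. (um) to subtract from
#'   the perpendicular MSD; 0 (default) disables the correction.
#' @return List with `F_x` (fN, positive towards the tip), `v_x` (um/s),
#'   `D_perp` (um^2/s), `n` (window length).
#' @export
window_force <- function(x_par, y_perp, dt, phys = physical_params(),
                         min_window = 20, sigma_loc = 0) {
  n <- length(x_par)
  stopifnot(n == length(y_perp), dt > 0, sigma_loc >= 0)
  if (n < min_window) {
    stop(sprintf("window of %d frames is below the minimum of %d", n, min_window))
  }
  t <- (seq_len(n) - 1) * dt
  tc <- t - mean(t)
  v_x <- sum(tc * (x_par - mean(x_par))) / sum(tc^2)
  D_perp <- mean(diff(y_perp)^2) / (2 * dt) - sigma_loc^2 / dt
  if (D_perp <= 0) {
    stop("perpendicular diffusion is zero or negative; force undefined")
  }
  list(F_x = kBT_fN_um(phys) * v_x / D_perp, v_x = v_x, D_perp = D_perp,
       n = n)
}

#' Sliding-window force estimates along one trajectory
#'
#' Splits a track into windows of `window_len` frames advanced by `step`
#' frames (default 50% overlap), rotates each window into the needle frame
#' and applies [window_force()]. Each estimate carries `d_x`, the mean
#' Euclidean distance to the tip over its window, for force-distance
#' profiling.
#'
#' @param traj Single-track data frame with `x_um`, `y_um` (frame order).
#' @param tip Length-2 needle tip position (um), or a [needle_geometry()].
#' @param dt Frame interval (s).
#' @param window_len Window length in frames (default 50).
#' @param step Window advance in frames (default 25).
#' @param phys A [physical_params()] object.
#' @param track_id Identifier carried into the result.
#' @param sigma_loc Optional noise correction, see [window_force()].
#' @return Data frame with one row per window: `track_id`, `w_start`,
#'   `w_end` (0-based frames), `F_x`, `v_x`, `D_perp`, `d_x`. A track
#'   shorter than one window yields zero rows with attribute
#'   `too_short = TRUE`.
#' @export
track_forces <- function(traj, tip, dt, window_len = 50, step = 25,
                         phys = physical_params(), track_id = NA,
                         sigma_loc = 0) {
  stopifnot(is.data.frame(traj), all(c("x_um", "y_um") %in% names(traj)),
            window_len >= 2, step >= 1)
  if (inherits(tip, "needle_geometry")) tip <- tip$tip
  n <- nrow(traj)
  empty <- data.frame(track_id = vector(class(track_id), 0),
                      w_start = integer(0), w_end = integer(0),
                      F_x = numeric(0), v_x = numeric(0),
                      D_perp = numeric(0), d_x = numeric(0))
  if (n < window_len) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  starts <- seq(1L, n - window_len + 1L, by = step)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window_len - 1L)
    nf <- needle_frame(traj$x_um[idx], traj$y_um[idx], tip)
    wf <- window_force(nf$x_par, nf$y_perp, dt, phys,
                       min_window = window_len, sigma_loc = sigma_loc)
    data.frame(track_id = track_id, w_start = s - 1L,
               w_end = s + window_len - 2L, F_x = wf$F_x, v_x = wf$v_x,
               D_perp = wf$D_perp, d_x = mean(nf$dist))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window forces for every track in a set
#'
#' @param ts A [track_set()].
#' @param tip Needle tip (length-2 um vector or [needle_geometry()]).
#' @inheritParams track_forces
#' @return Data frame of window estimates across all tracks (see
#'   [track_forces()]).
#' @export
trackset_forces <- function(ts, tip, window_len = 50, step = 25,
                            phys = physical_params(), sigma_loc = 0) {
  stopifnot(inherits(ts, "track_set"))
  trs <- split_tracks(ts)
  out <- lapply(trs, function(tr) {
    track_forces(tr, tip, ts$dt, window_len, step, phys,
                 track_id = tr$track_id[1], sigma_loc = sigma_loc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-track force: mean over a track's window estimates
#'
#' @param estimates Data frame of window estimates for one track (from
#'   [track_forces()]); must contain at least one row.
#' @return Unweighted mean of window `F_x`, in fN.
#' @export
per_track_force <- function(estimates) {
  stopifnot(is.data.frame(estimates), "F_x" %in% names(estimates))
  if (!nrow(estimates)) stop("no window estimates for this track")
  mean(estimates$F_x)
}

#' Per-track forces for a whole window-estimate table
#'
#' @param estimates Window-estimate data frame from [trackset_forces()].
#' @return Named numeric vector of per-track mean forces (fN).
#' @export
per_track_forces <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) > 0)
  vapply(split(estimates, estimates$track_id), per_track_force, numeric(1))
}

#' Force-distance profile
#'
#' Bins window force estimates by their mean distance to the tip and
#' reports per-bin mean, sample s.d. and count. Estimates outside the bin
#' range are excluded; their number is reported so counts are conserved.
#'
#' @param estimates Window-estimate data frame with `F_x` and `d_x`.
#' @param bin_edges Strictly increasing numeric bin edges (um).
#' @return List with `profile` (data frame: `d_mid`, `mean_F`, `sd_F`,
#'   `count`; empty bins absent) and `n_excluded`.
#' @export
force_distance_profile <- function(estimates, bin_edges) {
  stopifnot(is.data.frame(estimates),
            all(c("F_x", "d_x") %in% names(estimates)))
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  bins <- cut(estimates$d_x, breaks = bin_edges, include.lowest = TRUE)
  inside <- !is.na(bins)
  by_bin <- split(estimates$F_x[inside], droplevels(bins[inside]))
  mids <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  names(mids) <- levels(cut(numeric(0), breaks = bin_edges,
                            include.lowest = TRUE))
  prof <- data.frame(
    d_mid = unname(mids[names(by_bin)]),
    mean_F = vapply(by_bin, mean, numeric(1)),
    sd_F = vapply(by_bin, function(v) if (length(v) > 1) sd(v) else NA_real_,
                  numeric(1)),
    count = vapply(by_bin, length, numeric(1))
  )
  prof <- prof[order(prof$d_mid), ]
  rownames(prof) <- NULL
  list(profile = prof, n_excluded = sum(!inside))
}

#' Ensemble force statistics
#'
#' @param forces Numeric vector of per-track forces (fN), n >= 1.
#' @return List with `mean_fN`, `sd_fN` (NA when n = 1), `n`.
#' @export
ensemble_force_stats <- function(forces) {
  forces <- forces[!is.na(forces)]
  if (!length(forces)) stop("no forces to summarize")
  list(mean_fN = mean(forces),
       sd_fN = if (length(forces) > 1) sd(forces) else NA_real_,
       n = length(forces))
}
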