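#' Time-averaged mean squared displacement of one track
#'
#' \eqn{MSD(k\,dt) = \langle |r(i+k) - r(i)|^2 \rangle_i} over all start
#' points, for lags 1..`max_lag` frames.
#'
#' @param traj Data frame with columns `x_um`, `y_um` in frame order
#'   (uniform frame interval assumed).
#' @param dt Frame interval in seconds.
#' @param max_lag Largest lag in frames; must be below the track length.
#' @return An object of class `msd_curve`: data frame with columns `lag_s`,
#'   `msd_um2`, `count`.
#' @export
compute_msd <- function(traj, dt, max_lag = 4) {
  stopifnot(is.data.frame(traj), all(c("x_um", "y_um") %in% names(traj)),
            dt > 0, max_lag >= 1)
  n <- nrow(traj)
  if (max_lag >= n) stop("max_lag must be smaller than the track length")
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    dx <- traj$x_um[(k + 1):n] - traj$x_um[1:(n - k)]
    dy <- traj$y_um[(k + 1):n] - traj$y_um[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  structure(data.frame(lag_s = lags * dt, msd_um2 = msd,
                       count = n - lags),
            class = c("msd_curve", "data.frame"))
}

#' Pooled MSD across all tracks of a set
#'
#' Count-weighted average of the per-track time-averaged MSD curves: every
#' displacement pair across the ensemble contributes equally.
#'
#' @param ts A [track_set()].
#' @param max_lag Largest lag in frames; tracks shorter than `max_lag + 1`
#'   frames contribute only their available lags.
#' @return An `msd_curve` (see [compute_msd()]) with pooled counts.
#' @export
pooled_msd <- function(ts, max_lag = 4) {
  stopifnot(inherits(ts, "track_set"))
  curves <- lapply(split_tracks(ts), function(tr) {
    ml <- min(max_lag, nrow(tr) - 1L)
    if (ml < 1L) return(NULL)
    compute_msd(tr, ts$dt, max_lag = ml)
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (!length(curves)) stop("no track long enough for any lag")
  lags <- seq_len(max_lag) * ts$dt
  num <- den <- numeric(max_lag)
  for (cv in curves) {
    k <- seq_len(nrow(cv))
    num[k] <- num[k] + cv$msd_um2 * cv$count
    den[k] <- den[k] + cv$count
  }
  keep <- den > 0
  structure(data.frame(lag_s = lags[keep], msd_um2 = num[keep] / den[keep],
                       count = den[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of MSD against lag time over the first
#' `n_fit_lags` lags, with a free intercept that absorbs the static
#' localization-noise offset (\eqn{4\sigma_{loc}^2} for 2D data). For 2D
#' Brownian motion the slope is \eqn{4D}, so `D = slope / 4`. A negative
#' fitted slope is reported as is and flagged, not censored.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_fit_lags Number of leading lags to fit (>= 2). Default 4; short
#'   lags limit the bias from correlated MSD points.
#' @param track_id Optional identifier carried through to the result.
#' @return List of class `diffusion_estimate` with `D` (um^2/s),
#'   `intercept` (um^2), `n_fit_lags`, `track_id`, `negative` flag.
#' @export
fit_diffusion <- function(msd, n_fit_lags = 4, track_id = NA) {
  stopifnot(inherits(msd, "msd_curve"), n_fit_lags >= 2)
  if (n_fit_lags > nrow(msd)) {
    stop("n_fit_lags exceeds the number of available lags")
  }
  d <- msd[seq_len(n_fit_lags), ]
  fit <- lm(msd_um2 ~ lag_s, data = d)
  slope <- unname(coef(fit)[2])
  structure(list(D = slope / 4, intercept = unname(coef(fit)[1]),
                 n_fit_lags = as.integer(n_fit_lags), track_id = track_id,
                 negative = slope < 0),
            class = "diffusion_estimate")
}

#' Per-track diffusion coefficients for a track set
#'
#' Convenience wrapper: [compute_msd()] + [fit_diffusion()] per track.
#' Tracks too short for the requested lags get `D = NA`.
#'
#' @param ts A [track_set()].
#' @param n_fit_lags Lags used in the fit (default 4).
#' @return Data frame with columns `track_id`, `n_frames`, `D`, `intercept`.
#' @export
track_diffusion <- function(ts, n_fit_lags = 4) {
  stopifnot(inherits(ts, "track_set"))
  trs <- split_tracks(ts)
  out <- lapply(names(trs), function(id) {
    tr <- trs[[id]]
    if (nrow(tr) <= n_fit_lags) {
      return(data.frame(track_id = tr$track_id[1], n_frames = nrow(tr),
                        D = NA_real_, intercept = NA_real_))
    }
    est <- fit_diffusion(compute_msd(tr, ts$dt, max_lag = n_fit_lags),
                         n_fit_lags, track_id = tr$track_id[1])
    data.frame(track_id = tr$track_id[1], n_frames = nrow(tr),
               D = est$D, intercept = est$intercept)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Track filtering rules
#'
#' Thresholds used to discard immobile, short, or (for force calibration)
#' insufficiently displaced tracks. Two presets mirror the standard
#' analysis settings:
#' * `filter_spec_spt()` - SPT analysis: discard immobile particles
#'   (D < 0.005 um^2/s) and tracks shorter than 50 frames.
#' * `filter_spec_force()` - force calibration: discard tracks slower than
#'   0.01 um^2/s, shorter than 200 frames, or with a net displacement
#'   smaller than 10 um.
#'
#' "Displacement" is the net start-to-end Euclidean distance: magnet-pulled
#' tracks are nearly straight, so net displacement and path length nearly
#' coincide, and net displacement is the conventional reading.
#'
#' @param min_length Minimum track length in frames (>= 2).
#' @param D_min Minimum diffusion coefficient, um^2/s.
#' @param min_displacement Minimum net start-to-end displacement in um, or
#'   `NA` to skip this criterion.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_length, D_min, min_displacement = NA_real_) {
  stopifnot(min_length >= 2, D_min >= 0)
  structure(list(min_length = as.integer(min_length), D_min = D_min,
                 min_displacement = min_displacement),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
filter_spec_spt <- function() filter_spec(50, 0.005)

#' @rdname filter_spec
#' @export
filter_spec_force <- function() filter_spec(200, 0.01, 10)

#' Apply track filters
#'
#' Keeps tracks with length >= `min_length`, `D >= D_min`, and (when set)
#' net displacement >= `min_displacement`. Track order is preserved;
#' applying the same spec twice is idempotent.
#'
#' @param ts A [track_set()].
#' @param spec A [filter_spec()].
#' @param D Named numeric vector of per-track diffusion coefficients
#'   (names = track ids), e.g. from [track_diffusion()]. Every track in
#'   `ts` must have an entry.
#' @return The filtered [track_set()]; attribute `n_discarded` records the
#'   number of tracks removed.
#' @export
apply_filters <- function(ts, spec, D) {
  stopifnot(inherits(ts, "track_set"), inherits(spec, "filter_spec"))
  lens <- track_lengths(ts)
  ids <- names(lens)
  if (is.null(names(D))) stop("D must be a named vector (names = track ids)")
  miss <- setdiff(ids, names(D))
  if (length(miss)) {
    stop("missing diffusion coefficient for track(s): ",
         paste(miss, collapse = ", "))
  }
  keep <- lens >= spec$min_length & !is.na(D[ids]) & D[ids] >= spec$D_min
  if (!is.na(spec$min_displacement)) {
    keep <- keep & net_displacements(ts)[ids] >= spec$min_displacement
  }
  kept_ids <- ids[keep]
  out <- track_set(ts$tracks[ts$tracks$track_id %in% kept_ids, , drop = FALSE],
                   dt = ts$dt, pixel_size_nm = ts$pixel_size_nm,
                   notes = ts$notes)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Summary statistics of diffusion coefficients
#'
#' Arithmetic mean and median of D, plus moments of ln(D). Diffusion
#' coefficients of tracked membrane particles are approximately log-normal,
#' so location/scale statistics are computed on the natural log; non-positive
#' values are excluded from the log moments and their count reported.
#'
#' @param Ds Numeric vector of diffusion coefficients (um^2/s).
#' @return List with `mean`, `median`, `n`, `mean_logD`, `sd_logD`,
#'   `n_nonpositive`.
#' @export
summarize_D <- function(Ds) {
  Ds <- Ds[!is.na(Ds)]
  if (!length(Ds)) stop("no diffusion coefficients to summarize")
  pos <- Ds[Ds > 0]
  list(mean = mean(Ds), median = median(Ds), n = length(Ds),
       mean_logD = if (length(pos)) mean(log(pos)) else NA_real_,
       sd_logD = if (length(pos) > 1) sd(log(pos)) else NA_real_,
       n_nonpositive = sum(Ds <= 0))
}

#' Paired t-test on log diffusion coefficients
#'
#' Two-tailed paired Student's t-test on ln(before) - ln(after), the
#' appropriate scale for log-normally distributed D. The t statistic is
#' invariant to the log base and to rescaling all values by a common
#' positive factor.
#'
#' @param before,after Positive numeric vectors of equal length n >= 2
#'   (paired per particle).
#' @return List of class `ttest_result` with `t`, `df`, `p`.
#' @export
paired_logD_test <- function(before, after) {
  if (length(before) != length(after)) {
    stop("before and after must have equal lengths (paired values)")
  }
  if (length(before) < 2) stop("at least 2 pairs are required")
  if (any(before <= 0) || any(after <= 0)) {
    stop("all diffusion coefficients must be positive for the log test")
  }
  d <- log(before) - log(after)
  if (sd(d) == 0) {
    # degenerate: all paired differences identical; t is 0 when they vanish,
    # +/-Inf otherwise
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(structure(list(t = t_stat, df = length(d) - 1L,
                          p = if (t_stat == 0) 1 else 0),
                     class = "ttest_result"))
  }
  ht <- t.test(log(before), log(after), paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "ttest_result")
}

#' Two-sided Student's t p-value
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-sided tail probability.
#' @examples
#' students_t_pvalue(0.63, 9)  # 0.54 at two decimals
#' @export
students_t_pvalue <- function(t, df) {
  stopifnot(is.numeric(t), is.numeric(df))
  if (df < 1) stop("degrees of freedom must be >= 1")
  2 * pt(-abs(t), df)
}
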