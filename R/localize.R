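# Separable Gaussian convolution with replicate padding. Kernel radius
# 3*sigma; works on frames smaller than the kernel, which FFT-based image
# filters reject.
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- numeric(length(v))
    for (j in seq_along(k)) out <- out + k[j] * vp[j:(j + length(v) - 1L)]
    out
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

#' Detect and localize diffraction-limited spots in one frame
#'
#' Detection runs on a band-passed image (difference of Gaussians at 1x and
#' 2x the PSF sigma); candidate pixels are local 3 x 3 maxima exceeding
#' `detect_threshold` robust standard deviations (MAD) above the median of
#' the band-passed image. Each candidate is refined by least-squares fitting
#' of a 2D Gaussian plus constant offset in a window of half-width
#' `3 * psf_sigma` pixels. Fits that fail to converge, collapse to
#' non-positive width, or wander outside their window are flagged
#' `fit_ok = FALSE` and should be excluded downstream.
#'
#' @param frame Numeric matrix (rows x cols) of pixel intensities.
#' @param cam A [camera_model()] matching the frame geometry.
#' @param detect_threshold Detection threshold in robust s.d. units above
#'   the median of the band-passed image. Default 5.
#' @param fixed_sigma If `TRUE`, the Gaussian width is fixed at the camera
#'   PSF sigma instead of being fitted. Default `FALSE` (free width), since
#'   large nanoparticle labels slightly broaden spots.
#' @return Data frame with columns `x_um`, `y_um`, `amplitude` (integrated
#'   photons, `2 pi sigma^2 A`), `fit_sigma_nm`, `fit_ok`.
#' @export
localize_spots <- function(frame, cam, detect_threshold = 5,
                           fixed_sigma = FALSE) {
  stopifnot(is.matrix(frame), inherits(cam, "camera_model"))
  if (!all(dim(frame) == cam$frame_shape)) {
    stop("frame dimensions do not match the camera model")
  }
  s_px <- cam$psf_sigma_nm / cam$pixel_size_nm
  band <- gauss_smooth(frame, s_px) - gauss_smooth(frame, 2 * s_px)
  thr <- median(band) + detect_threshold * mad(band)
  nr <- nrow(band)
  nc <- ncol(band)
  win <- max(2L, ceiling(3 * s_px))
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      amplitude = numeric(0), fit_sigma_nm = numeric(0),
                      fit_ok = logical(0))
  if (nr < 2 * win + 1 || nc < 2 * win + 1) return(empty)
  # 3x3 local maxima away from the fitting margin
  cand <- which(band > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > win & cand[, 1] <= nr - win &
               cand[, 2] > win & cand[, 2] <= nc - win, , drop = FALSE]
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    band[r, c] >= max(band[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  px_um <- cam$pixel_size_nm / 1000
  res <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rows <- (r0 - win):(r0 + win)
    cols <- (c0 - win):(c0 + win)
    z <- as.vector(frame[rows, cols])
    yy <- rep(rows - 1, times = length(cols))   # y in px (0-based)
    xx <- rep(cols - 1, each = length(rows))    # x in px (0-based)
    b0 <- min(z)
    A0 <- max(frame[r0, c0] - b0, 1e-6)
    # par = (A, x0, y0, b) or (A, x0, y0, b, s); positional because nls.lm
    # does not preserve names in the callback
    par0 <- if (fixed_sigma) c(A0, c0 - 1, r0 - 1, b0)
            else c(A0, c0 - 1, r0 - 1, b0, s_px)
    resid_fn <- function(par) {
      s <- if (fixed_sigma) s_px else par[5]
      par[4] + par[1] *
        exp(-((xx - par[2])^2 + (yy - par[3])^2) / (2 * s^2)) - z
    }
    fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = resid_fn,
                                       control = minpack.lm::nls.lm.control(maxiter = 100)),
                    error = function(e) NULL)
    bad <- function() data.frame(x_um = (c0 - 1) * px_um, y_um = (r0 - 1) * px_um,
                                 amplitude = NA_real_, fit_sigma_nm = NA_real_,
                                 fit_ok = FALSE)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(bad())
    p <- unlist(fit$par)
    s_fit <- if (fixed_sigma) s_px else abs(p[5])
    if (!is.finite(s_fit) || s_fit <= 0 ||
        abs(p[2] - (c0 - 1)) > win || abs(p[3] - (r0 - 1)) > win) {
      return(bad())
    }
    data.frame(x_um = p[2] * px_um, y_um = p[3] * px_um,
               amplitude = 2 * pi * s_fit^2 * p[1],
               fit_sigma_nm = s_fit * cam$pixel_size_nm,
               fit_ok = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Localize spots in every frame of a stack
#'
#' @param fs A `frame_stack` from [render_frames()] or [read_frame_stack()].
#' @param cam A [camera_model()]; defaults to one matching the stack's
#'   pixel size and frame shape with default PSF/noise settings.
#' @param ... Passed to [localize_spots()].
#' @return Data frame of localizations with a 0-based `frame` column.
#' @export
localize_stack <- function(fs, cam = NULL, ...) {
  stopifnot(inherits(fs, "frame_stack"))
  d <- dim(fs$frames)
  if (is.null(cam)) {
    cam <- camera_model(pixel_size_nm = fs$pixel_size_nm,
                        frame_shape = d[1:2])
  }
  out <- lapply(seq_len(d[3]), function(i) {
    loc <- localize_spots(fs$frames[, , i], cam, ...)
    if (nrow(loc)) cbind(frame = i - 1L, loc) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), amplitude = numeric(0),
                      fit_sigma_nm = numeric(0), fit_ok = logical(0)))
  }
  do.call(rbind, out)
}

#' Link per-frame localizations into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' a localization in frame f and one in frame f+1 are linked when each is
#' the other's nearest neighbour and their distance does not exceed
#' `max_disp`. Unmatched localizations start new tracks; there is no gap
#' closing, so a track ends as soon as its particle misses one frame. Ties
#' are broken by smaller distance, then by lower track id.
#'
#' @param locs Data frame of localizations with columns `frame`, `x_um`,
#'   `y_um` and optionally `fit_ok` (rows with `fit_ok = FALSE` are dropped).
#' @param max_disp Maximum linking distance per frame, um.
#' @param dt Frame interval in seconds.
#' @return A [track_set()].
#' @export
link_localizations <- function(locs, max_disp, dt) {
  stopifnot(is.data.frame(locs), max_disp > 0, dt > 0)
  if ("fit_ok" %in% names(locs)) locs <- locs[locs$fit_ok, , drop = FALSE]
  locs <- locs[order(locs$frame), , drop = FALSE]
  if (!nrow(locs)) {
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)), dt = dt))
  }
  frames <- sort(unique(locs$frame))
  next_id <- 1L
  rows <- vector("list", length(frames))
  prev <- NULL  # data.frame: track_id, x_um, y_um (ordered by track_id)
  for (k in seq_along(frames)) {
    f <- frames[k]
    cur <- locs[locs$frame == f, c("x_um", "y_um"), drop = FALSE]
    cur$track_id <- NA_integer_
    if (!is.null(prev) && k > 1L && frames[k - 1L] == f - 1L && nrow(prev)) {
      dmat <- outer(prev$x_um, cur$x_um, "-")^2 +
              outer(prev$y_um, cur$y_um, "-")^2
      dmat <- sqrt(dmat)
      # mutual nearest neighbours under the threshold, smallest distance first
      ord <- order(dmat)
      used_p <- logical(nrow(prev))
      used_c <- logical(nrow(cur))
      for (idx in ord) {
        if (dmat[idx] > max_disp) break
        i <- (idx - 1L) %% nrow(prev) + 1L
        j <- (idx - 1L) %/% nrow(prev) + 1L
        if (used_p[i] || used_c[j]) next
        if (which.min(dmat[i, ]) == j && which.min(dmat[, j]) == i) {
          cur$track_id[j] <- prev$track_id[i]
          used_p[i] <- TRUE
          used_c[j] <- TRUE
        }
      }
    }
    new <- which(is.na(cur$track_id))
    if (length(new)) {
      cur$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    rows[[k]] <- data.frame(track_id = cur$track_id, frame = f,
                            t_s = f * dt, x_um = cur$x_um, y_um = cur$y_um)
    prev <- cur[order(cur$track_id), c("track_id", "x_um", "y_um")]
  }
  track_set(do.call(rbind, rows), dt = dt)
}

#' Localization precision from an immobile particle
#'
#' The standard deviation of repeated localizations of a stuck particle is
#' the empirical localization precision. Immobility is asserted by the
#' caller (the deliberate use of stuck particles), not auto-detected.
#' Sample (n - 1) standard deviations are used.
#'
#' @param traj Data frame with columns `x_um`, `y_um` (a single track).
#' @return List with `sigma_x_nm`, `sigma_y_nm`, `n_localizations`.
#' @export
localization_precision <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("x_um", "y_um") %in% names(traj)))
  n <- nrow(traj)
  if (n < 2L) stop("localization precision requires at least 2 localizations")
  list(sigma_x_nm = sd(traj$x_um) * 1000,
       sigma_y_nm = sd(traj$y_um) * 1000,
       n_localizations = n)
}
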