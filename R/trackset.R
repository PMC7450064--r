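#' Construct a track set
#'
#' A track set is the package's container for single-particle trajectories:
#' a data frame with columns `track_id`, `frame`, `t_s`, `x_um`, `y_um`
#' (frames are 0-based integers; `t_s = frame * dt`) plus shared metadata.
#' All tracks in a set share one frame interval `dt`.
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`.
#' @param dt Frame interval in seconds, shared by all tracks.
#' @param pixel_size_nm Optional camera pixel size in nm (metadata only).
#' @param notes Optional character provenance notes.
#'
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, dt, pixel_size_nm = NA_real_, notes = character()) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    stop("track data frame is missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  tracks <- tracks[order(tracks$track_id, tracks$frame), need, drop = FALSE]
  rownames(tracks) <- NULL
  if (anyDuplicated(tracks[, c("track_id", "frame")])) {
    i <- anyDuplicated(tracks[, c("track_id", "frame")])
    stop(sprintf("duplicate (track_id, frame) pair at row %d: track %s frame %s",
                 i, tracks$track_id[i], tracks$frame[i]))
  }
  structure(list(tracks = tracks, dt = dt,
                 pixel_size_nm = pixel_size_nm, notes = notes),
            class = "track_set")
}

#' Number of tracks in a track set
#' @param ts A `track_set`.
#' @return Integer count of distinct tracks.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  length(unique(ts$tracks$track_id))
}

#' Split a track set into per-track data frames
#' @param ts A `track_set`.
#' @return Named list of per-track data frames, ordered by track id.
#' @export
split_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  split(ts$tracks, ts$tracks$track_id)
}

#' Track lengths (frames per track)
#' @param ts A `track_set`.
#' @return Named integer vector of per-track lengths.
#' @export
track_lengths <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  tab <- table(ts$tracks$track_id)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d localizations, dt = %g s\n",
              n_tracks(x), nrow(x$tracks), x$dt))
  if (!is.na(x$pixel_size_nm)) {
    cat(sprintf("  pixel size: %g nm\n", x$pixel_size_nm))
  }
  invisible(x)
}

# internal: net start-to-end displacement per track, um
net_displacements <- function(ts) {
  vapply(split_tracks(ts), function(tr) {
    n <- nrow(tr)
    sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2)
  }, numeric(1))
}
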