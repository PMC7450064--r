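#' Read a track set from CSV
#'
#' Expects columns `track_id`, `frame`, `t_s`, `x_um`, `y_um`. Rows are
#' grouped by track id and sorted by frame; the frame interval is inferred
#' from the time stamps and checked to be uniform within and across tracks.
#'
#' @param path CSV file path.
#' @param dt_tol Relative tolerance for frame-interval uniformity.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dt_tol = 1e-4) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  df <- df[order(df$track_id, df$frame), ]
  dup <- which(duplicated(df[, c("track_id", "frame")]))
  if (length(dup)) {
    stop(sprintf("duplicate (track_id, frame) in '%s': track %s frame %s",
                 path, df$track_id[dup[1]], df$frame[dup[1]]))
  }
  dts <- unlist(lapply(split(df, df$track_id), function(tr) {
    if (nrow(tr) < 2) return(numeric(0))
    diff(tr$t_s) / diff(tr$frame)
  }))
  if (!length(dts)) stop(sprintf("'%s' contains no track with >= 2 frames", path))
  dt <- median(dts)
  off <- which(abs(dts - dt) > dt_tol * dt)
  if (length(off)) {
    stop(sprintf("non-uniform frame interval in '%s' (found %g s vs %g s)",
                 path, dts[off[1]], dt))
  }
  track_set(df, dt = dt, notes = sprintf("read from %s", basename(path)))
}

#' Write a track set to CSV
#'
#' Deterministic output: columns `track_id, frame, t_s, x_um, y_um`, rows
#' ordered by track id then frame, positions at fixed 6-decimal precision
#' (micrometre coordinates, i.e. picometre resolution). Two writes of the
#' same track set are byte-identical.
#'
#' @param ts A [track_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- ts$tracks
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("track_id,frame,t_s,x_um,y_um", con)
  if (nrow(df)) {
    writeLines(sprintf("%s,%d,%.6f,%.6f,%.6f", df$track_id,
                       as.integer(df$frame), df$t_s, df$x_um, df$y_um), con)
  }
  invisible(path)
}

#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 16-bit TIFF pages (values above 65535 are
#' clipped with a warning). The sidecar `<path>.json` records pixel size,
#' frame interval, ground-truth emitter positions and the clip count.
#'
#' @param fs A `frame_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(fs, path) {
  stopifnot(inherits(fs, "frame_stack"))
  mx <- max(fs$frames)
  if (mx > 65535) warning("intensities above 65535 clipped for 16-bit TIFF")
  pages <- lapply(seq_len(dim(fs$frames)[3]), function(i) {
    pmin(pmax(round(fs$frames[, , i]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(pixel_size_nm = fs$pixel_size_nm, dt = fs$dt,
               n_clipped = fs$n_clipped, ground_truth = fs$ground_truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must sit beside it.
#' @return A `frame_stack` with integer photon counts.
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 65535)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar JSON: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(frames = frames, pixel_size_nm = side$pixel_size_nm,
                 dt = side$dt,
                 ground_truth = as.data.frame(side$ground_truth),
                 n_clipped = side$n_clipped),
            class = "frame_stack")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file: ", path)
  }
}
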