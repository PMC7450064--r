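#' Camera model for synthetic frame rendering
#'
#' Pixel geometry and noise model of the sCMOS detector emulated by
#' [render_frames()]. The two pixel-size presets correspond to the imaging
#' configurations used for SPT (99 nm/px) and for force calibration at
#' 2 x 2 binning (217 nm/px).
#'
#' @param pixel_size_nm Pixel size in nm (99 or 217 are the presets; any
#'   positive value is accepted).
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm.
#' @param photons_per_spot Expected total photons per emitter per frame.
#' @param background Background level, photons per pixel.
#' @param read_noise Gaussian read noise, e- r.m.s. per pixel.
#' @param frame_shape Integer `c(rows, cols)`.
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 99, psf_sigma_nm = 150,
                         photons_per_spot = 5000, background = 10,
                         read_noise = 2, frame_shape = c(64, 64)) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm > 0, photons_per_spot > 0,
            background >= 0, read_noise >= 0,
            length(frame_shape) == 2L, all(frame_shape >= 4))
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 photons_per_spot = photons_per_spot, background = background,
                 read_noise = read_noise,
                 frame_shape = as.integer(frame_shape)),
            class = "camera_model")
}

#' Render trajectories into a synthetic camera movie
#'
#' Draws each emitter as a pixel-integrated 2D Gaussian (the PSF integral
#' over each pixel, so the expected total signal equals `photons_per_spot`
#' up to edge truncation), adds a constant background, then applies Poisson
#' shot noise on signal plus background and additive Gaussian read noise.
#' Emitters whose centre falls outside the frame are skipped with a warning
#' and counted in the output metadata (warn-and-clip policy).
#'
#' Coordinates follow the image convention: x rightward along columns,
#' y downward along rows, with the centre of pixel (0, 0) at (0, 0) um.
#'
#' @param ts A [track_set()] with positions in um.
#' @param cam A [camera_model()].
#' @param seed Optional integer seed for the noise draws.
#' @param shot_noise,read_noise Logical; disable to obtain noise-free
#'   expectation images (background still added).
#' @return An object of class `frame_stack`: list with `frames` (array
#'   rows x cols x time), `pixel_size_nm`, `dt`, `ground_truth` (data frame
#'   of true emitter positions per frame) and `n_clipped`.
#' @export
render_frames <- function(ts, cam, seed = NULL, shot_noise = TRUE,
                          read_noise = TRUE) {
  stopifnot(inherits(ts, "track_set"), inherits(cam, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  nr <- cam$frame_shape[1]
  nc <- cam$frame_shape[2]
  px <- cam$pixel_size_nm / 1000  # um per px
  s_px <- cam$psf_sigma_nm / cam$pixel_size_nm
  tr <- ts$tracks
  n_frames <- if (nrow(tr)) max(tr$frame) + 1L else 0L
  if (n_frames == 0L) n_frames <- 1L
  frames <- array(0, dim = c(nr, nc, n_frames))
  n_clipped <- 0L
  for (f in seq_len(n_frames) - 1L) {
    img <- matrix(cam$background, nr, nc)
    em <- tr[tr$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(em))) {
      x_px <- em$x_um[i] / px
      y_px <- em$y_um[i] / px
      if (x_px < -0.5 || x_px > nc - 0.5 || y_px < -0.5 || y_px > nr - 0.5) {
        n_clipped <- n_clipped + 1L
        next
      }
      cols <- 0:(nc - 1)
      rows <- 0:(nr - 1)
      wx <- pnorm((cols + 0.5 - x_px) / s_px) - pnorm((cols - 0.5 - x_px) / s_px)
      wy <- pnorm((rows + 0.5 - y_px) / s_px) - pnorm((rows - 0.5 - y_px) / s_px)
      img <- img + cam$photons_per_spot * outer(wy, wx)
    }
    if (shot_noise) {
      img <- matrix(rpois(nr * nc, lambda = img), nr, nc)
    }
    if (read_noise && cam$read_noise > 0) {
      img <- img + matrix(rnorm(nr * nc, sd = cam$read_noise), nr, nc)
    }
    frames[, , f + 1L] <- pmax(img, 0)
  }
  if (n_clipped > 0L) {
    warning(sprintf("%d emitter position(s) outside the frame were clipped",
                    n_clipped))
  }
  gt <- tr[, c("frame", "track_id", "x_um", "y_um")]
  structure(list(frames = frames, pixel_size_nm = cam$pixel_size_nm,
                 dt = ts$dt, ground_truth = gt, n_clipped = n_clipped),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px at %g nm/px, dt = %g s\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$dt))
  invisible(x)
}
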