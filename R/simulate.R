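#' Simulation configuration for drift-diffusion tracks
#'
#' Parameters of the Brownian-dynamics trajectory generator. Defaults follow
#' the membrane-diffusion regime the package targets: lipid-bound particles
#' on a supported bilayer diffusing at D ~ 0.13 um^2/s, imaged at 50 Hz with
#' ~10 nm localization noise.
#'
#' @param D_true Diffusion coefficient in um^2/s (>= 0).
#' @param dt Frame interval in seconds (> 0).
#' @param n_frames Number of frames per track (>= 2).
#' @param n_tracks Number of tracks.
#' @param sigma_loc Localization noise s.d. per axis in um, added to the
#'   reported positions only (it does not feed back into the dynamics).
#' @param arena Bounding box `c(xmin, xmax, ymin, ymax)` in um. Tracks are
#'   truncated at their first step outside the arena (particles leaving the
#'   field of view), never reflected.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param start_box Optional box `c(xmin, xmax, ymin, ymax)` for initial
#'   positions; defaults to the arena.
#' @param D_drift Optional mobility diffusivity used for the drift response
#'   `v = F * D_drift / (kB T)`; defaults to `D_true`. Setting `D_true = 0`
#'   with `D_drift > 0` yields the noise-free drift limit.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(D_true = 0.13, dt = 0.02, n_frames = 500,
                       n_tracks = 100, sigma_loc = 0.01,
                       arena = c(-80, 80, -80, 80), seed,
                       start_box = NULL, D_drift = NULL) {
  stopifnot(is.numeric(D_true), D_true >= 0,
            is.numeric(dt), dt > 0,
            n_frames >= 2, n_tracks >= 1,
            is.numeric(sigma_loc), sigma_loc >= 0,
            is.numeric(arena), length(arena) == 4L,
            arena[2] > arena[1], arena[4] > arena[3])
  if (missing(seed)) stop("sim_config() requires an explicit integer seed")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.null(start_box)) {
    stopifnot(length(start_box) == 4L,
              start_box[2] >= start_box[1], start_box[4] >= start_box[3])
  }
  if (!is.null(D_drift)) stopifnot(is.numeric(D_drift), D_drift >= 0)
  structure(list(D_true = D_true, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_tracks = as.integer(n_tracks),
                 sigma_loc = sigma_loc, arena = as.numeric(arena),
                 seed = as.integer(seed), start_box = start_box,
                 D_drift = D_drift %||% D_true),
            class = "sim_config")
}

#' Simulate drift-diffusion trajectories under a needle force field
#'
#' Euler-Maruyama integration with the frame interval as the step:
#' \deqn{\Delta r = v(r)\,dt + \sqrt{2 D \, dt}\,\xi,}
#' with \eqn{\xi} standard bivariate normal and the drift velocity obtained
#' from the force field through the Einstein mobility,
#' \eqn{v(r) = F(r) D / (k_B T)}. The force is evaluated at the start of each
#' step; at the length scales simulated here the field varies slowly over one
#' step. Independent Gaussian localization noise is added to the reported
#' positions afterwards. Tracks are truncated at their first exit from the
#' arena; tracks shorter than 2 frames after truncation are dropped.
#'
#' @param config A [sim_config()].
#' @param needle A [needle_geometry()], or `NULL` for free diffusion.
#' @param phys A [physical_params()] object.
#' @return A [track_set()]; the simulation is bit-reproducible given the
#'   config seed.
#' @examples
#' cfg <- sim_config(n_tracks = 3, n_frames = 50, seed = 1)
#' ts <- simulate_tracks(cfg)
#' ts
#' @export
simulate_tracks <- function(config, needle = NULL,
                            phys = physical_params()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(needle)) stopifnot(inherits(needle, "needle_geometry"))
  set.seed(config$seed)
  n <- config$n_tracks
  nf <- config$n_frames
  sb <- config$start_box %||% config$arena
  x <- runif(n, sb[1], sb[2])
  y <- runif(n, sb[3], sb[4])
  X <- matrix(NA_real_, nf, n)
  Y <- matrix(NA_real_, nf, n)
  X[1, ] <- x
  Y[1, ] <- y
  step_sd <- sqrt(2 * config$D_true * config$dt)
  mobility <- config$D_drift / kBT_fN_um(phys)  # (um/s) per fN
  for (i in seq_len(nf - 1L)) {
    if (!is.null(needle)) {
      Fv <- force_field(needle, cbind(x, y))
      x <- x + Fv[, 1] * mobility * config$dt
      y <- y + Fv[, 2] * mobility * config$dt
    }
    x <- x + step_sd * rnorm(n)
    y <- y + step_sd * rnorm(n)
    X[i + 1L, ] <- x
    Y[i + 1L, ] <- y
  }
  a <- config$arena
  out <- X < a[1] | X > a[2] | Y < a[3] | Y > a[4]
  keep_len <- apply(out, 2L, function(o) {
    j <- which(o)
    if (length(j)) j[1] - 1L else nf
  })
  dfs <- lapply(seq_len(n), function(k) {
    len <- keep_len[k]
    if (len < 2L) return(NULL)
    xs <- X[seq_len(len), k]
    ys <- Y[seq_len(len), k]
    if (config$sigma_loc > 0) {
      xs <- xs + rnorm(len, sd = config$sigma_loc)
      ys <- ys + rnorm(len, sd = config$sigma_loc)
    }
    data.frame(track_id = k, frame = 0:(len - 1L),
               t_s = (0:(len - 1L)) * config$dt, x_um = xs, y_um = ys)
  })
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (!length(dfs)) stop("all simulated tracks were truncated below 2 frames")
  track_set(do.call(rbind, dfs), dt = config$dt,
            notes = sprintf("simulated, seed %d", config$seed))
}

#' Generate a matched pair of fiducial point sets
#'
#' Samples `n` source points uniformly in a box and maps them through a
#' nonreflective similarity transform, optionally adding isotropic Gaussian
#' noise to the target points. Used to exercise fiducial-based registration
#' with known ground truth.
#'
#' @param transform A [similarity_transform()].
#' @param n Number of fiducials (>= 2; fewer leave the transform
#'   underdetermined downstream).
#' @param noise_sd Isotropic Gaussian noise s.d. (um) added to `dst`.
#' @param seed Optional integer seed.
#' @param box Sampling box `c(xmin, xmax, ymin, ymax)` in um.
#' @return List with `src` and `dst`, each an n x 2 matrix (um).
#' @export
make_fiducial_pair <- function(transform, n, noise_sd = 0, seed = NULL,
                               box = c(0, 100, 0, 100)) {
  stopifnot(inherits(transform, "similarity_transform"),
            is.numeric(n), length(n) == 1L)
  if (n < 2) stop("at least 2 fiducials are required")
  stopifnot(noise_sd >= 0, length(box) == 4L)
  if (!is.null(seed)) set.seed(seed)
  src <- cbind(runif(n, box[1], box[2]), runif(n, box[3], box[4]))
  dst <- apply_transform(transform, src)
  if (noise_sd > 0) {
    dst <- dst + matrix(rnorm(2 * n, sd = noise_sd), ncol = 2L)
  }
  list(src = src, dst = dst)
}
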