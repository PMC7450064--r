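#' Nonreflective similarity transform
#'
#' Uniform scale + rotation + translation with positive determinant (no
#' mirroring): \eqn{p \mapsto s R(\theta) p + t}. This is the transform
#' class used to register single-particle trajectories onto a second
#' imaging modality via fiducial markers.
#'
#' @param scale Positive uniform scale factor.
#' @param rotation Rotation angle in radians (counter-clockwise in the
#'   (x, y) coordinate order used throughout).
#' @param translation Length-2 translation vector (um).
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0,
            is.numeric(rotation), length(rotation) == 1L,
            length(translation) == 2L)
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
    x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param t A [similarity_transform()].
#' @param points Length-2 vector or n x 2 matrix of (x, y) points.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, points) {
  stopifnot(inherits(t, "similarity_transform"))
  single <- is.null(dim(points))
  if (single) points <- matrix(as.numeric(points), ncol = 2L)
  R <- matrix(c(cos(t$rotation), sin(t$rotation),
                -sin(t$rotation), cos(t$rotation)), 2L, 2L)
  out <- t$scale * points %*% t(R)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  if (single) drop(out) else out
}

#' Invert a similarity transform
#'
#' @param t A [similarity_transform()].
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  inv_tr <- -apply_transform(similarity_transform(1 / t$scale, -t$rotation),
                             t$translation)
  similarity_transform(1 / t$scale, -t$rotation, inv_tr)
}

#' Fit a nonreflective similarity transform to corresponding points
#'
#' Closed-form least squares (Procrustes with uniform scale, reflection
#' disallowed by construction): writing points as complex numbers, the
#' optimal scale-rotation is the complex regression coefficient of the
#' centred destination on the centred source, whose modulus (the scale) is
#' positive whenever the sources are not all coincident — the implied
#' linear map therefore always has positive determinant. Deterministic and
#' exact for noise-free input at n = 2. Correspondence is given by input
#' order; there is no automatic matching.
#'
#' @param src,dst n x 2 matrices (or 2-column data frames) of corresponding
#'   points, n >= 2.
#' @return The fitted [similarity_transform()].
#' @export
fit_similarity <- function(src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal point counts")
  if (nrow(src) < 2L) stop("at least 2 point pairs are required")
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  zs_c <- zs - mean(zs)
  zd_c <- zd - mean(zd)
  denom <- sum(Mod(zs_c)^2)
  if (denom < 1e-18) stop("degenerate source points (all coincident)")
  a <- sum(Conj(zs_c) * zd_c) / denom
  if (Mod(a) < 1e-15) {
    stop("degenerate correspondence: destination collapses to a point")
  }
  scale <- Mod(a)
  rotation <- Arg(a)
  mu_s <- c(mean(src[, 1]), mean(src[, 2]))
  mu_d <- c(mean(dst[, 1]), mean(dst[, 2]))
  translation <- mu_d - apply_transform(
    similarity_transform(scale, rotation), mu_s)
  similarity_transform(scale, rotation, translation)
}

#' Root-mean-square registration residual
#'
#' @param t A [similarity_transform()].
#' @param src,dst Corresponding point sets (n x 2), n >= 1.
#' @return r.m.s. of `|t(src_i) - dst_i|`, in the units of the input.
#' @export
registration_residual <- function(t, src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal point counts")
  if (!nrow(src)) stop("no points to evaluate")
  r <- apply_transform(t, src) - dst
  sqrt(mean(r[, 1]^2 + r[, 2]^2))
}
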