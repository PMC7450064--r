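#' Magnetic needle geometry and attractive force field
#'
#' Describes the in-plane position of the needle tip and a radially
#' attractive force field of magnitude \eqn{F(d) = F_0 (d_0/d)^p}, where
#' \eqn{d} is the Euclidean distance to the tip. The power law is a model
#' choice: any monotone decay reproduces the qualitative force-distance
#' behaviour of a magnetized needle, and `p` is configurable (`p = 0` gives a
#' spatially constant force, convenient for calibration simulations).
#'
#' @param tip Numeric length-2: tip position (x, y) in um.
#' @param F0 Force magnitude at the reference distance, in fN. Must be >= 0.
#' @param d0 Reference distance in um. Must be > 0.
#' @param p Decay exponent (dimensionless, >= 0). Default 1.
#'
#' @return An object of class `needle_geometry`.
#' @examples
#' ndl <- needle_geometry(tip = c(0, 0), F0 = 13.4, d0 = 50, p = 1)
#' force_field(ndl, c(-100, 0))  # (6.7, 0) fN, pointing towards the tip
#' @export
needle_geometry <- function(tip, F0, d0, p = 1) {
  stopifnot(is.numeric(tip), length(tip) == 2L, all(is.finite(tip)),
            is.numeric(F0), length(F0) == 1L, F0 >= 0,
            is.numeric(d0), length(d0) == 1L, d0 > 0,
            is.numeric(p), length(p) == 1L, p >= 0)
  structure(list(tip = as.numeric(tip), F0 = F0, d0 = d0, p = p),
            class = "needle_geometry")
}

#' Evaluate the needle force field
#'
#' @param needle A [needle_geometry()] object.
#' @param pos A length-2 numeric position (um) or an n x 2 matrix of
#'   positions.
#' @return The force vector(s) in fN: a length-2 vector for a single
#'   position, otherwise an n x 2 matrix. Each vector points from `pos`
#'   towards the tip with magnitude \eqn{F_0 (d_0/d)^p}.
#' @export
force_field <- function(needle, pos) {
  stopifnot(inherits(needle, "needle_geometry"))
  single <- is.null(dim(pos))
  if (single) {
    stopifnot(length(pos) == 2L)
    pos <- matrix(as.numeric(pos), ncol = 2L)
  }
  stopifnot(ncol(pos) == 2L)
  dx <- needle$tip[1] - pos[, 1]
  dy <- needle$tip[2] - pos[, 2]
  d <- sqrt(dx^2 + dy^2)
  if (any(d < 1e-9)) {
    stop("force field is singular at the needle tip (zero distance)")
  }
  mag <- needle$F0 * (needle$d0 / d)^needle$p
  out <- cbind(mag * dx / d, mag * dy / d)
  if (single) drop(out) else out
}
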