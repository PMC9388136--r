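#' Thin simulation box, periodic in X/Y, reflective in Z
#'
#' The simulation domain is a thin three-dimensional box: the X and Y
#' directions are periodic (with periods `size_x`, `size_y`) and the Z
#' direction is bounded on `[0, size_z]` by mirror reflection. The network
#' scenarios use boxes whose thickness is far smaller than their lateral
#' extent (e.g. 60 x 60 x 0.2 um); this is not enforced, only conventional.
#'
#' @param size_x,size_y,size_z Box edge lengths in micrometers; all strictly
#'   positive.
#' @return An object of class `simulation_box`.
#' @examples
#' box <- simulation_box(20, 20, 0.2)
#' minimum_image(c(19, 0, 0.1), box)
#' @export
simulation_box <- function(size_x, size_y, size_z) {
  sizes <- c(size_x, size_y, size_z)
  if (!all(is.finite(sizes)) || any(sizes <= 0)) {
    stop("box sizes must be finite and strictly positive")
  }
  structure(list(size_x = size_x, size_y = size_y, size_z = size_z),
            class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("simulation box: %g x %g x %g um (periodic X/Y, reflective Z)\n",
              x$size_x, x$size_y, x$size_z))
  invisible(x)
}

#' Minimum-image convention for displacements
#'
#' Wraps the X and Y components of a displacement into the half-open
#' interval `[-L/2, L/2)` for the respective box period `L`, yielding the
#' shortest periodic image. The Z component is returned unchanged (Z is
#' reflective, not periodic). The half-open convention resolves the
#' exact-half tie deterministically toward `-L/2`.
#'
#' @param dx Displacement: a length-3 vector or an n x 3 matrix (um).
#' @param box A [simulation_box()].
#' @return Wrapped displacement of the same shape as `dx`.
#' @export
minimum_image <- function(dx, box) {
  v <- is.null(dim(dx))
  m <- if (v) matrix(dx, ncol = 3) else dx
  if (ncol(m) != 3L) stop("dx must have 3 columns")
  if (!all(is.finite(m))) stop("non-finite displacement: corrupted state")
  m[, 1] <- m[, 1] - box$size_x * floor(m[, 1] / box$size_x + 0.5)
  m[, 2] <- m[, 2] - box$size_y * floor(m[, 2] / box$size_y + 0.5)
  if (v) as.vector(m[1, ]) else m
}

#' Mirror reflection into the Z slab
#'
#' Applies the mirror rule `z < 0 -> -z`, `z > size_z -> 2 size_z - z`
#' repeatedly until the coordinate lies in `[0, size_z]`. Positions only:
#' first-order Brownian dynamics carries no persistent velocity state.
#'
#' @param z Numeric vector of Z coordinates after an unconstrained update.
#' @param box A [simulation_box()].
#' @return Reflected coordinates in `[0, size_z]`.
#' @export
reflect_z <- function(z, box) {
  if (!all(is.finite(z))) stop("non-finite z coordinate: corrupted state")
  L <- box$size_z
  # Closed form of the iterated mirror map: fold into [0, 2L) then mirror.
  zf <- z %% (2 * L)
  ifelse(zf > L, 2 * L - zf, zf)
}
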