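#' Unit-cell parameters
#'
#' Constructs a validated set of unit-cell parameters. Lengths are in
#' angstrom, angles in degrees. The fractional-to-Cartesian convention used
#' throughout the package places `a` along x, `b` along y, and `c` in the
#' xz-plane, which handles monoclinic obliquity exactly.
#'
#' @param a,b,c cell edge lengths in angstrom, all positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @export
#' @examples
#' unit_cell(19.9960, 16.7246, 19.1703, beta = 116.319)
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("cell lengths must be finite and positive")
  }
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    abort("cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
  if (cell_volume_raw(cell) <= 0 || !is.finite(cell_volume_raw(cell))) {
    abort("degenerate cell: the metric volume is not positive")
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)
  ))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cell_volume_raw <- function(cell) {
  ca <- cos(deg2rad(cell$alpha))
  cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(NaN)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Unit-cell volume
#'
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}. For a monoclinic cell this reduces to
#' \eqn{abc\sin\beta}.
#'
#' @param cell a [unit_cell()].
#' @return volume in cubic angstrom.
#' @export
#' @examples
#' cell_volume(unit_cell(19.9960, 16.7246, 19.1703, beta = 116.319))
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  v <- cell_volume_raw(cell)
  if (!is.finite(v) || v <= 0) abort("degenerate cell: volume is not positive")
  v
}

#' Fractional-to-Cartesian transformation matrix
#'
#' Returns the 3x3 matrix `M` such that Cartesian coordinates (angstrom) are
#' `M %*% frac`. Convention: `a` along x, `b` along y, `c` in the xz-plane
#' for monoclinic (general triclinic handled with the standard construction,
#' c component arrangement chosen so that `det(M) = V`).
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
frac_to_cart_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  al <- deg2rad(cell$alpha); be <- deg2rad(cell$beta); ga <- deg2rad(cell$gamma)
  v <- cell_volume(cell) / (cell$a * cell$b * cell$c)
  # standard crystallographic matrix; for beta-unique monoclinic this is
  # a along x, b along y, c in the xz-plane
  m <- matrix(0, 3, 3)
  m[1, 1] <- cell$a
  m[1, 2] <- cell$b * cos(ga)
  m[2, 2] <- cell$b * sin(ga)
  m[1, 3] <- cell$c * cos(be)
  m[2, 3] <- cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  m[3, 3] <- cell$c * v / sin(ga)
  m
}

#' Reciprocal-lattice basis matrix
#'
#' Columns are the Cartesian reciprocal vectors a*, b*, c* (crystallographic
#' convention, no 2*pi), so the plane normal of `(hkl)` is
#' `reciprocal_matrix(cell) %*% c(h, k, l)` and its length is `1/d_hkl`.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix with reciprocal vectors as columns.
#' @export
reciprocal_matrix <- function(cell) {
  t(solve(frac_to_cart_matrix(cell)))
}

check_hkl <- function(hkl) {
  hkl <- as.matrix(hkl)
  if (is.null(dim(hkl)) || ncol(hkl) == 1) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "double"
  if (ncol(hkl) != 3) abort("hkl must have three components")
  if (any(rowSums(abs(hkl)) == 0)) abort("Miller indices (0,0,0) are not a plane")
  hkl
}

#' Interplanar spacing d_hkl
#'
#' Computes \eqn{d_{hkl} = 1/|h\mathbf{a}^* + k\mathbf{b}^* + l\mathbf{c}^*|}
#' through the reciprocal metric tensor; exact for any crystal system,
#' including the monoclinic cross term.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer vector of length 3, or a matrix/data frame with columns
#'   h, k, l (one plane per row).
#' @return numeric vector of spacings in angstrom.
#' @export
#' @examples
#' cell <- unit_cell(19.9960, 16.7246, 19.1703, beta = 116.319)
#' d_spacing(cell, c(1, 1, 0))
#' d_spacing(cell, rbind(c(0, 0, 2), c(1, 1, -1)))
d_spacing <- function(cell, hkl) {
  hkl <- check_hkl(hkl)
  g <- reciprocal_matrix(cell)
  vecs <- hkl %*% t(g)
  1 / sqrt(rowSums(vecs^2))
}

#' Angle between two lattice planes
#'
#' The interfacial angle between `(h1 k1 l1)` and `(h2 k2 l2)`, i.e. the
#' angle between their reciprocal-lattice normal vectors, in degrees within
#' \[0, 180\].
#'
#' @param cell a [unit_cell()].
#' @param hkl1,hkl2 integer vectors of length 3 (not all zero).
#' @return angle in degrees.
#' @export
#' @examples
#' interfacial_angle(unit_cell(10, 10, 10), c(1, 0, 0), c(0, 1, 0))
interfacial_angle <- function(cell, hkl1, hkl2) {
  v1 <- drop(reciprocal_matrix(cell) %*% drop(check_hkl(hkl1)))
  v2 <- drop(reciprocal_matrix(cell) %*% drop(check_hkl(hkl2)))
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}
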