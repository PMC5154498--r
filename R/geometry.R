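#' Minimum-image displacement in an xy-periodic box
#'
#' Computes the displacement vector(s) from `p` to `q` under the membrane
#' convention: the box is periodic in x and y only, never in z. Inputs may be
#' single points (length-3 vectors) or n x 3 matrices; matrices are recycled
#' row-wise against each other.
#'
#' @param p,q Numeric length-3 vectors or n x 3 matrices of positions (nm).
#' @param box Numeric length-3 box edge lengths (nm); only `box[1]` and
#'   `box[2]` are used for wrapping.
#' @return An n x 3 matrix (or length-3 vector when both inputs are vectors)
#'   of minimum-image displacements p -> q.
#' @examples
#' min_image_displacement(c(9.5, 5, 0), c(0.5, 5, 0), c(10, 10, 11))
#' @export
min_image_displacement <- function(p, q, box) {
  stopifnot(all(box[1:2] > 0))
  pv <- is.null(dim(p)) && is.null(dim(q))
  p <- matrix(p, ncol = 3L)
  q <- matrix(q, ncol = 3L)
  if (nrow(p) != nrow(q)) {
    if (nrow(p) == 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
    if (nrow(q) == 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  }
  d <- q - p
  for (k in 1:2) {
    L <- box[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  if (pv) drop(d) else d
}

#' Pairwise minimum-image distances between two bead sets
#'
#' @param a,b n x 3 / m x 3 coordinate matrices (nm).
#' @param box length-3 box (xy-periodic).
#' @return n x m matrix of distances.
#' @export
min_image_dist <- function(a, b, box) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  dz <- outer(a[, 3], b[, 3], `-`)
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Center of mass of a bead selection
#'
#' Martini beads are treated as equal mass, so the center of mass is the
#' unweighted mean of bead positions. To stay consistent across the periodic
#' x/y boundaries each bead is first unwrapped about the first bead of the
#' selection (minimum-image), the plain mean is taken, and the result is
#' wrapped back into the box.
#'
#' @param coords n x 3 matrix of bead positions (nm).
#' @param box length-3 box (xy-periodic).
#' @param wrap Wrap the result back into `[0, L)` in x and y (default TRUE).
#' @return Length-3 numeric position (nm).
#' @export
center_of_mass <- function(coords, box, wrap = TRUE) {
  coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) == 0L) abort("center_of_mass(): empty bead selection")
  ref <- coords[1L, ]
  d <- min_image_displacement(ref, coords, box)
  com <- ref + colMeans(matrix(d, ncol = 3L))
  if (wrap) {
    com[1] <- com[1] %% box[1]
    com[2] <- com[2] %% box[2]
  }
  com
}

# wrap xy coordinates into [0, L)
wrap_xy <- function(coords, box) {
  coords[, 1] <- coords[, 1] %% box[1]
  coords[, 2] <- coords[, 2] %% box[2]
  coords
}

# signed angle of 2d vector(s), in (-pi, pi]
atan2_angle <- function(dx, dy) {
  a <- atan2(dy, dx)
  a[a <= -pi] <- pi
  a
}

# wrap an angle difference into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}
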