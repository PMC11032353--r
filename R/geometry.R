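## Geometry helpers: minimum-image displacements, bond angles and dihedral
## angles with analytic Cartesian gradients. All functions are vectorized
## over rows of coordinate matrices.

# minimum-image displacement(s) a - b in an orthorhombic box; box may be
# NULL for open boundaries
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (ax in 1:3) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

# row-wise Euclidean norms
row_norm <- function(m) sqrt(rowSums(m * m))

row_dot <- function(a, b) rowSums(a * b)

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# wrap coordinates into [0, box)
wrap_coords <- function(x, box) {
  for (ax in 1:3) x[, ax] <- x[, ax] - box[ax] * floor(x[, ax] / box[ax])
  x
}

#' Bond angle and its Cartesian gradient
#'
#' Angle at j formed by particles i-j-k (radians) with analytic gradients,
#' using minimum-image displacements when a box is given.
#'
#' @param xi,xj,xk coordinate matrices (n x 3).
#' @param box orthorhombic box lengths or NULL.
#' @return list with `theta` (n), and gradients `dthet_di`, `dthet_dj`,
#'   `dthet_dk` (n x 3 each).
#' @export
angle_geometry <- function(xi, xj, xk, box = NULL) {
  u <- min_image(xi - xj, box)
  v <- min_image(xk - xj, box)
  nu <- row_norm(u); nv <- row_norm(v)
  cth <- pmin(1, pmax(-1, row_dot(u, v) / (nu * nv)))
  th <- acos(cth)
  sth <- sqrt(pmax(1e-24, 1 - cth * cth))
  # d(theta)/d(xi) = -(v/|v| - cos(th) u/|u|) / (|u| sin th)
  uh <- u / nu; vh <- v / nv
  di <- -(vh - cth * uh) / (nu * sth)
  dk <- -(uh - cth * vh) / (nv * sth)
  dj <- -(di + dk)
  list(theta = th, dthet_di = di, dthet_dj = dj, dthet_dk = dk)
}

#' Dihedral angle and its Cartesian gradient
#'
#' Dihedral i-j-k-l on (-pi, pi] with analytic gradients (standard
#' cross-product formulation), minimum-image aware.
#'
#' @param xi,xj,xk,xl coordinate matrices (n x 3).
#' @param box orthorhombic box lengths or NULL.
#' @return list with `phi` and gradients `dphi_di` .. `dphi_dl`.
#' @export
dihedral_geometry <- function(xi, xj, xk, xl, box = NULL) {
  b1 <- min_image(xj - xi, box)
  b2 <- min_image(xk - xj, box)
  b3 <- min_image(xl - xk, box)
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  m1 <- row_cross(n1, b2 / nb2)
  x <- row_dot(n1, n2)
  y <- row_dot(m1, n2)
  phi <- atan2(y, x)
  n1sq <- pmax(1e-24, rowSums(n1 * n1))
  n2sq <- pmax(1e-24, rowSums(n2 * n2))
  di <- (nb2 / n1sq) * n1
  dl <- -(nb2 / n2sq) * n2
  f1 <- row_dot(b1, b2) / (nb2 * nb2)
  f3 <- row_dot(b3, b2) / (nb2 * nb2)
  dj <- -(1 + f1) * di + f3 * dl
  dk <- f1 * di - (1 + f3) * dl
  list(phi = phi, dphi_di = di, dphi_dj = dj, dphi_dk = dk, dphi_dl = dl)
}

# minimum-image angular difference on (-pi, pi]
ang_diff <- function(a, b) {
  d <- a - b
  d - 2 * pi * round(d / (2 * pi))
}
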