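#' Deterministic near-uniform rotation sampling via Hopf coordinates
#'
#' Samples n rotations from SO(3) using the Hopf fibration of the unit
#' quaternion sphere: the base 2-sphere is covered by a spherical Fibonacci
#' lattice and the circular fiber by a golden-ratio offset sequence, giving
#' a deterministic, seed-free lattice that is near-uniform with respect to
#' the Haar measure.  The identity rotation is always the first element.
#'
#' @param n Number of rotations (>= 1); the study-scale default elsewhere
#'   in the package is 2000.
#' @return A `rotation_set`: list with `quaternions` (n x 4 matrix of unit
#'   quaternions, scalar part first) and `count`.
#' @export
hopf_rotations <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  q <- matrix(0, n, 4)
  q[1, ] <- c(1, 0, 0, 0)
  if (n > 1) {
    m <- n - 1L
    i <- seq_len(m) - 0.5
    golden <- (1 + sqrt(5)) / 2
    # base S^2: spherical Fibonacci lattice (theta polar, phi azimuth)
    cos_theta <- 1 - 2 * i / m
    theta <- acos(pmin(1, pmax(-1, cos_theta)))
    phi <- (2 * pi * i * golden) %% (2 * pi)
    # fiber S^1: low-discrepancy angle from a second irrational stride
    psi <- (2 * pi * i * sqrt(2)) %% (2 * pi)
    q[-1, ] <- cbind(
      cos(theta / 2) * cos(psi / 2),
      cos(theta / 2) * sin(psi / 2),
      sin(theta / 2) * cos(phi + psi / 2),
      sin(theta / 2) * sin(phi + psi / 2)
    )
  }
  q <- q / sqrt(rowSums(q^2))
  structure(list(quaternions = q, count = n), class = "rotation_set")
}

#' @export
print.rotation_set <- function(x, ...) {
  cat(sprintf("<rotation_set: %d Hopf-sampled unit quaternions>\n", x$count))
  invisible(x)
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Numeric length-4 unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Quaternion algebra helpers
#'
#' `quat_multiply()` composes two rotations (apply `b`, then `a`);
#' `quat_conjugate()` inverts a unit quaternion; `rotation_distance()` is
#' the geodesic distance between two rotations, i.e. the angle of the
#' relative rotation in radians (0 to pi).
#'
#' @param a,b,q Length-4 quaternions, scalar part first.
#' @return A quaternion, or a distance in radians.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quat_multiply
#' @export
rotation_distance <- function(a, b) {
  2 * acos(pmin(1, abs(sum(a * b))))
}

# max over points of the distance to its nearest neighbour (radians);
# quaternions as an n x 4 matrix
max_nn_gap <- function(q) {
  n <- nrow(q)
  d <- abs(q %*% t(q))            # |dot| handles the q ~ -q identification
  diag(d) <- 0
  nn <- apply(d, 1, max)
  max(2 * acos(pmin(1, nn)))
}

# ideal nearest-neighbour spacing of n perfectly uniform rotations:
# cube-root of (Haar volume of SO(3) under the rotation-angle metric) / n
ideal_rotation_gap <- function(n) (8 * pi^2 / n)^(1 / 3)

#' Rigidly rotate a molecule about a center
#'
#' @param molecule A [molecule()].
#' @param q Unit quaternion (scalar part first).
#' @param center Length-3 rotation center (Angstrom); defaults to the
#'   origin.
#' @return The rotated [molecule()]; interatomic distances are preserved.
#' @export
rotate_molecule <- function(molecule, q, center = c(0, 0, 0)) {
  if (abs(sum(q^2) - 1) > 1e-8) stop("q must be a unit quaternion",
                                     call. = FALSE)
  R <- quat_to_matrix(q)
  coords <- atom_coords(molecule)
  rotated <- sweep(sweep(coords, 2, center, "-") %*% t(R), 2, center, "+")
  set_atom_coords(molecule, rotated)
}
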