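#' Promolecule Gaussian charge density on a grid
#'
#' The default, analytic stand-in for a quantum-chemical charge density: a
#' signed sum of atom-centered isotropic Gaussians, one per atom, each
#' normalised to the atom's partial charge,
#' \deqn{\rho(x) = \sum_a q_a (2\pi\sigma_a^2)^{-3/2}
#'       \exp(-|x - R_a|^2 / 2\sigma_a^2),}
#' with width \eqn{\sigma_a} = `width_scale` times the element's Bondi van
#' der Waals radius.  Evaluation is pointwise (separable per axis), so grid
#' refinement leaves shared-node values unchanged.
#'
#' @param molecule A [molecule()] with partial charges.
#' @param grid A [grid_spec()].
#' @param width_scale Dimensionless Gaussian width factor (default 0.5).
#' @return A [scalar_field()] of kind `"density"` (e/Angstrom^3).
#' @export
promolecule_density <- function(molecule, grid, width_scale = 0.5) {
  ax <- grid_axes(grid)
  coords <- atom_coords(molecule)
  sigma <- width_scale * element_property(molecule$atoms$element, "r_vdw")
  q <- molecule$atoms$charge
  # truncation warning when an atom sits close to a box face
  lo <- grid$origin
  hi <- grid$origin + grid$spacing * (grid$npoints - 1)
  face_dist <- pmin(
    apply(sweep(coords, 2, lo, "-"), 1, min),
    apply(sweep(-coords, 2, -hi, "-"), 1, min)
  )
  if (any(face_dist < 2 * sigma)) {
    warning(sum(face_dist < 2 * sigma),
            " atom(s) within 2 sigma of a box face: density truncated",
            call. = FALSE)
  }
  rho <- array(0, grid$npoints)
  for (a in seq_along(q)) {
    s2 <- 2 * sigma[a]^2
    gx <- exp(-(ax[[1]] - coords[a, 1])^2 / s2)
    gy <- exp(-(ax[[2]] - coords[a, 2])^2 / s2)
    gz <- exp(-(ax[[3]] - coords[a, 3])^2 / s2)
    amp <- q[a] * (pi * s2)^(-1.5)
    # separable outer product, z-major accumulation
    plane <- outer(gx, gy)
    for (k in seq_along(gz)) {
      rho[, , k] <- rho[, , k] + amp * gz[k] * plane
    }
  }
  scalar_field(grid, rho, "density")
}

#' Density backends
#'
#' A density backend turns a molecule into a charge-density
#' [scalar_field()] on any requested grid.  `promolecule_backend()` uses
#' the analytic Gaussian partial-charge density; `cube_backend()` serves
#' pre-computed densities (e.g. from external quantum chemistry) stored as
#' Gaussian cube files, resampled onto the requested grid by trilinear
#' interpolation (zero outside the cube's support).
#'
#' @param width_scale Gaussian width factor for the promolecule backend.
#' @param paths Named character vector mapping molecule id to cube file.
#' @return A `density_backend` object with a `$density(molecule, grid)`
#'   function.
#' @export
promolecule_backend <- function(width_scale = 0.5) {
  structure(
    list(name = "promolecule", width_scale = width_scale,
         density = function(molecule, grid) {
           promolecule_density(molecule, grid, width_scale = width_scale)
         }),
    class = "density_backend"
  )
}

#' @rdname promolecule_backend
#' @export
cube_backend <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  structure(
    list(name = "cube", paths = paths,
         density = function(molecule, grid) {
           p <- paths[[molecule$id]]
           if (is.null(p)) stop("no cube file registered for molecule ",
                                molecule$id, call. = FALSE)
           src <- read_cube(p)
           ax <- grid_axes(grid)
           pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
           vals <- trilinear_sample(src$values, src$grid, pts)
           scalar_field(grid, array(vals, grid$npoints), "density")
         }),
    class = "density_backend"
  )
}

#' @export
print.density_backend <- function(x, ...) {
  cat(sprintf("<density_backend: %s>\n", x$name))
  invisible(x)
}

# trilinear interpolation of a 3D array at arbitrary points (n x 3);
# values outside the grid support are 0
trilinear_sample <- function(values, grid, pts) {
  np <- grid$npoints
  # fractional index coordinates (0-based)
  f <- sweep(pts, 2, grid$origin, "-") / grid$spacing
  i0 <- floor(f)
  t <- f - i0
  out <- numeric(nrow(pts))
  # pad array with a zero shell so out-of-support lookups read 0
  padded <- array(0, np + 2L)
  padded[2:(np[1] + 1), 2:(np[2] + 1), 2:(np[3] + 1)] <- values
  # clamp 0-based corner indices into the padded frame (-1 .. np maps to
  # padded index ii + 2); np must broadcast per column, not recycle
  np_row <- matrix(np, nrow(f), 3, byrow = TRUE)
  ii <- pmin(pmax(i0, -1), np_row)
  inside <- f >= -1 & f < np_row   # beyond that every corner reads 0
  keep <- inside[, 1] & inside[, 2] & inside[, 3]
  if (!any(keep)) return(out)
  ii <- ii[keep, , drop = FALSE] + 2L
  tt <- t[keep, , drop = FALSE]
  dpad <- dim(padded)
  idx <- function(dx, dy, dz) {
    (ii[, 1] + dx - 1L) +
      (ii[, 2] + dy - 1L) * dpad[1] +
      (ii[, 3] + dz - 1L) * dpad[1] * dpad[2] + 1L
  }
  v <- (1 - tt[, 1]) * (1 - tt[, 2]) * (1 - tt[, 3]) * padded[idx(0L, 0L, 0L)] +
       tt[, 1]       * (1 - tt[, 2]) * (1 - tt[, 3]) * padded[idx(1L, 0L, 0L)] +
       (1 - tt[, 1]) * tt[, 2]       * (1 - tt[, 3]) * padded[idx(0L, 1L, 0L)] +
       tt[, 1]       * tt[, 2]       * (1 - tt[, 3]) * padded[idx(1L, 1L, 0L)] +
       (1 - tt[, 1]) * (1 - tt[, 2]) * tt[, 3]       * padded[idx(0L, 0L, 1L)] +
       tt[, 1]       * (1 - tt[, 2]) * tt[, 3]       * padded[idx(1L, 0L, 1L)] +
       (1 - tt[, 1]) * tt[, 2]       * tt[, 3]       * padded[idx(0L, 1L, 1L)] +
       tt[, 1]       * tt[, 2]       * tt[, 3]       * padded[idx(1L, 1L, 1L)]
  out[keep] <- v
  out
}
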